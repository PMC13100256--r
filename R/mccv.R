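#' Monte Carlo cross-validation configuration
#'
#' Defaults mirror the study design: 2000 subjects sampled from the cohort
#' at random, 100 times; within each sample 1500 train and 500 test. The
#' full model covariates are age, gender, race, a body-size term (BSA),
#' CCI, atrial fibrillation, OSA, hypertension, mPAP and PAC; handicapped
#' variants refit the model with one variable removed (age, mPAP or PAC by
#' default).
#'
#' @param n_sample subjects drawn (without replacement) per repetition.
#' @param n_train training subjects per repetition; the remaining
#'   `n_sample - n_train` form the test set.
#' @param n_reps repetitions (>= 2).
#' @param seed master seed; per-repetition sub-seeds are spawned from it
#'   deterministically.
#' @param model_covariates character vector of full-model covariates.
#' @param handicaps variables to remove one at a time.
#' @param ties tie-handling for the Cox fits.
#' @return list of class `mccv_config`.
#' @export
mccv_config <- function(n_sample = 2000L, n_train = 1500L, n_reps = 100L,
                        seed = 1L,
                        model_covariates = c("age", "gender", "race", "bsa",
                                             "cci", "afib", "osa", "htn",
                                             "mpap", "pac"),
                        handicaps = c("age", "mpap", "pac"),
                        ties = "efron") {
  stopifnot(n_train < n_sample, n_reps >= 2,
            all(handicaps %in% model_covariates))
  structure(list(n_sample = as.integer(n_sample),
                 n_train = as.integer(n_train),
                 n_test = as.integer(n_sample - n_train),
                 n_reps = as.integer(n_reps), seed = as.integer(seed),
                 model_covariates = model_covariates,
                 handicaps = handicaps, ties = ties),
            class = "mccv_config")
}

#' Monte Carlo cross-validation of full versus handicapped Cox models
#'
#' Per repetition: draw `n_sample` subjects from the cohort without
#' replacement, split them into a training and a test set, fit the full
#' Cox model and each handicapped model (the same variable set minus one
#' variable, refit from scratch) on the same training set, and score the
#' same test set by hold-out Harrell's concordance. Results are paired by
#' repetition: every model variant sees identical partitions. The master
#' seed spawns one sub-seed per repetition, so any repetition is
#' reproducible in isolation and the whole run is deterministic.
#'
#' A repetition in which a variant's fit fails, does not converge, or whose
#' test set has no comparable pairs is recorded as failed for that variant
#' (NA concordance) and excluded from summaries, with counts reported.
#'
#' @param cohort annotated cohort containing the model covariates, `time`
#'   and `status`.
#' @param config an [mccv_config()].
#' @param train_c also record training-set concordance (used for optimism
#'   diagnostics; off by default since it costs an extra O(n_train^2) pass
#'   per variant and repetition).
#' @return Object of class `mccv_result`: list with `c_index` (n_reps x
#'   n_variants matrix, columns `full`, `minus_<var>`), `train_c`
#'   (training-set concordance, same shape, NA unless requested),
#'   `failures` (per-variant counts), `partitions` (per-rep train/test row
#'   indices), and `config`.
#' @export
run_mccv <- function(cohort, config = mccv_config(), train_c = FALSE) {
  stopifnot(inherits(config, "mccv_config"))
  need <- c(config$model_covariates, "time", "status")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  use <- stats::complete.cases(cohort[, need])
  dat <- cohort[use, , drop = FALSE]
  if (nrow(dat) < config$n_sample)
    stop("cohort has ", nrow(dat), " complete rows; n_sample = ",
         config$n_sample, call. = FALSE)

  design <- build_design(dat, config$model_covariates)
  var_cols <- attr(design, "var_cols")
  variants <- c("full", paste0("minus_", config$handicaps))
  keep_cols <- c(list(full = seq_len(ncol(design))),
                 lapply(config$handicaps,
                        function(v) setdiff(seq_len(ncol(design)),
                                            var_cols[[v]])))
  names(keep_cols) <- variants

  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, config$n_reps)
  cmat <- matrix(NA_real_, config$n_reps, length(variants),
                 dimnames = list(NULL, variants))
  tmat <- cmat
  partitions <- vector("list", config$n_reps)
  for (r in seq_len(config$n_reps)) {
    set.seed(rep_seeds[r])
    idx <- sample.int(nrow(dat), config$n_sample)
    tr <- idx[seq_len(config$n_train)]
    te <- idx[(config$n_train + 1):config$n_sample]
    partitions[[r]] <- list(train = tr, test = te)
    for (v in variants) {
      cols <- keep_cols[[v]]
      res <- tryCatch({
        fit <- fit_cox(design[tr, cols, drop = FALSE], dat$time[tr],
                       dat$status[tr], ties = config$ties)
        if (!fit$converged) stop("fit did not converge")
        sc_te <- predict_risk(fit, design[te, cols, drop = FALSE])
        ctr <- if (train_c) {
          sc_tr <- predict_risk(fit, design[tr, cols, drop = FALSE])
          harrell_c(sc_tr, dat$time[tr], dat$status[tr])$c_index
        } else NA_real_
        c(test = harrell_c(sc_te, dat$time[te], dat$status[te])$c_index,
          train = ctr)
      }, error = function(e) NULL)
      if (!is.null(res)) {
        cmat[r, v] <- res["test"]
        tmat[r, v] <- res["train"]
      }
    }
  }
  failures <- colSums(is.na(cmat))
  structure(list(c_index = cmat, train_c = tmat, failures = failures,
                 partitions = partitions, config = config),
            class = "mccv_result")
}

#' @export
print.mccv_result <- function(x, ...) {
  cat(sprintf("MCCV: %d reps of %d/%d train/test from samples of %d\n",
              x$config$n_reps, x$config$n_train, x$config$n_test,
              x$config$n_sample))
  print(round(rbind(mean_c = colMeans(x$c_index, na.rm = TRUE),
                    sd_c = apply(x$c_index, 2, stats::sd, na.rm = TRUE),
                    failed = x$failures), 4))
  invisible(x)
}

#' Compare full and handicapped concordance distributions
#'
#' Computes (1) a one-way ANOVA across all model variants on the per-rep
#' hold-out concordance values, (2) for each handicapped variant a paired
#' contrast against the full model on the per-repetition differences (the
#' partitions are shared, so differences are paired by construction), and
#' (3) a Bayesian estimate of each paired mean difference with the
#' posterior mass inside the region of practical equivalence |d| < `rope`
#' (see [rope_posterior()]). The omnibus ANOVA and the paired contrasts are
#' both reported and labelled distinctly: MCCV repetitions share subjects,
#' so the nominal p-values are approximate.
#'
#' @param mccv an [run_mccv()] result (or any object with a `c_index`
#'   matrix whose first column group is the full model).
#' @param rope ROPE half-width on the concordance-difference scale.
#' @param full name of the reference (full) column.
#' @return Object of class `mccv_comparison`: list with `anova_p`, `table`
#'   (per-handicap data.frame: `model`, `mean_difference`, `pairwise_p`,
#'   `rope_mass`, `post_mean`, `hdi_low`, `hdi_high`, `n_pairs`), `rope`,
#'   and `posteriors`.
#' @export
compare_models <- function(mccv, rope = 0.01, full = "full") {
  cmat <- if (inherits(mccv, "mccv_result")) mccv$c_index else as.matrix(mccv)
  if (!full %in% colnames(cmat))
    stop("no '", full, "' column in the concordance matrix", call. = FALSE)
  if (nrow(cmat) < 2)
    stop("paired comparison needs at least two repetitions", call. = FALSE)
  long <- data.frame(
    c_index = as.vector(cmat),
    model = factor(rep(colnames(cmat), each = nrow(cmat)),
                   levels = colnames(cmat)))
  long <- long[!is.na(long$c_index), ]
  long$model <- droplevels(long$model)
  anova_p <- if (nlevels(long$model) >= 2) {
    summary(stats::aov(c_index ~ model, data = long))[[1]][["Pr(>F)"]][1]
  } else NA_real_  # all but one variant failed every repetition

  others <- setdiff(colnames(cmat), full)
  posteriors <- list()
  rows <- lapply(others, function(v) {
    d <- cmat[, full] - cmat[, v]
    d <- d[!is.na(d)]
    if (length(d) < 2) {
      warning("variant '", v, "' has ", length(d),
              " paired repetitions; contrast unavailable", call. = FALSE)
      return(data.frame(model = v, mean_difference = NA_real_,
                        pairwise_p = NA_real_, rope_mass = NA_real_,
                        post_mean = NA_real_, hdi_low = NA_real_,
                        hdi_high = NA_real_, n_pairs = length(d),
                        stringsAsFactors = FALSE))
    }
    post <- rope_posterior(d, rope = rope)
    posteriors[[v]] <<- post
    # constant differences break the t machinery; the p-value is then 0/1
    p_pair <- if (stats::sd(d) == 0) as.numeric(mean(d) == 0)
              else stats::t.test(d)$p.value
    data.frame(model = v, mean_difference = mean(d),
               pairwise_p = p_pair,
               rope_mass = post$rope_mass, post_mean = post$mean,
               hdi_low = post$hdi[1], hdi_high = post$hdi[2],
               n_pairs = length(d), stringsAsFactors = FALSE)
  })
  structure(list(anova_p = anova_p, table = do.call(rbind, rows),
                 rope = rope, posteriors = posteriors),
            class = "mccv_comparison")
}

#' @export
print.mccv_comparison <- function(x, ...) {
  cat(sprintf("Omnibus ANOVA across variants: p = %.4g (approximate; reps share subjects)\n",
              x$anova_p))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], function(z) signif(z, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' PVR bins used for subgroup analyses
#'
#' Four bins with the boundaries assigned to the lower bin at 2 and 3 Wood
#' units and the top bin open above 5: (-Inf, 2], (2, 3], (3, 5],
#' (5, Inf).
#'
#' @param pvr numeric vector of PVR values (Wood units).
#' @return factor with levels `<=2`, `2-3`, `3-5`, `>5`.
#' @export
pvr_bins <- function(pvr) {
  cut(pvr, breaks = c(-Inf, 2, 3, 5, Inf),
      labels = c("<=2", "2-3", "3-5", ">5"), right = TRUE)
}

#' Monte Carlo cross-validation within subgroups
#'
#' Runs [run_mccv()] and [compare_models()] within each stratum of either
#' the PH classification (NO_PH, PRECAP, IPCPH, CPCPH) or the PVR bins
#' ([pvr_bins()]). When a stratum is smaller than `n_sample`, the sampling
#' scheme shrinks proportionally: `n_sample` becomes five-sixths of the
#' stratum size rounded down to a multiple of four, split 3:1 into train
#' and test (e.g. a stratum of 120 rows gives 100 sampled, 75/25), and the
#' shrink is reported. Strata smaller than `min_stratum` rows are skipped
#' with a message. Rows with a missing stratifier are counted separately.
#'
#' @param cohort annotated cohort (needs `ph_class` or `pvr`).
#' @param config an [mccv_config()].
#' @param stratifier `"ph"` or `"pvr"`.
#' @param rope ROPE half-width passed to [compare_models()].
#' @param min_stratum smallest stratum analysed.
#' @return Named list per stratum: `mccv`, `comparison`, `n_stratum`,
#'   `config_used`, `shrunk`; attributes `"skipped"` and `"n_missing"`.
#' @export
subgroup_mccv <- function(cohort, config = mccv_config(),
                          stratifier = c("ph", "pvr"), rope = 0.01,
                          min_stratum = 40L) {
  stratifier <- match.arg(stratifier)
  strata <- if (stratifier == "ph") {
    f <- cohort$ph_class
    factor(f, levels = c("NO_PH", "PRECAP", "IPCPH", "CPCPH"))
  } else {
    pvr_bins(cohort$pvr)
  }
  n_missing <- sum(is.na(strata))
  out <- list()
  skipped <- character(0)
  for (lev in levels(strata)) {
    rows <- which(!is.na(strata) & strata == lev)
    if (length(rows) < min_stratum) {
      message("stratum '", lev, "' has ", length(rows),
              " rows (< ", min_stratum, "); skipped")
      skipped <- c(skipped, lev)
      next
    }
    cfg <- config
    shrunk <- FALSE
    if (length(rows) < config$n_sample) {
      ns <- (floor(length(rows) * 5 / 6) %/% 4L) * 4L
      cfg <- mccv_config(n_sample = ns, n_train = (ns * 3L) %/% 4L,
                         n_reps = config$n_reps, seed = config$seed,
                         model_covariates = config$model_covariates,
                         handicaps = config$handicaps, ties = config$ties)
      shrunk <- TRUE
      message("stratum '", lev, "': n_sample shrunk to ", ns,
              " (", cfg$n_train, "/", cfg$n_test, " train/test)")
    }
    mc <- run_mccv(cohort[rows, , drop = FALSE], cfg)
    out[[lev]] <- list(mccv = mc, comparison = compare_models(mc, rope = rope),
                       n_stratum = length(rows), config_used = cfg,
                       shrunk = shrunk)
  }
  attr(out, "skipped") <- skipped
  attr(out, "n_missing") <- n_missing
  out
}
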