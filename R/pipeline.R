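#' Read a pipeline run configuration
#'
#' A run configuration is a YAML (or JSON) document with fields:
#' \describe{
#'   \item{seed}{integer master seed.}
#'   \item{outdir}{output directory; each invocation creates one
#'     timestamped run directory inside it, never overwriting in place.}
#'   \item{stages}{subset of `generate`, `qc`, `associate`, `predict`.}
#'   \item{input}{path to an existing cohort table (omit when the
#'     `generate` stage is enabled).}
#'   \item{column_map}{optional named mapping of file columns to the
#'     documented names.}
#'   \item{generator}{arguments for [generator_config()] (e.g. `n`,
#'     `coefficients`).}
#'   \item{association}{arguments for the association stage (`threshold`,
#'     `subgroups`, `body_size`).}
#'   \item{mccv}{arguments for [mccv_config()] plus optional `rope`.}
#' }
#'
#' Note: YAML 1.1 reads bare `n`, `y`, `yes`, `no` keys as booleans; quote
#' such keys (`"n": 5000`) in YAML configs.
#'
#' @param path file path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (grepl("[.]json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

# stable hash of a config list: md5 of its canonical JSON serialization
config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                           digits = NA)), f)
  unname(tools::md5sum(f))
}

.coerce_coefficients <- function(x) {
  lapply(x, function(term) {
    term$beta <- as.numeric(term$beta)
    if (!is.null(term$threshold)) term$threshold <- as.numeric(term$threshold)
    term
  })
}

#' Run the analysis pipeline
#'
#' Orchestrates generate -> qc/classify -> associate -> predict as one
#' reproducible run. Enabled stages execute in order; every artifact is
#' written into a fresh timestamped run directory together with a
#' provenance sidecar (`provenance.json`) carrying the config, its hash,
#' the seeds, and consort-style per-stage row counts. Any stage error halts
#' the run with a stage-named message; artifacts already written are
#' retained.
#'
#' @param config a list as returned by [read_run_config()], or a path to a
#'   config file.
#' @param seed optional override of `config$seed`.
#' @param outdir optional override of `config$outdir`.
#' @return The run directory path, invisibly; the provenance list as
#'   attribute `"provenance"`.
#' @export
run_pipeline <- function(config, seed = NULL, outdir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- read_run_config(config)
  }
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!is.null(outdir)) config$outdir <- outdir
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$stages)) config$stages <- c("generate", "qc")
  bad <- setdiff(config$stages, c("generate", "qc", "associate", "predict"))
  if (length(bad))
    stop("[config] unknown stage(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(config$outdir)) config$outdir <- "."
  run_dir <- file.path(config$outdir,
                       paste0("run_", format(Sys.time(), "%Y%m%d_%H%M%S"),
                              "_", config$seed))
  i <- 0
  while (dir.exists(run_dir)) {
    i <- i + 1
    run_dir <- paste0(run_dir, letters[i])
  }
  dir.create(run_dir, recursive = TRUE)
  hash <- config_hash(config)
  prov <- list(config = config, config_hash = hash, stages_run = character(0),
               row_counts = list())
  write_prov <- function() {
    jsonlite::write_json(prov, file.path(run_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      write_prov()
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  cohort <- NULL
  if ("generate" %in% config$stages) {
    cohort <- stage("generate", {
      gargs <- config$generator
      if (!is.null(gargs$coefficients))
        gargs$coefficients <- .coerce_coefficients(gargs$coefficients)
      gargs$seed <- config$seed
      gcfg <- do.call(generator_config, gargs)
      co <- generate_cohort(gcfg)
      gt <- co[, intersect(c("pac_true", "rc_time", "lp_true"), names(co))]
      write_cohort(co[, setdiff(names(co), names(gt))],
                   file.path(run_dir, "cohort.csv"))
      write_cohort(gt, file.path(run_dir, "ground_truth.csv"))
      prov$row_counts$generate <- nrow(co)
      co
    })
    prov$stages_run <- c(prov$stages_run, "generate")
  } else if (!is.null(config$input)) {
    cohort <- stage("load", {
      co <- read_cohort(config$input, column_map = config$column_map)
      required <- c("hr", "spap", "dpap", "mpap", "pawp", "co",
                    "time", "status")
      miss <- setdiff(required, names(co))
      if (length(miss))
        stop("input cohort is missing mapped column(s): ",
             paste(miss, collapse = ", "))
      prov$row_counts$input <- nrow(co)
      co
    })
  }

  if ("qc" %in% config$stages) {
    cohort <- stage("qc", {
      if (is.null(cohort)) stop("no cohort: enable 'generate' or set input")
      excl <- apply_exclusions(cohort)
      utils::write.csv(excl$audit, file.path(run_dir, "exclusion_audit.csv"),
                       row.names = FALSE)
      co <- annotate_cohort(excl$cohort)
      write_cohort(co, file.path(run_dir, "cohort_annotated.csv"))
      prov$row_counts$qc_in <- nrow(cohort)
      prov$row_counts$qc_out <- nrow(co)
      co
    })
    prov$stages_run <- c(prov$stages_run, "qc")
  }

  if ("associate" %in% config$stages) {
    stage("associate", {
      if (is.null(cohort)) stop("no cohort available")
      if (!"pac" %in% names(cohort)) cohort <- annotate_cohort(cohort)
      aargs <- config$association
      covs <- association_covariates(
        if (is.null(aargs$body_size)) "bmi" else aargs$body_size)
      curve <- spline_hr_curve(cohort, adjusted = TRUE, covariates = covs)
      utils::write.csv(curve, file.path(run_dir, "spline_hr_curve.csv"),
                       row.names = FALSE)
      subs <- if (is.null(aargs$subgroups)) subgroup_filters()
              else aargs$subgroups
      thr <- if (is.null(aargs$threshold)) 3 else aargs$threshold
      hrs <- do.call(rbind, lapply(subs, function(s)
        dichotomized_hr(cohort, threshold = thr, subgroup = s,
                        covariates = covs)))
      utils::write.csv(hrs, file.path(run_dir, "hr_table.csv"),
                       row.names = FALSE)
      prov$row_counts$associate <- nrow(cohort)
    })
    prov$stages_run <- c(prov$stages_run, "associate")
  }

  if ("predict" %in% config$stages) {
    stage("predict", {
      if (is.null(cohort)) stop("no cohort available")
      if (!"pac" %in% names(cohort)) cohort <- annotate_cohort(cohort)
      margs <- config$mccv
      rope <- if (is.null(margs$rope)) 0.01 else margs$rope
      margs$rope <- NULL
      if (is.null(margs$seed)) margs$seed <- config$seed
      mcfg <- do.call(mccv_config, margs)
      mc <- run_mccv(cohort, mcfg)
      long <- data.frame(
        rep = rep(seq_len(nrow(mc$c_index)), ncol(mc$c_index)),
        model_label = rep(colnames(mc$c_index), each = nrow(mc$c_index)),
        c_index = as.vector(mc$c_index))
      utils::write.csv(long, file.path(run_dir, "cindex_long.csv"),
                       row.names = FALSE)
      cmp <- compare_models(mc, rope = rope)
      tab <- cmp$table
      tab$anova_p <- cmp$anova_p
      utils::write.csv(tab, file.path(run_dir, "comparison.csv"),
                       row.names = FALSE)
      prov$row_counts$predict <- nrow(cohort)
      prov$mccv_failures <- as.list(mc$failures)
    })
    prov$stages_run <- c(prov$stages_run, "predict")
  }

  write_prov()
  structure(invisible(run_dir), provenance = prov)
}
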