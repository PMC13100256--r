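#' Default adjustment covariates for the association analysis
#'
#' Age, gender, race, a body-size term, the Charlson Comorbidity Index, and
#' the three comorbidity indicators. The body-size term defaults to BMI;
#' body surface area (`"bsa"`) may be substituted.
#'
#' @param body_size `"bmi"` or `"bsa"`.
#' @export
association_covariates <- function(body_size = c("bmi", "bsa")) {
  body_size <- match.arg(body_size)
  c("age", "gender", "race", body_size, "cci", "afib", "osa", "htn")
}

# expand covariates (factors to treatment-coded dummies) into a numeric
# design matrix; returns the matrix with an attribute mapping variable ->
# column indices so model variants can drop whole variables
build_design <- function(cohort, vars) {
  miss <- setdiff(vars, names(cohort))
  if (length(miss))
    stop("cohort is missing covariate column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df <- cohort[, vars, drop = FALSE]
  mm <- stats::model.matrix(~ ., data = df)
  assign <- attr(mm, "assign")
  mm <- mm[, -1, drop = FALSE]
  assign <- assign[-1]
  var_cols <- lapply(seq_along(vars), function(i) which(assign == i))
  names(var_cols) <- vars
  attr(mm, "var_cols") <- var_cols
  mm
}

#' Spline hazard-ratio curve for PAC
#'
#' Fits a Cox model with a 4-knot linear tail-restricted cubic spline in
#' PAC (optionally adjusted for the standard covariates) and returns the
#' hazard-ratio curve relative to the reference PAC, with a pointwise 95%
#' delta-method band. The curve is the exponentiated spline contrast
#' against the reference, so the adjustment covariates — held at any fixed
#' reference level — cancel exactly and `hr` is identically 1 at the
#' reference, with a zero-width band there.
#'
#' @param cohort annotated cohort (needs `pac`, `time`, `status`, and the
#'   adjustment covariates when `adjusted = TRUE`).
#' @param adjusted adjust for [association_covariates()]?
#' @param spec a [rcs_spec()]; default places knots at the conventional
#'   quantiles of observed PAC with reference 3 mL/mmHg.
#' @param grid PAC values at which to evaluate the curve; default 100
#'   points across the 1st-99th percentile range.
#' @param covariates adjustment covariate names.
#' @param ties tie-handling for the Cox fit.
#' @return data.frame (`pac`, `hr`, `ci_low`, `ci_high`) with attributes
#'   `adjusted`, `reference`, `knots`, and `fit`.
#' @export
spline_hr_curve <- function(cohort, adjusted = TRUE, spec = NULL, grid = NULL,
                            covariates = association_covariates(),
                            ties = "efron") {
  use <- stats::complete.cases(cohort[, c("pac", "time", "status",
                                          if (adjusted) covariates)])
  dat <- cohort[use, , drop = FALSE]
  if (is.null(spec)) spec <- rcs_spec(reference = 3, x = dat$pac)
  if (spec$reference < min(dat$pac) || spec$reference > max(dat$pac))
    stop("reference PAC ", spec$reference,
         " lies outside the observed PAC range", call. = FALSE)
  basis <- rcs_basis(dat$pac, spec)
  colnames(basis) <- paste0("pac_", colnames(basis))
  x <- basis
  if (adjusted) x <- cbind(basis, build_design(dat, covariates))
  fit <- fit_cox(x, dat$time, dat$status, ties = ties)
  if (is.null(grid)) {
    q <- stats::quantile(dat$pac, c(0.01, 0.99))
    grid <- seq(q[1], q[2], length.out = 100)
  }
  spl_cols <- seq_len(ncol(basis))
  bg <- rcs_basis(grid, spec)
  bref <- rcs_basis(spec$reference, spec)
  contrast <- sweep(bg, 2, drop(bref))
  beta <- fit$coefficients[spl_cols]
  sigma <- fit$covariance[spl_cols, spl_cols, drop = FALSE]
  log_hr <- drop(contrast %*% beta)
  se <- sqrt(rowSums((contrast %*% sigma) * contrast))
  out <- data.frame(pac = grid, hr = exp(log_hr),
                    ci_low = exp(log_hr - 1.96 * se),
                    ci_high = exp(log_hr + 1.96 * se))
  attr(out, "adjusted") <- adjusted
  attr(out, "reference") <- spec$reference
  attr(out, "knots") <- spec$knots
  attr(out, "fit") <- fit
  out
}

#' Subgroup filters for the dichotomized PAC analysis
#'
#' The documented subgroup set: none, wedge pressure at or below / above 15
#' mmHg, and pulmonary vascular resistance at or below / above 2.2 Wood
#' units.
#' @export
subgroup_filters <- function() {
  c("none", "pawp_low", "pawp_high", "pvr_low", "pvr_high")
}

.subgroup_keep <- function(cohort, subgroup) {
  switch(subgroup,
    none = rep(TRUE, nrow(cohort)),
    pawp_low = cohort$pawp <= 15,
    pawp_high = cohort$pawp > 15,
    pvr_low = cohort$pvr <= 2.2,
    pvr_high = cohort$pvr > 2.2)
}

#' Adjusted hazard ratio for dichotomized PAC
#'
#' Dichotomizes PAC at `threshold` (low = PAC strictly below the threshold,
#' so the boundary value falls in the high group) and fits an adjusted Cox
#' model for the indicator within an optional hemodynamic subgroup. The
#' orientation is configurable and labelled: `"low_vs_high"` reports the
#' hazard in low relative to high PAC; `"high_vs_low"` its exact
#' reciprocal.
#'
#' @param cohort annotated cohort.
#' @param threshold PAC cut point, mL/mmHg.
#' @param subgroup one of [subgroup_filters()].
#' @param orientation `"low_vs_high"` or `"high_vs_low"`.
#' @param covariates adjustment covariate names.
#' @param ties tie-handling for the Cox fit.
#' @return One-row data.frame: `subgroup_label`, `orientation`, `hr`,
#'   `ci_low`, `ci_high`, `p_value`, `n`, `n_events`; attribute `"fit"`.
#' @export
dichotomized_hr <- function(cohort, threshold = 3,
                            subgroup = "none",
                            orientation = c("low_vs_high", "high_vs_low"),
                            covariates = association_covariates(),
                            ties = "efron") {
  orientation <- match.arg(orientation)
  subgroup <- match.arg(subgroup, subgroup_filters())
  keep <- .subgroup_keep(cohort, subgroup)
  keep[is.na(keep)] <- FALSE
  dat <- cohort[keep, , drop = FALSE]
  use <- stats::complete.cases(dat[, c("pac", "time", "status", covariates)])
  dat <- dat[use, , drop = FALSE]
  low <- as.numeric(dat$pac < threshold)
  ev_low <- sum(dat$status[low == 1])
  ev_high <- sum(dat$status[low == 0])
  if (ev_low < 2 || ev_high < 2)
    stop("subgroup '", subgroup, "' has fewer than 2 events in a PAC arm ",
         "(low: ", ev_low, ", high: ", ev_high, "); estimate declined",
         call. = FALSE)
  ind <- if (orientation == "low_vs_high") low else 1 - low
  x <- cbind(pac_ind = ind, build_design(dat, covariates))
  fit <- fit_cox(x, dat$time, dat$status, ties = ties)
  s <- cox_summary(fit)[1, ]
  out <- data.frame(subgroup_label = subgroup, orientation = orientation,
                    hr = s$hr, ci_low = s$ci_low, ci_high = s$ci_high,
                    p_value = s$p_value, n = nrow(dat),
                    n_events = sum(dat$status), stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  out
}

#' Sensitivity analysis restricted to pulmonary hypertension
#'
#' Re-runs the association analyses on the subset with PH (mPAP > 20 mmHg,
#' i.e. exactly the rows not labelled `NO_PH`), labelling the results.
#'
#' @param cohort annotated cohort (needs `mpap`).
#' @param threshold PAC cut point for the dichotomized analysis.
#' @param subgroups which subgroup HRs to compute.
#' @param ... passed to [spline_hr_curve()] and [dichotomized_hr()].
#' @return list with `curve`, `hr_table`, and `n` (subset size).
#' @export
ph_only_sensitivity <- function(cohort, threshold = 3,
                                subgroups = "none", ...) {
  sub <- cohort[!is.na(cohort$mpap) & cohort$mpap > 20, , drop = FALSE]
  if (nrow(sub) == 0)
    stop("PH subset is empty (no rows with mPAP > 20)", call. = FALSE)
  curve <- spline_hr_curve(sub, ...)
  hrs <- do.call(rbind, lapply(subgroups, function(s)
    dichotomized_hr(sub, threshold = threshold, subgroup = s, ...)))
  hrs$analysis <- "ph_only"
  list(curve = curve, hr_table = hrs, n = nrow(sub))
}
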