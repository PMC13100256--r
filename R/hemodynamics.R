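#' Derive calculated hemodynamic variables from a right-heart-catheterization
#' measurement
#'
#' Computes the five standard derived quantities from directly measured
#' pressures and flows: pulmonary pulse pressure (PP = sPAP - dPAP),
#' transpulmonary gradient (TPG = mPAP - PAWP), pulmonary vascular resistance
#' (PVR = TPG / CO, Wood units), stroke volume (SV = 1000 * CO / HR, mL), and
#' pulmonary artery compliance (PAC = SV / PP, mL/mmHg).
#'
#' Inputs may be vectors (one element per patient). `dpap <= mpap <= spap` is
#' deliberately not assumed: real catheterization data violate it, and QC
#' ([check_physiologic]) flags rather than repairs such records. When the
#' pulse pressure is nonpositive, PAC is undefined for that record: `pac` is
#' `NA` and `pac_defined` is `FALSE`, while the remaining derived fields are
#' still returned.
#'
#' @param hr heart rate, beats/min; must be positive.
#' @param spap,dpap,mpap systolic / diastolic / mean pulmonary artery
#'   pressure, mmHg.
#' @param pawp pulmonary artery wedge pressure, mmHg.
#' @param co cardiac output, L/min; must be positive.
#' @return A data.frame with columns `pp`, `tpg`, `pvr`, `sv`, `pac`
#'   and logical `pac_defined`.
#' @examples
#' derive_hemodynamics(hr = 80, spap = 48, dpap = 18, mpap = 28,
#'                     pawp = 13, co = 6)
#' @export
derive_hemodynamics <- function(hr, spap, dpap, mpap, pawp, co) {
  n <- max(length(hr), length(spap), length(dpap), length(mpap),
           length(pawp), length(co))
  hr <- rep_len(hr, n); spap <- rep_len(spap, n); dpap <- rep_len(dpap, n)
  mpap <- rep_len(mpap, n); pawp <- rep_len(pawp, n); co <- rep_len(co, n)
  if (any(!is.na(hr) & hr <= 0))
    stop("heart rate must be positive", call. = FALSE)
  if (any(!is.na(co) & co <= 0))
    stop("cardiac output must be positive", call. = FALSE)
  pp  <- spap - dpap
  tpg <- mpap - pawp
  pvr <- tpg / co
  sv  <- 1000 * co / hr
  pac_defined <- !is.na(pp) & pp > 0
  pac <- ifelse(pac_defined, sv / pp, NA_real_)
  data.frame(pp = pp, tpg = tpg, pvr = pvr, sv = sv, pac = pac,
             pac_defined = pac_defined)
}

#' Physiologic-range quality control reason codes
#'
#' The enumerated QC reason codes, in the documented order of application
#' used when a record fails for more than one reason (first applicable
#' reason wins in exclusion audits): age, date errors, prior transplant or
#' ventricular assist device, then the hemodynamic ranges.
#' @export
qc_reason_codes <- function() {
  c("AGE_RANGE", "DATE_ERROR", "PRIOR_TX_VAD",
    "CO_RANGE", "MPAP_RANGE", "DPAP_RANGE", "SPAP_RANGE",
    "PAWP_RANGE", "HR_RANGE", "NONPOSITIVE_PP")
}

# Strict (open) physiologic bounds: a value passes iff it is neither
# strictly below the lower bound nor strictly above the upper bound.
.qc_bounds <- list(
  CO_RANGE   = list(var = "co",   lo = 0.5, hi = 15),
  MPAP_RANGE = list(var = "mpap", lo = 5,   hi = 80),
  DPAP_RANGE = list(var = "dpap", lo = 0,   hi = 70),
  SPAP_RANGE = list(var = "spap", lo = 7,   hi = 130),
  PAWP_RANGE = list(var = "pawp", lo = 0,   hi = 60),
  HR_RANGE   = list(var = "hr",   lo = 10,  hi = 200),
  AGE_RANGE  = list(var = "age",  lo = 18,  hi = 90)
)

#' Check physiologic plausibility of a measurement
#'
#' Applies the study's strict-inequality range checks: cardiac output < 0.5
#' or > 15 L/min; mPAP < 5 or > 80 mmHg; dPAP < 0 or > 70 mmHg; sPAP < 7 or
#' > 130 mmHg; PAWP < 0 or > 60 mmHg; heart rate < 10 or > 200 bpm; and age
#' under 18 or over 90 years. Boundary values pass (e.g. mPAP = 80 survives
#' the strict "> 80" rule). Missing fields yield no range code for that
#' field; QC reports, it never raises.
#'
#' @inheritParams derive_hemodynamics
#' @param age age at catheterization, years.
#' @return A data.frame with logical `passed` and a character
#'   `reason_codes` column (codes joined by `";"`, `""` when passed); the
#'   attribute `"codes"` carries the per-record code list.
#' @export
check_physiologic <- function(hr = NA, spap = NA, dpap = NA, mpap = NA,
                              pawp = NA, co = NA, age = NA) {
  vals <- list(hr = hr, spap = spap, dpap = dpap, mpap = mpap,
               pawp = pawp, co = co, age = age)
  n <- max(vapply(vals, length, 1L))
  vals <- lapply(vals, rep_len, n)
  codes <- rep(list(character(0)), n)
  for (code in names(.qc_bounds)) {
    b <- .qc_bounds[[code]]
    x <- vals[[b$var]]
    bad <- !is.na(x) & (x < b$lo | x > b$hi)
    for (i in which(bad)) codes[[i]] <- c(codes[[i]], code)
  }
  joined <- vapply(codes, paste, "", collapse = ";")
  out <- data.frame(passed = joined == "", reason_codes = joined,
                    stringsAsFactors = FALSE)
  attr(out, "codes") <- codes
  out
}

#' Hemodynamic pulmonary hypertension classification (2022 ESC/ERS rules)
#'
#' Classifies each record from its mean pulmonary artery pressure, wedge
#' pressure and pulmonary vascular resistance:
#' \describe{
#'   \item{NO_PH}{mPAP <= 20 mmHg}
#'   \item{PRECAP}{mPAP > 20, PAWP <= 15 mmHg, PVR > 2 WU (pre-capillary PH)}
#'   \item{IPCPH}{mPAP > 20, PAWP > 15 mmHg, PVR <= 2 WU (isolated
#'     post-capillary PH)}
#'   \item{CPCPH}{mPAP > 20, PAWP > 15 mmHg, PVR > 2 WU (combined post- and
#'     pre-capillary PH)}
#'   \item{UNDETERMINED}{mPAP > 20 but no named subgroup applies, e.g.
#'     mPAP > 20, PAWP <= 15 and PVR <= 2 WU}
#' }
#' The five labels partition the space of complete (mPAP, PAWP, PVR)
#' triples: every record maps to exactly one label.
#'
#' @param mpap,pawp,pvr mean PA pressure (mmHg), wedge pressure (mmHg),
#'   pulmonary vascular resistance (Wood units). All must be present and
#'   finite; missing values raise an error identifying the offending rows
#'   (records are reported, never silently dropped).
#' @return A factor with levels `NO_PH`, `PRECAP`, `IPCPH`, `CPCPH`,
#'   `UNDETERMINED`.
#' @examples
#' classify_ph(25, 10, 1.5)  # UNDETERMINED
#' classify_ph(25, 18, 3.0)  # CPCPH
#' @export
classify_ph <- function(mpap, pawp, pvr) {
  n <- max(length(mpap), length(pawp), length(pvr))
  mpap <- rep_len(mpap, n); pawp <- rep_len(pawp, n); pvr <- rep_len(pvr, n)
  bad <- !is.finite(mpap) | !is.finite(pawp) | !is.finite(pvr)
  if (any(bad))
    stop("classification requires complete (mpap, pawp, pvr); missing in rows: ",
         paste(utils::head(which(bad), 10), collapse = ", "), call. = FALSE)
  lab <- ifelse(mpap <= 20, "NO_PH",
         ifelse(pawp <= 15 & pvr > 2,  "PRECAP",
         ifelse(pawp > 15  & pvr <= 2, "IPCPH",
         ifelse(pawp > 15  & pvr > 2,  "CPCPH", "UNDETERMINED"))))
  factor(lab, levels = ph_levels())
}

#' @rdname classify_ph
#' @export
ph_levels <- function() c("NO_PH", "PRECAP", "IPCPH", "CPCPH", "UNDETERMINED")

#' Apply cohort exclusions with a consort-style audit
#'
#' Filters a cohort table on QC and administrative criteria and returns
#' per-reason exclusion counts. A row failing several criteria is counted
#' once, under the first applicable reason in the documented order: age
#' range, date error, prior transplant/VAD, then the hemodynamic ranges in
#' the order of [qc_reason_codes()].
#'
#' @param cohort a data.frame with the measurement columns (`hr`, `spap`,
#'   `dpap`, `mpap`, `pawp`, `co`), `age`, and optionally logical
#'   `date_error` and `prior_tx_vad` flags.
#' @return A list with `cohort` (retained rows), `audit` (a data.frame of
#'   reason/count, all reasons listed, zeros included), and `order` (the
#'   reason order applied).
#' @export
apply_exclusions <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  n <- nrow(cohort)
  get <- function(col, default) {
    if (col %in% names(cohort)) cohort[[col]] else rep(default, n)
  }
  qc <- check_physiologic(hr = get("hr", NA), spap = get("spap", NA),
                          dpap = get("dpap", NA), mpap = get("mpap", NA),
                          pawp = get("pawp", NA), co = get("co", NA),
                          age = get("age", NA))
  codes <- attr(qc, "codes")
  date_err <- as.logical(get("date_error", FALSE))
  tx_vad <- as.logical(get("prior_tx_vad", FALSE))
  date_err[is.na(date_err)] <- FALSE
  tx_vad[is.na(tx_vad)] <- FALSE

  order_codes <- qc_reason_codes()
  first_reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    hit <- character(0)
    if ("AGE_RANGE" %in% codes[[i]]) hit <- c(hit, "AGE_RANGE")
    if (date_err[i]) hit <- c(hit, "DATE_ERROR")
    if (tx_vad[i]) hit <- c(hit, "PRIOR_TX_VAD")
    hit <- c(hit, setdiff(codes[[i]], "AGE_RANGE"))
    if (length(hit))
      first_reason[i] <- order_codes[min(match(hit, order_codes))]
  }
  keep <- is.na(first_reason)
  if (!any(keep))
    stop("all rows excluded; downstream stages need data", call. = FALSE)
  counts <- table(factor(first_reason, levels = order_codes))
  audit <- data.frame(reason = order_codes, n_excluded = as.integer(counts),
                      stringsAsFactors = FALSE)
  list(cohort = cohort[keep, , drop = FALSE], audit = audit,
       order = order_codes)
}

#' Read or write a cohort table
#'
#' Thin delimited-text interface for cohort tables: a header row, documented
#' column names (`age`, `gender`, `race`, `bmi`, `bsa`, `cci`, `afib`,
#' `osa`, `htn`, `hr`, `spap`, `dpap`, `mpap`, `pawp`, `rap`, `co`, `time`,
#' `status`), configurable delimiter, empty fields as missing.
#'
#' @param path file path.
#' @param sep field delimiter (default comma).
#' @param column_map optional named character vector mapping file column
#'   names to the documented names, e.g. `c(heart_rate = "hr")`.
#' @return `read_cohort`: a data.frame.
#' @export
read_cohort <- function(path, sep = ",", column_map = NULL) {
  x <- utils::read.table(path, header = TRUE, sep = sep, na.strings = c("", "NA"),
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    idx <- match(names(column_map), names(x))
    if (anyNA(idx))
      stop("column_map refers to absent columns: ",
           paste(names(column_map)[is.na(idx)], collapse = ", "), call. = FALSE)
    names(x)[idx] <- unname(column_map)
  }
  x
}

#' @rdname read_cohort
#' @param cohort a data.frame to write.
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  utils::write.table(cohort, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Append derived hemodynamics, QC and PH class to a cohort table
#'
#' Convenience wrapper running [derive_hemodynamics()],
#' [check_physiologic()] and [classify_ph()] over a cohort table and
#' appending the results as columns. Records with incomplete
#' (mPAP, PAWP, PVR) get an `NA` PH class and are counted in the returned
#' attribute `"n_unclassified"` rather than raising.
#'
#' @param cohort a data.frame with measurement columns and `age`.
#' @return The cohort with appended columns `pp`, `tpg`, `pvr`, `sv`,
#'   `pac`, `pac_defined`, `qc_pass`, `qc_codes`, `ph_class`.
#' @export
annotate_cohort <- function(cohort) {
  d <- derive_hemodynamics(cohort$hr, cohort$spap, cohort$dpap, cohort$mpap,
                           cohort$pawp, cohort$co)
  qc <- check_physiologic(hr = cohort$hr, spap = cohort$spap,
                          dpap = cohort$dpap, mpap = cohort$mpap,
                          pawp = cohort$pawp, co = cohort$co,
                          age = if ("age" %in% names(cohort)) cohort$age else NA)
  out <- cbind(cohort, d)
  out$qc_pass <- qc$passed
  out$qc_codes <- qc$reason_codes
  complete <- is.finite(out$mpap) & is.finite(out$pawp) & is.finite(out$pvr)
  ph <- factor(rep(NA_character_, nrow(out)), levels = ph_levels())
  if (any(complete))
    ph[complete] <- classify_ph(out$mpap[complete], out$pawp[complete],
                                out$pvr[complete])
  out$ph_class <- ph
  attr(out, "n_unclassified") <- sum(!complete)
  out
}
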