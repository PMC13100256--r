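#' Harrell's concordance index under right censoring
#'
#' A pair of subjects is comparable when the smaller observed time belongs
#' to an event (we know who failed first); a pair tied on time between an
#' event and a censored subject is comparable with the event treated as
#' failing first; a pair tied on time with both members events is not
#' comparable. A comparable pair is concordant when the subject who fails
#' first carries the strictly higher risk score; score ties count one half.
#'
#' Orientation: higher score means higher predicted risk, i.e. shorter
#' expected survival. C = 0.5 is chance, 1 is perfect ranking.
#'
#' @param score per-subject risk score, finite.
#' @param time observed follow-up time.
#' @param status event indicator 1/0.
#' @return A list of class `concordance_result`: `c_index`,
#'   `comparable_pairs`, `concordant`, `tied_score`.
#' @examples
#' harrell_c(c(4, 3, 1, 2), time = 1:4, status = rep(1, 4))  # 5/6
#' @export
harrell_c <- function(score, time, status) {
  n <- length(score)
  stopifnot(length(time) == n, length(status) == n)
  if (any(!is.finite(score))) stop("scores must be finite", call. = FALSE)
  status <- as.integer(status)
  if (!all(status %in% c(0L, 1L))) stop("status must be 0/1", call. = FALSE)
  cnt <- concordance_counts(as.numeric(score), as.numeric(time), status)
  if (cnt$comparable == 0)
    stop("no comparable pairs (e.g. all subjects censored); concordance undefined",
         call. = FALSE)
  structure(list(
    c_index = (cnt$concordant + 0.5 * cnt$tied_score) / cnt$comparable,
    comparable_pairs = cnt$comparable,
    concordant = cnt$concordant,
    tied_score = cnt$tied_score), class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Harrell's C = %.4f (%d comparable pairs, %d concordant, %d score ties)\n",
              x$c_index, as.integer(x$comparable_pairs),
              as.integer(x$concordant), as.integer(x$tied_score)))
  invisible(x)
}
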