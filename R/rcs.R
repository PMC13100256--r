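#' Restricted cubic spline specification
#'
#' Four ordered knots on the exposure axis plus the reference value at which
#' the hazard ratio is anchored to 1. Default knot placement follows the
#' conventional quantile rule for four knots: the 0.05, 0.35, 0.65 and 0.95
#' quantiles of the observed exposure.
#'
#' @param knots numeric vector of 4 strictly increasing knot locations, or
#'   `NULL` to place them at the default quantiles of `x`.
#' @param reference exposure value where HR is anchored to 1 (must lie
#'   within the knot/data range when used for a curve).
#' @param x optional data vector used to place default knots.
#' @return A list of class `spline_spec` with `knots` and `reference`.
#' @export
rcs_spec <- function(knots = NULL, reference = 3, x = NULL) {
  if (is.null(knots)) {
    if (is.null(x)) stop("supply knots or data x", call. = FALSE)
    knots <- unname(stats::quantile(x, c(0.05, 0.35, 0.65, 0.95), na.rm = TRUE))
  }
  knots <- as.numeric(knots)
  if (length(knots) != 4) stop("exactly 4 knots required", call. = FALSE)
  if (any(diff(knots) <= 0))
    stop("knots must be strictly increasing (duplicates not allowed)",
         call. = FALSE)
  structure(list(knots = knots, reference = reference), class = "spline_spec")
}

#' Linear tail-restricted cubic spline basis (Harrell form)
#'
#' For 4 knots the basis has one linear column and two nonlinear columns of
#' the truncated-power form; any linear combination is a cubic spline that
#' is linear beyond the boundary knots. The nonlinear columns are scaled by
#' the square of the boundary-knot span for numerical stability and vanish
#' at and below the first knot.
#'
#' @param x values at which to evaluate the basis.
#' @param spec a [rcs_spec()].
#' @return An `length(x) x 3` matrix with columns `lin`, `nl1`, `nl2`.
#' @export
rcs_basis <- function(x, spec) {
  stopifnot(inherits(spec, "spline_spec"))
  k <- spec$knots
  nk <- length(k)
  tau <- (k[nk] - k[1])^2
  cube <- function(u) pmax(u, 0)^3
  nl <- function(j) {
    (cube(x - k[j]) -
       cube(x - k[nk - 1]) * (k[nk] - k[j]) / (k[nk] - k[nk - 1]) +
       cube(x - k[nk]) * (k[nk - 1] - k[j]) / (k[nk] - k[nk - 1])) / tau
  }
  out <- cbind(lin = x, nl1 = nl(1), nl2 = nl(2))
  rownames(out) <- NULL
  out
}
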