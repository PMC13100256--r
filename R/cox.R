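#' Numerical settings for the Cox partial-likelihood fitter
#'
#' @param tol convergence tolerance on the largest absolute score (gradient)
#'   component.
#' @param max_iter Newton iteration cap.
#' @param max_halvings step-halvings allowed per iteration when a full
#'   Newton step decreases the partial likelihood.
#' @return A list of settings consumed by [fit_cox()].
#' @export
cox_control <- function(tol = 1e-8, max_iter = 50L, max_halvings = 20L) {
  stopifnot(tol > 0, max_iter >= 1, max_halvings >= 0)
  list(tol = tol, max_iter = as.integer(max_iter),
       max_halvings = as.integer(max_halvings))
}

#' Fit a Cox proportional-hazards model by Newton-Raphson
#'
#' Maximises the Cox log partial likelihood over the coefficient vector with
#' the chosen correction for tied event times (Efron by default, Breslow
#' available), using damped Newton iterations: a full step is halved until
#' the partial likelihood does not decrease. Convergence is declared when
#' the largest absolute score component falls below `control$tol`.
#'
#' Constant or exactly collinear design columns are detected up front and
#' reported by name, since they make the information matrix singular.
#' Non-convergence (e.g. monotone likelihood under separation) yields an
#' explicit `converged = FALSE` result, never a silent one.
#'
#' @param x numeric design matrix (one column per covariate; no intercept —
#'   the Cox model has none).
#' @param time observed follow-up times, positive.
#' @param status event indicator, 1 = event, 0 = censored; at least one
#'   event is required.
#' @param ties `"efron"` or `"breslow"`.
#' @param control see [cox_control()].
#' @param init optional starting coefficients (default zero).
#' @return An object of class `cox_fit`: list with `coefficients`, `se`,
#'   `covariance`, `loglik` (at the optimum), `loglik_null`, `iterations`,
#'   `converged`, `ties`, `n`, `n_events`, and `x_center` (column means used
#'   to centre the design; see [predict_risk()]).
#' @export
fit_cox <- function(x, time, status, ties = c("efron", "breslow"),
                    control = cox_control(), init = NULL) {
  ties <- match.arg(ties)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- nrow(x)
  stopifnot(length(time) == n, length(status) == n)
  if (any(!is.finite(time)) || any(time <= 0))
    stop("times must be finite and positive", call. = FALSE)
  status <- as.integer(status)
  if (!all(status %in% c(0L, 1L)))
    stop("status must be 0/1", call. = FALSE)
  if (sum(status) < 1L) stop("at least one event is required", call. = FALSE)
  if (any(!is.finite(x))) stop("design matrix must be finite", call. = FALSE)

  # reject degenerate designs by name
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s) in design: ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  qx <- qr(scale(x, center = TRUE, scale = FALSE))
  if (qx$rank < ncol(x)) {
    drop_idx <- qx$pivot[(qx$rank + 1):ncol(x)]
    stop("exactly collinear column(s) in design: ",
         paste(colnames(x)[drop_idx], collapse = ", "), call. = FALSE)
  }

  # centre and scale internally so the score tolerance is unit-free;
  # coefficients and covariance are mapped back to the raw scale below
  x_center <- colMeans(x)
  x_scale <- sds
  xc <- sweep(sweep(x, 2, x_center), 2, x_scale, "/")
  ord <- order(time)
  xs <- xc[ord, , drop = FALSE]
  ts <- time[ord]
  ss <- status[ord]
  efron <- as.integer(ties == "efron")

  p <- ncol(x)
  beta <- if (is.null(init)) rep(0, p) else as.numeric(init) * x_scale
  stopifnot(length(beta) == p)

  d0 <- cox_deriv(xs, ts, ss, rep(0, p), efron, 0L)
  loglik_null <- d0$loglik
  d <- cox_deriv(xs, ts, ss, beta, efron, 0L)
  converged <- FALSE
  iter <- 0L
  repeat {
    if (max(abs(d$grad)) < control$tol) { converged <- TRUE; break }
    if (iter >= control$max_iter) break
    iter <- iter + 1L
    step <- tryCatch(drop(solve(d$hess, d$grad)), error = function(e) NULL)
    if (is.null(step))
      stop("singular information matrix; check design columns: ",
           paste(colnames(x), collapse = ", "), call. = FALSE)
    new_beta <- beta + step
    new_d <- cox_deriv(xs, ts, ss, new_beta, efron, 0L)
    # a step must not decrease the likelihood beyond floating-point noise
    eps_ll <- 1e-9 * (abs(d$loglik) + 1)
    h <- 0L
    while ((!is.finite(new_d$loglik) || new_d$loglik < d$loglik - eps_ll) &&
           h < control$max_halvings) {
      h <- h + 1L
      new_beta <- beta + step / 2^h
      new_d <- cox_deriv(xs, ts, ss, new_beta, efron, 0L)
    }
    if (!is.finite(new_d$loglik) || new_d$loglik < d$loglik - eps_ll)
      break  # no acceptable step found: report non-convergence
    beta <- new_beta
    d <- new_d
    if (max(abs(d$grad)) < control$tol) { converged <- TRUE; break }
  }
  cov <- tryCatch(solve(d$hess), error = function(e) matrix(NA_real_, p, p))
  cov <- (cov + t(cov)) / 2
  # back to the raw covariate scale
  beta <- drop(beta) / x_scale
  cov <- cov / tcrossprod(x_scale)
  names(beta) <- colnames(x)
  dimnames(cov) <- list(colnames(x), colnames(x))
  structure(list(coefficients = beta, se = sqrt(diag(cov)), covariance = cov,
                 loglik = d$loglik, loglik_null = loglik_null,
                 iterations = iter, converged = converged, ties = ties,
                 n = n, n_events = sum(ss), x_center = x_center,
                 x_scale = x_scale,
                 sorted = list(x = xs, time = ts, status = ss)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox fit (%s ties): n = %d, events = %d, %s in %d iterations\n",
              x$ties, x$n, x$n_events,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  est <- cbind(coef = x$coefficients, `exp(coef)` = exp(x$coefficients),
               se = x$se)
  print(round(est, 4))
  invisible(x)
}

#' Linear risk predictor from a Cox fit
#'
#' Returns the centred linear predictor `(x - center) %*% beta` for new
#' data. Centring uses the training-column means stored in the fit, so
#' adding a constant to any covariate column before refitting leaves
#' predictions unchanged (the Cox model has no intercept; only contrasts
#' matter). Higher values mean higher predicted risk.
#'
#' @param fit a [fit_cox()] result.
#' @param x design matrix with the same columns (by name, when named) as the
#'   training design.
#' @return Numeric vector of linear predictors.
#' @export
predict_risk <- function(fit, x) {
  stopifnot(inherits(fit, "cox_fit"))
  x <- as.matrix(x)
  if (!is.null(colnames(x)) && !is.null(names(fit$coefficients))) {
    miss <- setdiff(names(fit$coefficients), colnames(x))
    if (length(miss))
      stop("design is missing fitted column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    x <- x[, names(fit$coefficients), drop = FALSE]
  } else if (ncol(x) != length(fit$coefficients)) {
    stop("design has ", ncol(x), " columns; fit has ",
         length(fit$coefficients), call. = FALSE)
  }
  drop(sweep(x, 2, fit$x_center) %*% fit$coefficients)
}

#' Wald summary of a Cox fit
#'
#' Hazard ratios with 95% Wald confidence intervals on the log scale and
#' two-sided normal p-values.
#'
#' @param fit a [fit_cox()] result.
#' @return data.frame with `term`, `coef`, `se`, `hr`, `ci_low`, `ci_high`,
#'   `p_value`.
#' @export
cox_summary <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  z <- fit$coefficients / fit$se
  data.frame(term = names(fit$coefficients), coef = unname(fit$coefficients),
             se = unname(fit$se), hr = exp(unname(fit$coefficients)),
             ci_low = exp(unname(fit$coefficients - 1.96 * fit$se)),
             ci_high = exp(unname(fit$coefficients + 1.96 * fit$se)),
             p_value = 2 * stats::pnorm(-abs(unname(z))),
             stringsAsFactors = FALSE)
}

#' Proportional-hazards diagnostic from scaled Schoenfeld residuals
#'
#' Tests, per covariate and globally, for association between the scaled
#' Schoenfeld residuals and a transform of event time (default:
#' Kaplan-Meier-scaled time, i.e. one minus the left-continuous KM estimate
#' of the censoring-ignored survival curve evaluated at each event time).
#' Under proportional hazards the residuals are uncorrelated with any time
#' transform; a small p-value flags a violation.
#'
#' @param fit a converged [fit_cox()] result.
#' @param transform `"km"`, `"identity"` or `"rank"`.
#' @return A list with `table` (data.frame: term, chisq, df, p) including a
#'   GLOBAL row, and `transform`.
#' @export
ph_diagnostic <- function(fit, transform = c("km", "identity", "rank")) {
  stopifnot(inherits(fit, "cox_fit"))
  transform <- match.arg(transform)
  if (!fit$converged)
    stop("proportional-hazards diagnostic requires a converged fit",
         call. = FALSE)
  if (fit$n_events < 2L)
    stop("proportional-hazards diagnostic needs at least two events",
         call. = FALSE)
  s <- fit$sorted  # standardized design; use matching coefficient scale
  # (the chi-square statistics are invariant to per-column rescaling)
  d <- cox_deriv(s$x, s$time, s$status,
                 fit$coefficients * fit$x_scale,
                 as.integer(fit$ties == "efron"), 1L)
  resid <- d$resid            # d x p Schoenfeld residuals, by event time
  etimes <- d$resid_time
  m <- nrow(resid)
  g <- switch(transform,
    identity = etimes,
    rank = rank(etimes),
    km = {
      # KM of the survival curve of observed time treating all as events is
      # not wanted; use the usual KM of survival from (time, status)
      km <- .km_left(s$time, s$status, etimes)
      1 - km
    })
  u <- g - mean(g)
  imat_inv <- fit$covariance * tcrossprod(fit$x_scale)
  if (any(!is.finite(imat_inv)))
    stop("information matrix not invertible; diagnostic unavailable",
         call. = FALSE)
  w <- drop(crossprod(u, resid))              # p-vector sum u_i s_i
  denom <- sum(u^2)
  p <- length(w)
  # chi_j = (sum u s*_j)^2 / (m * (I^-1)_jj * sum u^2) with s* = m I^-1 s,
  # i.e. the Grambsch-Therneau component test with averaged information
  per_chisq <- (m * (imat_inv %*% w)[, 1]^2) / (denom * diag(imat_inv))
  global <- drop(t(w) %*% imat_inv %*% w) * m / denom
  tab <- data.frame(
    term = c(names(fit$coefficients), "GLOBAL"),
    chisq = c(per_chisq, global),
    df = c(rep(1L, p), p),
    p = c(stats::pchisq(per_chisq, 1, lower.tail = FALSE),
          stats::pchisq(global, p, lower.tail = FALSE)),
    stringsAsFactors = FALSE)
  list(table = tab, transform = transform)
}

# left-continuous Kaplan-Meier estimate evaluated at given event times
.km_left <- function(time, status, at) {
  ut <- sort(unique(time[status == 1]))
  n_risk <- vapply(ut, function(t) sum(time >= t), 0)
  n_ev <- vapply(ut, function(t) sum(time == t & status == 1), 0)
  surv <- cumprod(1 - n_ev / n_risk)
  # left-continuous: S(t-) = product over event times strictly before t
  vapply(at, function(t) {
    k <- sum(ut < t)
    if (k == 0) 1 else surv[k]
  }, 0)
}
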