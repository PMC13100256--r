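# Independent oracles used to validate the survival kernel.  Both are
# deliberately naive: literal pair enumeration for the concordance index and
# direct evaluation of the partial likelihood on a coefficient grid.  They
# share no code with the package's C++ implementations.

# literal enumeration of all ordered pairs via outer()
oracle_concordance <- function(score, time, status) {
  n <- length(score)
  ti <- matrix(time, n, n)
  tj <- t(ti)
  si <- matrix(status, n, n)
  sj <- t(si)
  sci <- matrix(score, n, n)
  scj <- t(sci)
  comparable <- (si == 1) & ((ti < tj) | (ti == tj & sj == 0))
  diag(comparable) <- FALSE
  comp <- sum(comparable)
  conc <- sum(comparable & (sci > scj))
  tied <- sum(comparable & (sci == scj))
  list(comparable = comp, concordant = conc, tied_score = tied,
       c_index = if (comp > 0) (conc + 0.5 * tied) / comp else NA_real_)
}

# Cox log partial likelihood for a single covariate, evaluated at every
# value of a coefficient grid, with Breslow or Efron tie handling
oracle_cox_loglik_grid <- function(x, time, status, grid, ties = "efron") {
  ll <- numeric(length(grid))
  ew <- exp(outer(x, grid))                       # n x G
  for (t in sort(unique(time[status == 1]))) {
    risk <- time >= t
    dead <- time == t & status == 1
    d <- sum(dead)
    s0 <- colSums(ew[risk, , drop = FALSE])
    ll <- ll + colSums(outer(x[dead], grid))
    if (ties == "breslow") {
      ll <- ll - d * log(s0)
    } else {
      d0 <- colSums(ew[dead, , drop = FALSE])
      for (k in seq_len(d) - 1) ll <- ll - log(s0 - (k / d) * d0)
    }
  }
  ll
}

# small survival dataset with tied integer times and mixed censoring
random_tied_dataset <- function(n, tie_grid = 8L, cens_p = 0.3) {
  list(time = sample.int(tie_grid, n, replace = TRUE),
       status = as.integer(stats::runif(n) > cens_p),
       score = round(stats::rnorm(n), 1))
}
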