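// Cox partial-likelihood kernel: log-likelihood, score and information for a
// given coefficient vector, with Breslow or Efron handling of tied event
// times, plus Schoenfeld residuals at event times.  Rows must be sorted by
// observed time, ascending.  The Newton loop itself lives in R (fit_cox).
//
// The risk-set accumulators are updated with explicit symmetric loops (no
// per-row temporaries): the information matrix costs p(p+1)/2 multiplies
// per subject, which keeps repeated fitting (Monte Carlo cross-validation)
// cheap.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
List cox_deriv(const arma::mat& X, const arma::vec& time,
               const arma::ivec& status, const arma::vec& beta,
               const int efron, const int want_resid) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  arma::vec eta = X * beta;
  const double shift = eta.max();  // partial likelihood invariant under shift
  arma::vec w = arma::exp(eta - shift);

  double loglik = 0.0;
  arma::vec grad(p, arma::fill::zeros);
  arma::mat hess(p, p, arma::fill::zeros);

  // risk-set accumulators (sums over subjects with time >= current group)
  double S0 = 0.0;
  arma::vec S1(p, arma::fill::zeros);
  arma::mat S2(p, p, arma::fill::zeros);  // upper triangle maintained

  int n_events = 0;
  for (arma::uword i = 0; i < n; ++i) n_events += (status[i] == 1);
  arma::mat resid;
  arma::vec resid_time;
  if (want_resid) {
    resid.set_size(n_events, p);
    resid_time.set_size(n_events);
  }
  int ridx = n_events;  // fill residuals backwards (we scan late -> early)

  arma::vec D1(p), mu(p), mean_frac(p), sum_x(p);
  arma::mat D2(p, p);

  arma::uword i = n;
  while (i > 0) {
    // group of tied observed times [j, i)
    arma::uword j = i;
    const double t = time[i - 1];
    while (j > 0 && time[j - 1] == t) --j;

    // add the whole tie group to the risk set; collect event sums
    double D0 = 0.0, sum_eta = 0.0;
    arma::uword d = 0;
    D1.zeros(); D2.zeros(); sum_x.zeros();
    for (arma::uword k = j; k < i; ++k) {
      const double wk = w[k];
      const double* xk = X.colptr(0) + k;  // element (k, a) at xk[a * n]
      S0 += wk;
      for (arma::uword a = 0; a < p; ++a) {
        const double xa = xk[a * n];
        S1[a] += wk * xa;
        for (arma::uword b = a; b < p; ++b)
          S2(a, b) += wk * xa * xk[b * n];
      }
      if (status[k] == 1) {
        ++d;
        sum_eta += eta[k] - shift;
        D0 += wk;
        for (arma::uword a = 0; a < p; ++a) {
          const double xa = xk[a * n];
          sum_x[a] += xa;
          D1[a] += wk * xa;
          for (arma::uword b = a; b < p; ++b)
            D2(a, b) += wk * xa * xk[b * n];
        }
      }
    }

    if (d > 0) {
      loglik += sum_eta;
      grad += sum_x;
      mean_frac.zeros();
      for (arma::uword k = 0; k < d; ++k) {
        const double f = efron ? (double)k / (double)d : 0.0;
        const double S0k = S0 - f * D0;
        loglik -= std::log(S0k);
        for (arma::uword a = 0; a < p; ++a)
          mu[a] = (S1[a] - f * D1[a]) / S0k;
        grad -= mu;
        mean_frac += mu / (double)d;
        for (arma::uword a = 0; a < p; ++a)
          for (arma::uword b = a; b < p; ++b)
            hess(a, b) += (S2(a, b) - f * D2(a, b)) / S0k - mu[a] * mu[b];
      }
      if (want_resid) {
        for (arma::uword k = i; k-- > j;) {
          if (status[k] == 1) {
            --ridx;
            for (arma::uword a = 0; a < p; ++a)
              resid(ridx, a) = X(k, a) - mean_frac[a];
            resid_time[ridx] = t;
          }
        }
      }
    }
    i = j;
  }
  hess = arma::symmatu(hess);

  List out = List::create(_["loglik"] = loglik, _["grad"] = grad,
                          _["hess"] = hess, _["n_events"] = n_events);
  if (want_resid) {
    out["resid"] = resid;
    out["resid_time"] = resid_time;
  }
  return out;
}

// Harrell concordance pair counts under right censoring.  A pair is
// comparable when the earlier observed time is an event, or when times are
// tied between an event and a censored subject (the event is taken to occur
// first).  Pairs tied on time with both members events are not comparable.
// Within a comparable pair the earlier-failing subject should carry the
// higher risk score; score ties count one half.
// [[Rcpp::export]]
List concordance_counts(const arma::vec& score, const arma::vec& time,
                        const arma::ivec& status) {
  const arma::uword n = time.n_elem;
  double comparable = 0.0, concordant = 0.0, tied = 0.0;
  for (arma::uword i = 0; i < n; ++i) {
    if (status[i] != 1) continue;
    const double ti = time[i], si = score[i];
    for (arma::uword j = 0; j < n; ++j) {
      if (j == i) continue;
      const bool earlier = ti < time[j];
      const bool tied_ec = (ti == time[j]) && status[j] == 0;
      if (!(earlier || tied_ec)) continue;
      comparable += 1.0;
      if (si > score[j]) concordant += 1.0;
      else if (si == score[j]) tied += 1.0;
    }
  }
  return List::create(_["comparable"] = comparable,
                      _["concordant"] = concordant,
                      _["tied_score"] = tied);
}
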