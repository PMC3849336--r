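// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// Iteratively reweighted least squares for the binomial-logit GLM with an
// optional ridge penalty on the slope coefficients (column 0 is assumed to
// be the intercept and is never penalized).  Convergence mirrors
// stats::glm.fit: relative change in deviance below `tol`.
//
// Returns coefficients, Wald standard errors from (X'WX + P)^{-1}, the
// deviance, and flags for convergence, complete separation and numerical
// failure (rank-deficient weighted normal equations).
// [[Rcpp::export]]
Rcpp::List logit_irls(const arma::mat& X, const arma::vec& y,
                      double ridge = 0.0, int maxit = 200,
                      double tol = 1e-12) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  arma::vec beta(p, arma::fill::zeros);
  arma::vec pen(p, arma::fill::zeros);
  if (ridge > 0.0)
    for (arma::uword k = 1; k < p; ++k) pen(k) = ridge;

  arma::vec eta(n), mu(n);
  double dev = R_PosInf;
  bool converged = false, ok = true;

  for (int it = 0; it < maxit; ++it) {
    eta = X * beta;
    mu = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec w = mu % (1.0 - mu);
    w.transform([](double v) { return v < 1e-12 ? 1e-12 : v; });
    arma::vec z = eta + (y - mu) / w;
    arma::mat Xw = X.each_col() % w;
    arma::mat H = X.t() * Xw;
    H.diag() += pen;
    arma::vec bnew;
    if (!arma::solve(bnew, H, X.t() * (w % z),
                     arma::solve_opts::no_approx + arma::solve_opts::likely_sympd)) {
      ok = false;
      break;
    }
    beta = bnew;
    eta = X * beta;
    mu = 1.0 / (1.0 + arma::exp(-eta));
    double devnew = 0.0;
    for (arma::uword i = 0; i < n; ++i) {
      // clamp to keep the deviance finite under saturation
      double m = std::min(std::max(mu(i), 1e-300), 1.0 - 1e-16);
      devnew += (y(i) > 0.5) ? -2.0 * std::log(m) : -2.0 * std::log1p(-m);
    }
    // penalized objective would differ, but glm's deviance criterion is kept
    if (std::abs(devnew - dev) / (std::abs(devnew) + 0.1) < tol) {
      dev = devnew;
      converged = true;
      break;
    }
    dev = devnew;
  }

  // complete separation: every fitted probability saturates at its outcome
  bool separated = true;
  for (arma::uword i = 0; i < n; ++i) {
    if (std::abs(y(i) - mu(i)) > 1e-5) { separated = false; break; }
  }

  arma::vec se(p);
  se.fill(NA_REAL);
  if (ok) {
    arma::vec w = mu % (1.0 - mu);
    w.transform([](double v) { return v < 1e-12 ? 1e-12 : v; });
    arma::mat H = X.t() * (X.each_col() % w);
    H.diag() += pen;
    arma::mat Hinv;
    if (arma::inv_sympd(Hinv, H)) {
      se = arma::sqrt(Hinv.diag());
    } else {
      ok = false;
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("coefficients") = beta, Rcpp::Named("se") = se,
      Rcpp::Named("deviance") = dev, Rcpp::Named("converged") = converged,
      Rcpp::Named("separated") = separated, Rcpp::Named("ok") = ok);
}
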