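// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// Gaussian class-conditional model with class-specific covariance (QDA).
// Covariances use the n-1 denominator (as stats::cov) and are shrunk toward
// (trace/d)*I with coefficient `reg`; if the Cholesky factorization fails the
// shrinkage is escalated through 1e-2, 1e-1, 0.5.  This ladder must stay in
// sync with the reference implementation in R/qda.R.

static bool chol_shrunk(const arma::mat& S, double reg, arma::mat& R,
                        double& logdet) {
  const double ladder[4] = {reg, 1e-2, 1e-1, 0.5};
  const arma::uword d = S.n_rows;
  double tr = arma::trace(S);
  double scale = (tr > 0.0) ? tr / d : 1e-8;
  for (int k = 0; k < 4; ++k) {
    double g = ladder[k];
    if (g < reg) continue;
    arma::mat Sr = (1.0 - g) * S;
    Sr.diag() += g * scale;
    if (arma::chol(R, Sr)) {
      logdet = 2.0 * arma::accu(arma::log(R.diag()));
      return true;
    }
  }
  return false;
}

// Mann-Whitney AUC with midranks for ties.
static double auc_ranks(const arma::vec& s, const arma::uvec& y1) {
  const arma::uword n = s.n_elem;
  arma::uvec ord = arma::stable_sort_index(s);
  arma::vec rank(n);
  arma::uword i = 0;
  while (i < n) {
    arma::uword j = i;
    while (j + 1 < n && s(ord(j + 1)) == s(ord(i))) ++j;
    double r = 0.5 * (static_cast<double>(i) + static_cast<double>(j)) + 1.0;
    for (arma::uword k = i; k <= j; ++k) rank(ord(k)) = r;
    i = j + 1;
  }
  double n1 = static_cast<double>(arma::accu(y1));
  double n0 = static_cast<double>(n) - n1;
  if (n1 == 0.0 || n0 == 0.0) return NA_REAL;
  double rsum = 0.0;
  for (arma::uword k = 0; k < n; ++k)
    if (y1(k)) rsum += rank(k);
  return (rsum - n1 * (n1 + 1.0) / 2.0) / (n1 * n0);
}

// Per-fold accuracy and AUC of QDA trained on the complement of each fold.
// folds is 1-based; returns a k x 2 matrix (acc, auc), NaN where undefined
// (fold skipped: a training class with < 2 samples or failed factorization).
// auc_labels = true scores the AUC from the 0.5-thresholded predictions
// (balanced accuracy; the reference protocol), false from the posterior.
// [[Rcpp::export]]
arma::mat qda_cv_metrics(const arma::mat& X, const arma::uvec& y,
                         const arma::uvec& folds, int k, double reg,
                         bool auc_labels = true) {
  const arma::uword n = X.n_rows, d = X.n_cols;
  arma::mat out(k, 2);
  out.fill(NA_REAL);

  for (int f = 1; f <= k; ++f) {
    arma::uvec te = arma::find(folds == static_cast<arma::uword>(f));
    arma::uvec tr = arma::find(folds != static_cast<arma::uword>(f));
    if (te.n_elem == 0 || tr.n_elem == 0) continue;

    arma::uvec ytr = y(tr);
    arma::uvec idx1 = tr(arma::find(ytr == 1));
    arma::uvec idx0 = tr(arma::find(ytr == 0));
    if (idx1.n_elem < 2 || idx0.n_elem < 2) continue;

    arma::mat X1 = X.rows(idx1), X0 = X.rows(idx0);
    arma::rowvec m1 = arma::mean(X1, 0), m0 = arma::mean(X0, 0);
    arma::mat S1 = arma::cov(X1), S0 = arma::cov(X0);
    if (d == 1) {  // arma::cov on a single column returns 1x1 already
      S1.set_size(1, 1);
      S1(0, 0) = arma::as_scalar(arma::var(X1.col(0)));
      S0.set_size(1, 1);
      S0(0, 0) = arma::as_scalar(arma::var(X0.col(0)));
    }
    arma::mat R1, R0;
    double ld1, ld0;
    if (!chol_shrunk(S1, reg, R1, ld1) || !chol_shrunk(S0, reg, R0, ld0))
      continue;
    double lp1 = std::log(static_cast<double>(idx1.n_elem) / tr.n_elem);
    double lp0 = std::log(static_cast<double>(idx0.n_elem) / tr.n_elem);

    arma::mat Xte = X.rows(te);
    arma::mat C1 = Xte.each_row() - m1;
    arma::mat C0 = Xte.each_row() - m0;
    // Mahalanobis via triangular solve: cov = R'R so q = ||R^-T x||^2
    arma::mat Z1 = arma::solve(arma::trimatl(R1.t()), C1.t());
    arma::mat Z0 = arma::solve(arma::trimatl(R0.t()), C0.t());
    arma::vec q1 = arma::sum(arma::square(Z1), 0).t();
    arma::vec q0 = arma::sum(arma::square(Z0), 0).t();
    arma::vec l1 = lp1 - 0.5 * ld1 - 0.5 * q1;
    arma::vec l0 = lp0 - 0.5 * ld0 - 0.5 * q0;
    arma::vec post = 1.0 / (1.0 + arma::exp(l0 - l1));

    arma::uvec yte = y(te);
    arma::vec pred(te.n_elem);
    double correct = 0.0;
    for (arma::uword t = 0; t < te.n_elem; ++t) {
      pred(t) = post(t) > 0.5 ? 1.0 : 0.0;
      if (static_cast<int>(pred(t)) == static_cast<int>(yte(t)))
        correct += 1.0;
    }
    out(f - 1, 0) = correct / te.n_elem;
    out(f - 1, 1) = auc_ranks(auc_labels ? pred : post, yte);
  }
  return out;
}
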