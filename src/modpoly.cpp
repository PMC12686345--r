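// Iterative modified polynomial baseline fitting with noise-tolerant
// clipping. B is an orthonormal basis (p x k), so each least-squares fit is
// fit = B * (B' * y). Rows of Y are processed independently; per iteration,
// working points above fit + thr (thr = clip_sigma * estimated noise SD)
// are replaced by the fit itself, i.e. peak points become neutral while
// points inside the noise band are left untouched, and the fit is repeated
// until the baseline changes by less than `tol` (relative, max-norm) or
// `max_iter`. With thr = 0 this is exactly the classic clip
// work = min(work, fit); thr > 0 keeps the iteration from drifting onto
// the lower noise envelope without lifting the fit in peak-dense regions.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export(name = ".modpoly_fit")]]
arma::mat modpoly_fit(const arma::mat& Y, const arma::mat& B,
                      const arma::vec& thr, int max_iter, double tol) {
  const arma::uword n = Y.n_rows, p = Y.n_cols;
  arma::mat out(n, p);
  const arma::mat Bt = B.t();
  const double eps = std::numeric_limits<double>::epsilon();
  arma::vec work(p), fit(p), new_fit(p);
  for (arma::uword i = 0; i < n; ++i) {
    work = Y.row(i).t();
    fit = B * (Bt * work);
    const double ti = thr(i);
    for (int it = 0; it < max_iter; ++it) {
      for (arma::uword j = 0; j < p; ++j) {
        if (work(j) > fit(j) + ti) work(j) = fit(j);
      }
      new_fit = B * (Bt * work);
      double rel = arma::abs(new_fit - fit).max() /
                   (arma::abs(fit).max() + eps);
      fit = new_fit;
      if (rel < tol) break;
    }
    out.row(i) = fit.t();
  }
  return out;
}
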