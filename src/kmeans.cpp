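// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// One Lloyd iteration workhorse, column-major layout: points are the
// columns of Xt (d x n), centres the columns of Ct (d x k). Assigns every
// point to its nearest centre under squared Euclidean distance (ties to
// the lowest index) and accumulates per-cluster sums and counts in the
// same pass; blocked gemm keeps temporaries small.
// Returns: assign (1-based), dmin2, wss, sums (d x k), counts.
// [[Rcpp::export]]
List cppKmeansStep(const arma::mat& Xt, const arma::mat& Ct) {
  const arma::uword n = Xt.n_cols, k = Ct.n_cols;
  arma::rowvec c2 = arma::sum(arma::square(Ct), 0);
  arma::rowvec x2 = arma::sum(arma::square(Xt), 0);
  arma::ivec assign(n);
  arma::vec dmin2(n);
  arma::mat sums(Xt.n_rows, k, arma::fill::zeros);
  arma::ivec counts(k, arma::fill::zeros);
  double wss = 0.0;
  const arma::uword B = 4096;
  for (arma::uword s = 0; s < n; s += B) {
    const arma::uword e = std::min(n, s + B) - 1;
    arma::mat G = Ct.t() * Xt.cols(s, e);  // k x block
    for (arma::uword i = 0; i <= e - s; ++i) {
      const double* g = G.colptr(i);
      double best = c2[0] - 2.0 * g[0];
      arma::uword bi = 0;
      for (arma::uword j = 1; j < k; ++j) {
        const double v = c2[j] - 2.0 * g[j];
        if (v < best) { best = v; bi = j; }
      }
      const arma::uword r = s + i;
      double d2 = x2[r] + best;
      if (d2 < 0) d2 = 0;
      assign[r] = (int)bi + 1;
      dmin2[r] = d2;
      wss += d2;
      sums.col(bi) += Xt.col(r);
      counts[bi] += 1;
    }
  }
  return List::create(_["assign"] = assign, _["dmin2"] = dmin2,
                      _["wss"] = wss, _["sums"] = sums,
                      _["counts"] = counts);
}
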