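// Blockwise thresholded degree sums over the voxel correlation matrix.
// X is a k x N matrix of centred, unit-norm voxel signals, so crossprod
// blocks are Pearson correlations; degree accumulates edges with r > thr
// (strict), never materialising the full N x N matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
Rcpp::List deg_block_sums(const arma::mat& X, const double thr,
                          const int block_size) {
  const arma::uword N = X.n_cols;
  arma::vec d_bin(N, arma::fill::zeros);
  arma::vec d_wt(N, arma::fill::zeros);
  const arma::uword bs = block_size > 0 ? (arma::uword)block_size : 1024;
  for (arma::uword start = 0; start < N; start += bs) {
    const arma::uword end = std::min(start + bs, N) - 1;
    arma::mat C = X.cols(start, end).t() * X;   // (block) x N correlations
    const arma::uword nr = C.n_rows;
    const double* p = C.memptr();               // column-major, contiguous
    for (arma::uword j = 0; j < N; ++j) {
      const double* col = p + j * nr;
      for (arma::uword r = 0; r < nr; ++r) {
        const double v = col[r];
        if (v > thr && start + r != j) {
          d_bin(start + r) += 1.0;
          d_wt(start + r) += v;
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("binarized") = d_bin,
                            Rcpp::Named("weighted") = d_wt);
}
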