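// Batched 1D convolution primitives for the lead-reconstruction networks.
//
// Layout conventions (column-major, matching R arrays):
//   signals:  cube [channels x samples x batch]
//   weights:  mat  [out_channels x (in_channels * kernel)] where column index
//             c + in_channels * j holds the tap for input channel c, offset j
//   pad_mode: 0 = zero padding, 1 = reflection padding (edge sample excluded,
//             so pad width must be <= L - 1 on each side)
//
// Output length is (L + pl + pr - k) / stride + 1 with integer (floor)
// division; trailing samples that do not fill a window are ignored, and the
// backward passes are exact adjoints of that forward map.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat pad_signal(const mat& x, const int pl, const int pr, const int mode) {
  const int L = x.n_cols;
  mat xp(x.n_rows, L + pl + pr, fill::zeros);
  xp.cols(pl, pl + L - 1) = x;
  if (mode == 1) {
    for (int i = 0; i < pl; ++i) xp.col(pl - 1 - i) = x.col(i + 1);
    for (int i = 0; i < pr; ++i) xp.col(pl + L + i) = x.col(L - 2 - i);
  }
  return xp;
}

static mat im2col(const mat& xp, const int k, const int stride, const int Lout) {
  const int C = xp.n_rows;
  mat col(C * k, Lout);
  for (int t = 0; t < Lout; ++t) {
    const mat win = xp.cols(t * stride, t * stride + k - 1);
    std::memcpy(col.colptr(t), win.memptr(), sizeof(double) * C * k);
  }
  return col;
}

// [[Rcpp::export]]
arma::cube conv1d_fwd(const arma::cube& x, const arma::mat& W, const arma::vec& b,
                      int k, int stride, int pl, int pr, int pad_mode) {
  const int B = x.n_slices;
  const int Lp = x.n_cols + pl + pr;
  const int Lout = (Lp - k) / stride + 1;
  cube y(W.n_rows, Lout, B);
  for (int s = 0; s < B; ++s) {
    const mat xp = pad_signal(x.slice(s), pl, pr, pad_mode);
    y.slice(s) = W * im2col(xp, k, stride, Lout);
    y.slice(s).each_col() += b;
  }
  return y;
}

// [[Rcpp::export]]
arma::cube conv1d_bwd_input(const arma::cube& gy, const arma::mat& W,
                            int k, int stride, int pl, int pr, int pad_mode,
                            int Lin) {
  const int B = gy.n_slices;
  const int Cin = W.n_cols / k;
  const int Lout = gy.n_cols;
  const int Lp = Lin + pl + pr;
  cube gx(Cin, Lin, B);
  for (int s = 0; s < B; ++s) {
    const mat gcol = W.t() * gy.slice(s);  // (Cin*k) x Lout
    mat gxp(Cin, Lp, fill::zeros);
    for (int t = 0; t < Lout; ++t) {
      const int off = t * stride;
      for (int j = 0; j < k; ++j)
        gxp.col(off + j) += gcol.col(t).subvec(j * Cin, (j + 1) * Cin - 1);
    }
    mat g = gxp.cols(pl, pl + Lin - 1);
    if (pad_mode == 1) {
      for (int i = 0; i < pl; ++i) g.col(i + 1) += gxp.col(pl - 1 - i);
      for (int i = 0; i < pr; ++i) g.col(Lin - 2 - i) += gxp.col(pl + Lin + i);
    }
    gx.slice(s) = g;
  }
  return gx;
}

// [[Rcpp::export]]
Rcpp::List conv1d_bwd_wb(const arma::cube& x, const arma::cube& gy,
                         int k, int stride, int pl, int pr, int pad_mode) {
  const int B = x.n_slices;
  const int Lout = gy.n_cols;
  mat gW(gy.n_rows, x.n_rows * k, fill::zeros);
  vec gb(gy.n_rows, fill::zeros);
  for (int s = 0; s < B; ++s) {
    const mat xp = pad_signal(x.slice(s), pl, pr, pad_mode);
    gW += gy.slice(s) * im2col(xp, k, stride, Lout).t();
    gb += sum(gy.slice(s), 1);
  }
  return Rcpp::List::create(Rcpp::Named("gW") = gW, Rcpp::Named("gb") = gb);
}
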