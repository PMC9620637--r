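// Minimal CNN primitives: same-padding stride-1 convolution via im2col + GEMM,
// and 2x2 max pooling with argmax bookkeeping for backpropagation.
// Tensors are arma::cube in (H, W, C) layout, matching R arrays dim c(H, W, C).
// Convolution weights are a (kh*kw*Cin) x Cout matrix; the patch vector is
// ordered channel-major: q = ch*kh*kw + ki*kw + kj (ki, kj 0-based kernel
// row/col offsets).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, int kh, int kw) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int ph = kh / 2, pw = kw / 2;
  arma::mat M(H * W, kh * kw * C, arma::fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    for (int ki = 0; ki < kh; ++ki) {
      for (int kj = 0; kj < kw; ++kj) {
        const int q = ch * kh * kw + ki * kw + kj;
        // input row = out_row + ki - ph, input col = out_col + kj - pw
        for (int c = 0; c < W; ++c) {
          const int ic = c + kj - pw;
          if (ic < 0 || ic >= W) continue;
          for (int r = 0; r < H; ++r) {
            const int ir = r + ki - ph;
            if (ir < 0 || ir >= H) continue;
            M(r + H * c, q) = x(ir, ic, ch);
          }
        }
      }
    }
  }
  return M;
}

static arma::cube col2im(const arma::mat& dM, int H, int W, int C,
                         int kh, int kw) {
  const int ph = kh / 2, pw = kw / 2;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    for (int ki = 0; ki < kh; ++ki) {
      for (int kj = 0; kj < kw; ++kj) {
        const int q = ch * kh * kw + ki * kw + kj;
        for (int c = 0; c < W; ++c) {
          const int ic = c + kj - pw;
          if (ic < 0 || ic >= W) continue;
          for (int r = 0; r < H; ++r) {
            const int ir = r + ki - ph;
            if (ir < 0 || ir >= H) continue;
            dx(ir, ic, ch) += dM(r + H * c, q);
          }
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& w,
                      const arma::vec& b, int kh, int kw) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  if ((int)w.n_rows != kh * kw * (int)x.n_slices)
    stop("conv2d_fwd: weight rows do not match kh*kw*Cin");
  arma::mat Y;
  if (kh == 1 && kw == 1) {
    arma::mat X(const_cast<double*>(x.memptr()), H * W, x.n_slices, false);
    Y = X * w;
  } else {
    Y = im2col(x, kh, kw) * w;
  }
  Y.each_row() += b.t();
  return arma::cube(Y.memptr(), H, W, Cout);
}

// [[Rcpp::export]]
List conv2d_bwd(const arma::cube& x, const arma::mat& w, const arma::cube& dy,
                int kh, int kw) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = dy.n_slices;
  arma::mat dY(const_cast<double*>(dy.memptr()), H * W, Cout, false);
  arma::mat dw;
  arma::cube dx;
  if (kh == 1 && kw == 1) {
    arma::mat X(const_cast<double*>(x.memptr()), H * W, Cin, false);
    dw = X.t() * dY;
    arma::mat dX = dY * w.t();
    dx = arma::cube(dX.memptr(), H, W, Cin);
  } else {
    arma::mat M = im2col(x, kh, kw);
    dw = M.t() * dY;
    dx = col2im(dY * w.t(), H, W, Cin, kh, kw);
  }
  arma::vec db = arma::sum(dY, 0).t();
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (H % 2 || W % 2) stop("maxpool2_fwd: odd spatial dimensions");
  const int h = H / 2, w = W / 2;
  arma::cube y(h, w, C);
  arma::ucube idx(h, w, C); // linear index into the input slice
  for (int ch = 0; ch < C; ++ch) {
    for (int c = 0; c < w; ++c) {
      for (int r = 0; r < h; ++r) {
        int br = 2 * r, bc = 2 * c;
        double best = x(br, bc, ch);
        int bi = br + H * bc;
        // fixed visiting order makes argmax ties deterministic
        const int rr[4] = {br, br + 1, br, br + 1};
        const int cc[4] = {bc, bc, bc + 1, bc + 1};
        for (int k = 1; k < 4; ++k) {
          double v = x(rr[k], cc[k], ch);
          if (v > best) { best = v; bi = rr[k] + H * cc[k]; }
        }
        y(r, c, ch) = best;
        idx(r, c, ch) = bi;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_bwd(const arma::ucube& idx, const arma::cube& dy,
                        int H, int W) {
  const int h = dy.n_rows, w = dy.n_cols, C = dy.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int ch = 0; ch < C; ++ch)
    for (int c = 0; c < w; ++c)
      for (int r = 0; r < h; ++r)
        dx.slice(ch)(idx(r, c, ch)) += dy(r, c, ch);
  return dx;
}
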