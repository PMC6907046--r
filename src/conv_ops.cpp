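// Convolution / pooling primitives for the compact U-Net.
//
// Feature maps are arma::cube of shape H x W x C (double). Conv weights are
// stored as (k*k*Cin) x Cout matrices with row index di + k*dj + k*k*c
// (di = kernel row, dj = kernel col, c = input channel); up-convolution
// (2x2 transposed, stride 2) weights as (4*Cin) x Cout with row index
// di + 2*dj + 4*c. Zero padding; stride 1 for conv.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, int k, int pad, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(k * k * C, (arma::uword)Ho * Wo, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int r = di + k * dj + k * k * c;
        for (int jo = 0; jo < Wo; ++jo) {
          const int jin = jo + dj - pad;
          if (jin < 0 || jin >= W) continue;
          for (int io = 0; io < Ho; ++io) {
            const int iin = io + di - pad;
            if (iin < 0 || iin >= H) continue;
            cols(r, io + (arma::uword)Ho * jo) = x(iin, jin, c);
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export(name = ".conv2d_fw")]]
arma::cube conv2d_fw(const arma::cube& x, const arma::mat& W,
                     const arma::vec& b, int k, int pad) {
  const int Ho = x.n_rows + 2 * pad - k + 1;
  const int Wo = x.n_cols + 2 * pad - k + 1;
  if (Ho < 1 || Wo < 1) stop("conv output size would be non-positive");
  const int Cout = W.n_cols;
  arma::mat cols = im2col(x, k, pad, Ho, Wo);
  arma::mat y = W.t() * cols;           // Cout x (Ho*Wo)
  y.each_col() += b;
  arma::cube out(Ho, Wo, Cout);
  for (int o = 0; o < Cout; ++o)
    out.slice(o) = arma::reshape(y.row(o), Ho, Wo);
  return out;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(const arma::cube& x, const arma::mat& W, int k, int pad,
               const arma::cube& gy) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, Cout = gy.n_slices;
  const int H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  arma::mat gyMat(Cout, (arma::uword)Ho * Wo);
  for (int o = 0; o < Cout; ++o)
    gyMat.row(o) = arma::vectorise(gy.slice(o)).t();
  arma::mat cols = im2col(x, k, pad, Ho, Wo);
  arma::mat gW = cols * gyMat.t();            // (k*k*C) x Cout
  arma::vec gb = arma::sum(gyMat, 1);
  arma::mat gcols = W * gyMat;                // (k*k*C) x (Ho*Wo)
  arma::cube gx(H, Wd, C, arma::fill::zeros); // col2im scatter-add
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int r = di + k * dj + k * k * c;
        for (int jo = 0; jo < Wo; ++jo) {
          const int jin = jo + dj - pad;
          if (jin < 0 || jin >= Wd) continue;
          for (int io = 0; io < Ho; ++io) {
            const int iin = io + di - pad;
            if (iin < 0 || iin >= H) continue;
            gx(iin, jin, c) += gcols(r, io + (arma::uword)Ho * jo);
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// [[Rcpp::export(name = ".maxpool_fw")]]
List maxpool_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (H % 2 || W % 2) stop("maxpool input must have even height and width");
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C), idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double best = x(2 * i, 2 * j, c); int arg = 0;
        const double v1 = x(2 * i + 1, 2 * j, c);
        if (v1 > best) { best = v1; arg = 1; }
        const double v2 = x(2 * i, 2 * j + 1, c);
        if (v2 > best) { best = v2; arg = 2; }
        const double v3 = x(2 * i + 1, 2 * j + 1, c);
        if (v3 > best) { best = v3; arg = 3; }
        y(i, j, c) = best; idx(i, j, c) = arg;
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_bw")]]
arma::cube maxpool_bw(const arma::cube& gy, const arma::cube& idx) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, C = gy.n_slices;
  arma::cube gx(2 * Ho, 2 * Wo, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const int a = (int)idx(i, j, c);
        gx(2 * i + (a & 1), 2 * j + (a >> 1), c) = gy(i, j, c);
      }
  return gx;
}

// [[Rcpp::export(name = ".upconv_fw")]]
arma::cube upconv_fw(const arma::cube& x, const arma::mat& W,
                     const arma::vec& b) {
  const int H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  const int Cout = W.n_cols;
  arma::cube y(2 * H, 2 * Wd, Cout);
  for (int o = 0; o < Cout; ++o) y.slice(o).fill(b(o));
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < C; ++c)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          const double w = W(di + 2 * dj + 4 * c, o);
          if (w == 0) continue;
          for (int j = 0; j < Wd; ++j)
            for (int i = 0; i < H; ++i)
              y(2 * i + di, 2 * j + dj, o) += w * x(i, j, c);
        }
  return y;
}

// [[Rcpp::export(name = ".upconv_bw")]]
List upconv_bw(const arma::cube& x, const arma::mat& W, const arma::cube& gy) {
  const int H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  const int Cout = gy.n_slices;
  arma::cube gx(H, Wd, C, arma::fill::zeros);
  arma::mat gW(4 * C, Cout, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  for (int o = 0; o < Cout; ++o) {
    gb(o) = arma::accu(gy.slice(o));
    for (int c = 0; c < C; ++c)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          const double w = W(di + 2 * dj + 4 * c, o);
          double acc = 0.0;
          for (int j = 0; j < Wd; ++j)
            for (int i = 0; i < H; ++i) {
              const double g = gy(2 * i + di, 2 * j + dj, o);
              gx(i, j, c) += w * g;
              acc += x(i, j, c) * g;
            }
          gW(di + 2 * dj + 4 * c, o) = acc;
        }
  }
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}
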