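// Minimal single-threaded CNN primitives used by the tiny detector backbone.
// Layout convention: feature maps are R arrays dim c(H, W, C) == arma::cube
// (rows = y, cols = x, slices = channels). Convolutions are stride-1 with
// symmetric zero padding; downsampling happens in 2x2 max-pool layers.
// Weight matrix layout for a k x k conv: (k*k*Cin) x Cout with row index
// c*k*k + kx*k + ky (ky fastest). All kernels recompute the im2col buffer in
// the backward pass to keep memory flat.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col(const arma::cube& X, int k, int pad) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  arma::mat A(H * (long long)W, (long long)k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const arma::uword col = (arma::uword)c * k * k + kx * k + ky;
        for (int x = 0; x < W; ++x) {
          const int sx = x + kx - pad;
          if (sx < 0 || sx >= W) continue;
          for (int y = 0; y < H; ++y) {
            const int sy = y + ky - pad;
            if (sy < 0 || sy >= H) continue;
            A((arma::uword)y + (arma::uword)H * x, col) = X(sy, sx, c);
          }
        }
      }
    }
  }
  return A;
}

// [[Rcpp::export]]
arma::cube cn_conv_fwd(const arma::cube& X, const arma::mat& K,
                       const arma::vec& b, int k, int pad) {
  const int H = X.n_rows, W = X.n_cols;
  const int Cout = K.n_cols;
  arma::mat A = im2col(X, k, pad);
  arma::mat O = A * K;            // (H*W) x Cout
  O.each_row() += b.t();
  arma::cube out(H, W, Cout);
  for (int c = 0; c < Cout; ++c)
    out.slice(c) = arma::reshape(O.col(c), H, W);
  return out;
}

// [[Rcpp::export]]
List cn_conv_bwd(const arma::cube& X, const arma::mat& K,
                 const arma::cube& dOut, int k, int pad) {
  const int H = X.n_rows, W = X.n_cols, Cin = X.n_slices;
  const int Cout = dOut.n_slices;
  arma::mat dO(H * (long long)W, Cout);
  for (int c = 0; c < Cout; ++c)
    dO.col(c) = arma::vectorise(dOut.slice(c));
  arma::mat A = im2col(X, k, pad);
  arma::mat dK = A.t() * dO;
  arma::vec db = arma::sum(dO, 0).t();
  arma::mat dA = dO * K.t();      // (H*W) x (k*k*Cin)
  arma::cube dX(H, W, Cin, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const arma::uword col = (arma::uword)c * k * k + kx * k + ky;
        for (int x = 0; x < W; ++x) {
          const int sx = x + kx - pad;
          if (sx < 0 || sx >= W) continue;
          for (int y = 0; y < H; ++y) {
            const int sy = y + ky - pad;
            if (sy < 0 || sy >= H) continue;
            dX(sy, sx, c) += dA((arma::uword)y + (arma::uword)H * x, col);
          }
        }
      }
    }
  }
  return List::create(_["dX"] = dX, _["dK"] = dK, _["db"] = db);
}

// [[Rcpp::export]]
List cn_maxpool2_fwd(const arma::cube& X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int H2 = H / 2, W2 = W / 2;
  arma::cube out(H2, W2, C);
  IntegerVector idx(H2 * W2 * C);  // 0-based linear index into X
  long long p = 0;
  for (int c = 0; c < C; ++c) {
    for (int x = 0; x < W2; ++x) {
      for (int y = 0; y < H2; ++y) {
        double best = -1e300; long long bi = 0;
        for (int dx = 0; dx < 2; ++dx) {
          for (int dy = 0; dy < 2; ++dy) {
            const int sy = 2 * y + dy, sx = 2 * x + dx;
            const double v = X(sy, sx, c);
            if (v > best) {
              best = v;
              bi = (long long)sy + (long long)H * sx + (long long)H * W * c;
            }
          }
        }
        out(y, x, c) = best;
        idx[p++] = (int)bi;
      }
    }
  }
  // column-major fill order above matches dim c(H2, W2, C)
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cn_maxpool2_bwd(const arma::cube& dOut, const IntegerVector& idx,
                           int H, int W, int C) {
  arma::cube dX(H, W, C, arma::fill::zeros);
  const double* src = dOut.memptr();
  double* dst = dX.memptr();
  const long long n = (long long)dOut.n_elem;
  for (long long i = 0; i < n; ++i) dst[idx[i]] += src[i];
  return dX;
}

// RoI max pooling. boxes: n x 4 matrix (x0, y0, x1, y1) in *feature-map*
// coordinates, half-open. Degenerate boxes (projecting to < 1 cell) fall back
// to the nearest cell. Returns pooled values dim c(S, S, C, n) plus the
// 0-based argmax linear index into X for the backward pass.
// [[Rcpp::export]]
List cn_roipool_fwd(const arma::cube& X, const arma::mat& boxes, int S) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int n = boxes.n_rows;
  NumericVector out((long long)S * S * C * n);
  IntegerVector idx((long long)S * S * C * n);
  out.attr("dim") = IntegerVector::create(S, S, C, n);
  idx.attr("dim") = IntegerVector::create(S, S, C, n);
  long long p;
  for (int r = 0; r < n; ++r) {
    double x0 = boxes(r, 0), y0 = boxes(r, 1), x1 = boxes(r, 2), y1 = boxes(r, 3);
    for (int c = 0; c < C; ++c) {
      for (int bx = 0; bx < S; ++bx) {
        int cx0 = (int)std::floor(x0 + bx * (x1 - x0) / S);
        int cx1 = (int)std::ceil(x0 + (bx + 1) * (x1 - x0) / S);
        cx0 = std::max(0, std::min(cx0, W - 1));
        cx1 = std::max(cx0 + 1, std::min(cx1, W));
        for (int by = 0; by < S; ++by) {
          int cy0 = (int)std::floor(y0 + by * (y1 - y0) / S);
          int cy1 = (int)std::ceil(y0 + (by + 1) * (y1 - y0) / S);
          cy0 = std::max(0, std::min(cy0, H - 1));
          cy1 = std::max(cy0 + 1, std::min(cy1, H));
          double best = -1e300; long long bi = 0;
          for (int x = cx0; x < cx1; ++x) {
            for (int y = cy0; y < cy1; ++y) {
              const double v = X(y, x, c);
              if (v > best) {
                best = v;
                bi = (long long)y + (long long)H * x + (long long)H * W * c;
              }
            }
          }
          p = (long long)by + (long long)S * bx + (long long)S * S * c +
              (long long)S * S * C * r;
          out[p] = best;
          idx[p] = (int)bi;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cn_roipool_bwd(const NumericVector& dOut, const IntegerVector& idx,
                          int H, int W, int C) {
  arma::cube dX(H, W, C, arma::fill::zeros);
  double* dst = dX.memptr();
  const long long n = dOut.size();
  for (long long i = 0; i < n; ++i) dst[idx[i]] += dOut[i];
  return dX;
}
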