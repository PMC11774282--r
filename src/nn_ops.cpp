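// GEMM-backed layer primitives for the network channels.
// Layouts follow R's column-major arrays:
//   2-D tensors: (H, W, C); 3-D tensors: (T, H, W, C)
//   2-D kernels: (kh, kw, Cin, Cout); 3-D kernels: (kt, kh, kw, Cin, Cout)
// All convolutions use zero padding; output size (n + 2p - k)/s + 1.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_dim(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// ---- 2-D im2col: returns P x K (P = Ho*Wo positions, K = kh*kw*Cin) ----
static arma::mat im2col2d(const double* x, int H, int W, int C,
                          int kh, int kw, int s, int p) {
  const int Ho = out_dim(H, kh, s, p), Wo = out_dim(W, kw, s, p);
  arma::mat col(Ho * (long long)Wo, (long long)kh * kw * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (long long)c * H * W;
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int k = di + kh * (dj + kw * c);
        double* colk = col.colptr(k);
        for (int jo = 0; jo < Wo; ++jo) {
          const int j = jo * s - p + dj;
          if (j < 0 || j >= W) continue;
          for (int io = 0; io < Ho; ++io) {
            const int i = io * s - p + di;
            if (i < 0 || i >= H) continue;
            colk[io + (long long)Ho * jo] = xc[i + (long long)H * j];
          }
        }
      }
    }
  }
  return col;
}

static void col2im2d(const arma::mat& col, double* x, int H, int W, int C,
                     int kh, int kw, int s, int p) {
  const int Ho = out_dim(H, kh, s, p), Wo = out_dim(W, kw, s, p);
  for (int c = 0; c < C; ++c) {
    double* xc = x + (long long)c * H * W;
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int k = di + kh * (dj + kw * c);
        const double* colk = col.colptr(k);
        for (int jo = 0; jo < Wo; ++jo) {
          const int j = jo * s - p + dj;
          if (j < 0 || j >= W) continue;
          for (int io = 0; io < Ho; ++io) {
            const int i = io * s - p + di;
            if (i < 0 || i >= H) continue;
            xc[i + (long long)H * j] += colk[io + (long long)Ho * jo];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(rng = false)]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  if (wd[2] != C) stop("conv2d: channel mismatch");
  const int Ho = out_dim(H, kh, stride, pad), Wo = out_dim(W, kw, stride, pad);
  arma::mat col = im2col2d(REAL(x), H, W, C, kh, kw, stride, pad);
  arma::mat Wm(const_cast<double*>(REAL(w)), (long long)kh * kw * C, F, false, true);
  arma::mat out = col * Wm;                      // P x F
  NumericVector y(Ho * (long long)Wo * F);
  double* yp = REAL(y);
  for (int f = 0; f < F; ++f) {
    const double* of = out.colptr(f);
    const double bf = b[f];
    for (long long pix = 0; pix < (long long)Ho * Wo; ++pix)
      yp[pix + (long long)Ho * Wo * f] = of[pix] + bf;
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, F);
  return y;
}

// gradient w.r.t. the convolution input, given its spatial size (H, W)
// [[Rcpp::export(rng = false)]]
NumericVector cpp_conv2d_bw_input(NumericVector dout, NumericVector w,
                                  int H, int W, int stride, int pad) {
  IntegerVector dd = dout.attr("dim"), wd = w.attr("dim");
  const int Ho = dd[0], Wo = dd[1], F = dd[2];
  const int kh = wd[0], kw = wd[1], C = wd[2];
  if (wd[3] != F) stop("conv2d_bw_input: filter mismatch");
  arma::mat Dm(const_cast<double*>(REAL(dout)), (long long)Ho * Wo, F, false, true);
  arma::mat Wm(const_cast<double*>(REAL(w)), (long long)kh * kw * C, F, false, true);
  arma::mat dcol = Dm * Wm.t();                  // P x K
  NumericVector dx(H * (long long)W * C);
  col2im2d(dcol, REAL(dx), H, W, C, kh, kw, stride, pad);
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return dx;
}

// [[Rcpp::export(rng = false)]]
NumericVector cpp_conv2d_bw_filter(NumericVector x, NumericVector dout,
                                   int kh, int kw, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), dd = dout.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int F = dd[2];
  arma::mat col = im2col2d(REAL(x), H, W, C, kh, kw, stride, pad);
  arma::mat Dm(const_cast<double*>(REAL(dout)), (long long)dd[0] * dd[1], F, false, true);
  arma::mat dW = col.t() * Dm;                   // K x F
  NumericVector out(dW.begin(), dW.end());
  out.attr("dim") = IntegerVector::create(kh, kw, C, F);
  return out;
}

// ---- 3-D im2col: P = To*Ho*Wo, K = kt*kh*kw*Cin ----
static arma::mat im2col3d(const double* x, int T, int H, int W, int C,
                          int kt, int kh, int kw, int s, int pt, int p) {
  const int To = out_dim(T, kt, s, pt), Ho = out_dim(H, kh, s, p),
            Wo = out_dim(W, kw, s, p);
  arma::mat col((long long)To * Ho * Wo, (long long)kt * kh * kw * C,
                arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (long long)c * T * H * W;
    for (int dj = 0; dj < kw; ++dj)
      for (int di = 0; di < kh; ++di)
        for (int dt = 0; dt < kt; ++dt) {
          const int k = dt + kt * (di + kh * (dj + kw * c));
          double* colk = col.colptr(k);
          for (int jo = 0; jo < Wo; ++jo) {
            const int j = jo * s - p + dj;
            if (j < 0 || j >= W) continue;
            for (int io = 0; io < Ho; ++io) {
              const int i = io * s - p + di;
              if (i < 0 || i >= H) continue;
              const long long xoff = (long long)T * (i + (long long)H * j);
              const long long coff = (long long)To * (io + (long long)Ho * jo);
              for (int to = 0; to < To; ++to) {
                const int t = to * s - pt + dt;
                if (t < 0 || t >= T) continue;
                colk[to + coff] = xc[t + xoff];
              }
            }
          }
        }
  }
  return col;
}

static void col2im3d(const arma::mat& col, double* x, int T, int H, int W,
                     int C, int kt, int kh, int kw, int s, int pt, int p) {
  const int To = out_dim(T, kt, s, pt), Ho = out_dim(H, kh, s, p),
            Wo = out_dim(W, kw, s, p);
  for (int c = 0; c < C; ++c) {
    double* xc = x + (long long)c * T * H * W;
    for (int dj = 0; dj < kw; ++dj)
      for (int di = 0; di < kh; ++di)
        for (int dt = 0; dt < kt; ++dt) {
          const int k = dt + kt * (di + kh * (dj + kw * c));
          const double* colk = col.colptr(k);
          for (int jo = 0; jo < Wo; ++jo) {
            const int j = jo * s - p + dj;
            if (j < 0 || j >= W) continue;
            for (int io = 0; io < Ho; ++io) {
              const int i = io * s - p + di;
              if (i < 0 || i >= H) continue;
              const long long xoff = (long long)T * (i + (long long)H * j);
              const long long coff = (long long)To * (io + (long long)Ho * jo);
              for (int to = 0; to < To; ++to) {
                const int t = to * s - pt + dt;
                if (t < 0 || t >= T) continue;
                xc[t + xoff] += colk[to + coff];
              }
            }
          }
        }
  }
}

// [[Rcpp::export(rng = false)]]
NumericVector cpp_conv3d_fw(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int pad_t, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int T = xd[0], H = xd[1], W = xd[2], C = xd[3];
  const int kt = wd[0], kh = wd[1], kw = wd[2], F = wd[4];
  if (wd[3] != C) stop("conv3d: channel mismatch");
  const int To = out_dim(T, kt, stride, pad_t),
            Ho = out_dim(H, kh, stride, pad), Wo = out_dim(W, kw, stride, pad);
  arma::mat col = im2col3d(REAL(x), T, H, W, C, kt, kh, kw, stride, pad_t, pad);
  arma::mat Wm(const_cast<double*>(REAL(w)), (long long)kt * kh * kw * C, F,
               false, true);
  arma::mat out = col * Wm;
  const long long P = (long long)To * Ho * Wo;
  NumericVector y(P * F);
  double* yp = REAL(y);
  for (int f = 0; f < F; ++f) {
    const double* of = out.colptr(f);
    const double bf = b[f];
    for (long long pix = 0; pix < P; ++pix) yp[pix + P * f] = of[pix] + bf;
  }
  y.attr("dim") = IntegerVector::create(To, Ho, Wo, F);
  return y;
}

// [[Rcpp::export(rng = false)]]
NumericVector cpp_conv3d_bw_input(NumericVector dout, NumericVector w,
                                  int T, int H, int W, int stride, int pad_t,
                                  int pad) {
  IntegerVector dd = dout.attr("dim"), wd = w.attr("dim");
  const int F = dd[3];
  const int kt = wd[0], kh = wd[1], kw = wd[2], C = wd[3];
  arma::mat Dm(const_cast<double*>(REAL(dout)),
               (long long)dd[0] * dd[1] * dd[2], F, false, true);
  arma::mat Wm(const_cast<double*>(REAL(w)), (long long)kt * kh * kw * C, F,
               false, true);
  arma::mat dcol = Dm * Wm.t();
  NumericVector dx((long long)T * H * W * C);
  col2im3d(dcol, REAL(dx), T, H, W, C, kt, kh, kw, stride, pad_t, pad);
  dx.attr("dim") = IntegerVector::create(T, H, W, C);
  return dx;
}

// [[Rcpp::export(rng = false)]]
NumericVector cpp_conv3d_bw_filter(NumericVector x, NumericVector dout,
                                   int kt, int kh, int kw, int stride,
                                   int pad_t, int pad) {
  IntegerVector xd = x.attr("dim"), dd = dout.attr("dim");
  const int T = xd[0], H = xd[1], W = xd[2], C = xd[3];
  const int F = dd[3];
  arma::mat col = im2col3d(REAL(x), T, H, W, C, kt, kh, kw, stride, pad_t, pad);
  arma::mat Dm(const_cast<double*>(REAL(dout)),
               (long long)dd[0] * dd[1] * dd[2], F, false, true);
  arma::mat dW = col.t() * Dm;
  NumericVector out(dW.begin(), dW.end());
  out.attr("dim") = IntegerVector::create(kt, kh, kw, C, F);
  return out;
}

// ---- 2x2x2 max pooling, stride 2; argmax kept for the backward pass ----
// [[Rcpp::export(rng = false)]]
List cpp_maxpool3d_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int T = xd[0], H = xd[1], W = xd[2], C = xd[3];
  if (T % 2 || H % 2 || W % 2) stop("maxpool3d: dimensions must be even");
  const int To = T / 2, Ho = H / 2, Wo = W / 2;
  const long long n = (long long)To * Ho * Wo * C;
  NumericVector y(n);
  IntegerVector arg(n);  // 1-based linear index into x
  const double* xp = REAL(x);
  double* yp = REAL(y);
  int* ap = INTEGER(arg);
  long long q = 0;
  for (int c = 0; c < C; ++c)
    for (int jo = 0; jo < Wo; ++jo)
      for (int io = 0; io < Ho; ++io)
        for (int to = 0; to < To; ++to, ++q) {
          double best = R_NegInf;
          long long bidx = 0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di)
              for (int dt = 0; dt < 2; ++dt) {
                const long long idx = (2 * to + dt) +
                  (long long)T * ((2 * io + di) +
                  (long long)H * ((2 * jo + dj) + (long long)W * c));
                if (xp[idx] > best) { best = xp[idx]; bidx = idx; }
              }
          // column-major write position: (to, io, jo, c)
          const long long w = to + (long long)To * (io +
            (long long)Ho * (jo + (long long)Wo * c));
          yp[w] = best;
          ap[w] = (int)(bidx + 1);
        }
  y.attr("dim") = IntegerVector::create(To, Ho, Wo, C);
  arg.attr("dim") = IntegerVector::create(To, Ho, Wo, C);
  return List::create(_["out"] = y, _["argmax"] = arg);
}

// [[Rcpp::export(rng = false)]]
NumericVector cpp_maxpool3d_bw(NumericVector dout, IntegerVector argmax,
                               IntegerVector xdim) {
  const long long n = (long long)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  double* dp = REAL(dx);
  const double* gp = REAL(dout);
  const int* ap = INTEGER(argmax);
  const long long m = dout.size();
  for (long long q = 0; q < m; ++q) dp[ap[q] - 1] += gp[q];
  dx.attr("dim") = xdim;
  return dx;
}
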