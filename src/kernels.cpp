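// Numerical kernels: exact non-uniform DFTs (small-grid reference encoding)
// and the convolution/pooling primitives behind the neural layers.
// Array layout convention: image tensors are R arrays dim (H, W, C, B),
// column-major; weights dim (k, k, C_in, C_out).
#include <RcppArmadillo.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// s(k) = sum_xy I[x,y] exp(-2pi i (kx*x + ky*y)), pixel coords centered:
// x = col - (N/2), y = row - (N/2) (0-based), k in cycles/pixel.
// [[Rcpp::export]]
arma::cx_vec ndft_fwd_cpp(const arma::cx_mat& img, const arma::vec& kx,
                          const arma::vec& ky) {
  const int n = img.n_rows;  // square grids only
  const int m = kx.n_elem;
  const int h = n / 2;
  arma::cx_vec out(m, arma::fill::zeros);
  for (int s = 0; s < m; ++s) {
    std::complex<double> acc(0.0, 0.0);
    for (int j = 0; j < n; ++j) {        // column -> x
      const double px = -2.0 * M_PI * kx(s) * (j - h);
      for (int i = 0; i < n; ++i) {      // row -> y
        const double ph = px - 2.0 * M_PI * ky(s) * (i - h);
        acc += img(i, j) * std::complex<double>(std::cos(ph), std::sin(ph));
      }
    }
    out(s) = acc;
  }
  return out;
}

// Adjoint: a[x,y] = sum_s w_s * samp_s * exp(+2pi i (kx*x + ky*y))
// [[Rcpp::export]]
arma::cx_mat ndft_adj_cpp(const arma::cx_vec& samp, const arma::vec& kx,
                          const arma::vec& ky, const int n,
                          const arma::vec& w) {
  const int m = samp.n_elem;
  const int h = n / 2;
  arma::cx_mat out(n, n, arma::fill::zeros);
  for (int s = 0; s < m; ++s) {
    const std::complex<double> v = samp(s) * w(s);
    for (int j = 0; j < n; ++j) {
      const double px = 2.0 * M_PI * kx(s) * (j - h);
      for (int i = 0; i < n; ++i) {
        const double ph = px + 2.0 * M_PI * ky(s) * (i - h);
        out(i, j) += v * std::complex<double>(std::cos(ph), std::sin(ph));
      }
    }
  }
  return out;
}

// batched im2col: rows p = h + H*w + H*W*b ; cols q = kx + k*ky + k*k*c
// Padded-plane helpers for the shifted-gemm 3x3 convolution: each
// channel lives on an (H+2) x (W+2) plane whose border ring is zero, so
// a kernel tap is one dgemm on a pointer-shifted view of the plane
// stack (leading dimension = plane size). The pad ring absorbs border
// taps and interleaved pad rows inside the gemm row range read zeros.
static void to_pad(const double* x, double* xp, int H, int W, int C) {
  const int Hp = H + 2;
  const size_t plane = (size_t)Hp * (W + 2);
  std::memset(xp, 0, sizeof(double) * plane * C);
  for (int c = 0; c < C; ++c)
    for (int w_ = 0; w_ < W; ++w_)
      std::memcpy(xp + plane * c + (size_t)Hp * (w_ + 1) + 1,
                  x + (size_t)H * W * c + (size_t)H * w_,
                  sizeof(double) * H);
}
static void from_pad(const double* xp, double* x, int H, int W, int C,
                     double add = 0.0) {
  const int Hp = H + 2;
  const size_t plane = (size_t)Hp * (W + 2);
  for (int c = 0; c < C; ++c)
    for (int w_ = 0; w_ < W; ++w_) {
      const double* src = xp + plane * c + (size_t)Hp * (w_ + 1) + 1;
      double* dst = x + (size_t)H * W * c + (size_t)H * w_;
      for (int h_ = 0; h_ < H; ++h_) dst[h_] = src[h_] + add;
    }
}

// Same-padded stride-1 3x3 convolution. x: (H,W,C,B), w: (3,3,C,O), b: O.
// [[Rcpp::export]]
NumericVector conv2d_fw_cpp(NumericVector x, NumericVector w,
                            NumericVector b, IntegerVector dims) {
  const int H = dims[0], W = dims[1], C = dims[2], B = dims[3];
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], O = wd[3];
  const size_t HW = (size_t)H * W;
  NumericVector y(HW * O * B);
  y.attr("dim") = IntegerVector::create(H, W, O, B);
  if (k != 3) stop("only 3x3 kernels are supported");
  const int Hp = H + 2, Wp = W + 2;
  const size_t plane = (size_t)Hp * Wp;
  const int s = Hp + 1;                       // address of interior (0,0)
  const int n = (int)(plane - 2 * s);         // rows spanning the interior
  std::vector<double> xpad(plane * C), ypad(plane * O);
  std::vector<double> wbuf(9 * C * O);        // tap-major (C x O) blocks
  for (int t = 0; t < 9; ++t)
    for (int o = 0; o < O; ++o)
      for (int c = 0; c < C; ++c)
        wbuf[t * C * O + o * C + c] = w[t + 9 * c + 9 * C * o];
  const double one = 1.0, zero = 0.0;
  const int ld = (int)plane;
  for (int bb = 0; bb < B; ++bb) {
    to_pad(x.begin() + HW * C * bb, xpad.data(), H, W, C);
    std::memset(ypad.data(), 0, sizeof(double) * plane * O);
    for (int j = 0; j < 3; ++j)
      for (int i = 0; i < 3; ++i) {
        const int off = (i - 1) + Hp * (j - 1);
        const int t = i + 3 * j;
        F77_CALL(dgemm)("N", "N", &n, &O, &C, &one,
                        xpad.data() + s + off, &ld,
                        wbuf.data() + t * C * O, &C, &one,
                        ypad.data() + s, &ld FCONE FCONE);
      }
    for (int o = 0; o < O; ++o)
      from_pad(ypad.data() + plane * o, y.begin() + HW * (o + (size_t)O * bb),
               H, W, 1, b[o]);
  }
  return y;
}

// Backward pass of the 3x3 convolution. Returns dx, dw, db.
// [[Rcpp::export]]
List conv2d_bw_cpp(NumericVector x, NumericVector w, NumericVector dy,
                   IntegerVector dims) {
  const int H = dims[0], W = dims[1], C = dims[2], B = dims[3];
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], O = wd[3];
  if (k != 3) stop("only 3x3 kernels are supported");
  const size_t HW = (size_t)H * W;
  const int Hp = H + 2, Wp = W + 2;
  const size_t plane = (size_t)Hp * Wp;
  const int s = Hp + 1;
  const int n = (int)(plane - 2 * s);
  const int ld = (int)plane;
  const double one = 1.0;
  NumericVector dx(HW * C * B);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  NumericVector dwR((size_t)9 * C * O);
  dwR.attr("dim") = wd;
  NumericVector dbR(O);
  std::vector<double> xpad(plane * C), dypad(plane * O), dxpad(plane * C);
  std::vector<double> wbufT(9 * C * O);       // tap-major (O x C) blocks
  std::vector<double> dwbuf(9 * C * O, 0.0);  // tap-major (C x O) blocks
  for (int t = 0; t < 9; ++t)
    for (int o = 0; o < O; ++o)
      for (int c = 0; c < C; ++c)
        wbufT[t * C * O + c * O + o] = w[t + 9 * c + 9 * C * o];
  for (int bb = 0; bb < B; ++bb) {
    to_pad(x.begin() + HW * C * bb, xpad.data(), H, W, C);
    to_pad(dy.begin() + HW * O * bb, dypad.data(), H, W, O);
    std::memset(dxpad.data(), 0, sizeof(double) * plane * C);
    for (int j = 0; j < 3; ++j)
      for (int i = 0; i < 3; ++i) {
        const int off = (i - 1) + Hp * (j - 1);
        const int t = i + 3 * j;
        // dW_t += Xpad(view off)' * dY   ((C x n) . (n x O))
        F77_CALL(dgemm)("T", "N", &C, &O, &n, &one,
                        xpad.data() + s + off, &ld,
                        dypad.data() + s, &ld, &one,
                        dwbuf.data() + t * C * O, &C FCONE FCONE);
        // dXpad(view off) += dY * W_t'   ((n x O) . (O x C))
        F77_CALL(dgemm)("N", "N", &n, &C, &O, &one,
                        dypad.data() + s, &ld,
                        wbufT.data() + t * C * O, &O, &one,
                        dxpad.data() + s + off, &ld FCONE FCONE);
      }
    from_pad(dxpad.data(), dx.begin() + HW * C * bb, H, W, C);
    for (int o = 0; o < O; ++o) {
      const double* d = dy.begin() + HW * (o + (size_t)O * bb);
      double acc = 0.0;
      for (size_t p = 0; p < HW; ++p) acc += d[p];
      dbR[o] += acc;
    }
  }
  for (int t = 0; t < 9; ++t)
    for (int o = 0; o < O; ++o)
      for (int c = 0; c < C; ++c)
        dwR[t + 9 * c + 9 * C * o] = dwbuf[t * C * O + o * C + c];
  return List::create(_["dx"] = dx, _["dw"] = dwR, _["db"] = dbR);
}

// 2x2 max pooling (H, W even). Returns pooled values and flat argmax.
// [[Rcpp::export]]
List maxpool2_fw_cpp(NumericVector x, IntegerVector dims) {
  const int H = dims[0], W = dims[1], C = dims[2], B = dims[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  IntegerVector am((size_t)Ho * Wo * C * B);
  size_t o = 0;
  for (int bb = 0; bb < B; ++bb)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + C * bb);
      for (int w_ = 0; w_ < Wo; ++w_)
        for (int h_ = 0; h_ < Ho; ++h_) {
          int base = 2 * h_ + H * 2 * w_;
          int idx[4] = {base, base + 1, base + H, base + H + 1};
          int best = idx[0];
          double bv = xc[idx[0]];
          for (int t = 1; t < 4; ++t)
            if (xc[idx[t]] > bv) { bv = xc[idx[t]]; best = idx[t]; }
          y[o] = bv;
          am[o] = best + (int)((size_t)H * W * (c + C * bb));
          ++o;
        }
    }
  return List::create(_["y"] = y, _["argmax"] = am);
}

// [[Rcpp::export]]
NumericVector maxpool2_bw_cpp(NumericVector dy, IntegerVector argmax,
                              IntegerVector dims_in) {
  NumericVector dx((size_t)dims_in[0] * dims_in[1] * dims_in[2] * dims_in[3]);
  dx.attr("dim") = dims_in;
  const int n = dy.size();
  for (int i = 0; i < n; ++i) dx[argmax[i]] += dy[i];
  return dx;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export]]
NumericVector upsample2_fw_cpp(NumericVector x, IntegerVector dims) {
  const int H = dims[0], W = dims[1], C = dims[2], B = dims[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * C * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  for (int bb = 0; bb < B; ++bb)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + C * bb);
      double* yc = y.begin() + (size_t)Ho * Wo * (c + C * bb);
      for (int w_ = 0; w_ < Wo; ++w_)
        for (int h_ = 0; h_ < Ho; ++h_)
          yc[h_ + Ho * w_] = xc[(h_ / 2) + H * (w_ / 2)];
    }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_bw_cpp(NumericVector dy, IntegerVector dims_in) {
  const int H = dims_in[0], W = dims_in[1], C = dims_in[2], B = dims_in[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx((size_t)H * W * C * B);
  dx.attr("dim") = dims_in;
  for (int bb = 0; bb < B; ++bb)
    for (int c = 0; c < C; ++c) {
      const double* dyc = dy.begin() + (size_t)Ho * Wo * (c + C * bb);
      double* dxc = dx.begin() + (size_t)H * W * (c + C * bb);
      for (int w_ = 0; w_ < Wo; ++w_)
        for (int h_ = 0; h_ < Ho; ++h_)
          dxc[(h_ / 2) + H * (w_ / 2)] += dyc[h_ + Ho * w_];
    }
  return dx;
}
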