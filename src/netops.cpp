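#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static void get_dim4(const NumericVector& x, int* d) {
  IntegerVector dim = x.attr("dim");
  if (dim.size() != 4) stop("expected a 4-d array");
  for (int i = 0; i < 4; ++i) d[i] = dim[i];
}

// 'same' 2-d convolution (zero padding) over a batch.
// x: (H, W, Cin, N); w: (k, k, Cin, Cout); b: Cout.  Returns (H, W, Cout, N).
// [[Rcpp::export]]
NumericVector conv2d_same_cpp(const NumericVector& x, const NumericVector& w,
                              const NumericVector& b, bool relu) {
  int xd[4], wd[4];
  get_dim4(x, xd);
  get_dim4(w, wd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], K = wd[3];
  if (wd[1] != k || wd[2] != C) stop("weight dims do not match input channels");
  if (b.size() != K) stop("bias length mismatch");
  const int r = k / 2;
  NumericVector out((R_xlen_t)H * W * K * N);
  out.attr("dim") = IntegerVector::create(H, W, K, N);
  const double* px = x.begin();
  const double* pw = w.begin();
  double* po = out.begin();
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < K; ++co) {
      double* o = po + ((R_xlen_t)n * K + co) * H * W;
      const double bias = b[co];
      for (R_xlen_t t = 0; t < (R_xlen_t)H * W; ++t) o[t] = bias;
      for (int c = 0; c < C; ++c) {
        const double* xs = px + ((R_xlen_t)n * C + c) * H * W;
        for (int kj = 0; kj < k; ++kj) {
          const int dj = kj - r;
          for (int ki = 0; ki < k; ++ki) {
            const int di = ki - r;
            const double wv = pw[ki + k * (kj + k * (c + C * co))];
            if (wv == 0.0) continue;
            const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
            const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
            for (int j = j0; j < j1; ++j) {
              const double* xcol = xs + (R_xlen_t)(j + dj) * H + di;
              double* ocol = o + (R_xlen_t)j * H;
              for (int i = i0; i < i1; ++i) ocol[i] += wv * xcol[i];
            }
          }
        }
      }
      if (relu)
        for (R_xlen_t t = 0; t < (R_xlen_t)H * W; ++t)
          if (o[t] < 0) o[t] = 0;
    }
  }
  return out;
}

// 2x2 stride-2 pooling over a batch; odd trailing row/column is dropped.
// x: (H, W, C, N) -> (H/2, W/2, C, N).  mode 0 = max, 1 = average.
// [[Rcpp::export]]
NumericVector pool2_cpp(const NumericVector& x, int mode) {
  int xd[4];
  get_dim4(x, xd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  if (Ho < 1 || Wo < 1) stop("feature map too small to pool");
  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* px = x.begin();
  double* po = out.begin();
  for (R_xlen_t nc = 0; nc < (R_xlen_t)N * C; ++nc) {
    const double* xs = px + nc * H * W;
    double* o = po + nc * Ho * Wo;
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const double a = xs[2 * i + H * (2 * j)];
        const double b = xs[2 * i + 1 + H * (2 * j)];
        const double c = xs[2 * i + H * (2 * j + 1)];
        const double d = xs[2 * i + 1 + H * (2 * j + 1)];
        o[i + (R_xlen_t)Ho * j] =
            mode == 0 ? std::max(std::max(a, b), std::max(c, d))
                      : 0.25 * (a + b + c + d);
      }
  }
  return out;
}

// Per-channel spatial mean (global average pooling) over a batch.
// x: (H, W, C, N) -> matrix N x C.
// [[Rcpp::export]]
NumericMatrix gap_cpp(const NumericVector& x) {
  int xd[4];
  get_dim4(x, xd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericMatrix out(N, C);
  const double* px = x.begin();
  const double inv = 1.0 / ((double)H * W);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = px + ((R_xlen_t)n * C + c) * H * W;
      double acc = 0.0;
      for (R_xlen_t t = 0; t < (R_xlen_t)H * W; ++t) acc += xs[t];
      out(n, c) = acc * inv;
    }
  return out;
}

// Fused per-column affine (x * scale + offset per column) with optional ReLU;
// the workhorse for batch-norm affines and bias-add layers, avoiding R-level
// sweep()/pmax() allocations on large matrices.
// [[Rcpp::export]]
NumericMatrix affine_cols_cpp(const NumericMatrix& x, const NumericVector& scale,
                              const NumericVector& offset, bool relu) {
  const int n = x.nrow(), C = x.ncol();
  if (scale.size() != C || offset.size() != C) stop("scale/offset length mismatch");
  NumericMatrix out(n, C);
  for (int j = 0; j < C; ++j) {
    const double s = scale[j], o = offset[j];
    const double* xs = &x(0, j);
    double* os = &out(0, j);
    for (int i = 0; i < n; ++i) {
      double v = xs[i] * s + o;
      os[i] = (relu && v < 0) ? 0.0 : v;
    }
  }
  return out;
}

// Per-channel sum and sum of squares over each item's spatial map.
// x: (H, W, C, N) -> list(sum = N x C, sumsq = N x C).  Feeds exact batch-norm
// statistics for cached-activation training.
// [[Rcpp::export]]
List channel_moments_cpp(const NumericVector& x) {
  int xd[4];
  get_dim4(x, xd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericMatrix s(N, C), q(N, C);
  const double* px = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = px + ((R_xlen_t)n * C + c) * H * W;
      double acc = 0.0, acc2 = 0.0;
      for (R_xlen_t t = 0; t < (R_xlen_t)H * W; ++t) {
        acc += xs[t];
        acc2 += xs[t] * xs[t];
      }
      s(n, c) = acc;
      q(n, c) = acc2;
    }
  return List::create(_["sum"] = s, _["sumsq"] = q);
}
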