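#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>
using namespace Rcpp;

// symmetric (edge-including) reflection of an index into [0, n)
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix median_filter_cpp(const NumericMatrix& img, int k) {
  if (k < 1 || k % 2 == 0) stop("kernel must be an odd positive integer");
  const int H = img.nrow(), W = img.ncol(), r = k / 2;
  NumericMatrix out(H, W);
  std::vector<double> win(k * k);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      int m = 0;
      for (int dj = -r; dj <= r; ++dj) {
        const int jj = reflect_idx(j + dj, W);
        for (int di = -r; di <= r; ++di)
          win[m++] = img(reflect_idx(i + di, H), jj);
      }
      std::nth_element(win.begin(), win.begin() + m / 2, win.begin() + m);
      out(i, j) = win[m / 2];
    }
  }
  return out;
}

// CLAHE on an 8-bit image.  Tiles of ceil(H/tr) x ceil(W/tc); the image is
// padded by symmetric reflection so every tile is full.  Per-tile 256-bin
// histogram is clipped at clip_limit * tile_pixels / 256 (floor 1) with the
// excess redistributed uniformly; the per-tile LUT is the rescaled CDF and
// pixels are mapped by bilinear interpolation between the 4 nearest tile LUTs.
// [[Rcpp::export]]
NumericMatrix clahe_cpp(const NumericMatrix& img, double clip_limit,
                        int tiles_r, int tiles_c) {
  if (clip_limit <= 0) stop("clip_limit must be > 0");
  if (tiles_r < 1 || tiles_c < 1) stop("tile grid must be >= 1");
  const int H = img.nrow(), W = img.ncol();
  const int th = (H + tiles_r - 1) / tiles_r;
  const int tw = (W + tiles_c - 1) / tiles_c;
  const double npix = (double)th * tw;
  double clip = clip_limit * npix / 256.0;
  if (clip < 1.0) clip = 1.0;

  // LUTs: tiles_r x tiles_c x 256
  std::vector<double> lut((size_t)tiles_r * tiles_c * 256);
  std::vector<double> hist(256);
  for (int tr = 0; tr < tiles_r; ++tr) {
    for (int tc = 0; tc < tiles_c; ++tc) {
      std::fill(hist.begin(), hist.end(), 0.0);
      for (int j = 0; j < tw; ++j) {
        const int jj = reflect_idx(tc * tw + j, W);
        for (int i = 0; i < th; ++i) {
          int v = (int)img(reflect_idx(tr * th + i, H), jj);
          if (v < 0) v = 0;
          if (v > 255) v = 255;
          hist[v] += 1.0;
        }
      }
      double excess = 0.0;
      for (int b = 0; b < 256; ++b)
        if (hist[b] > clip) { excess += hist[b] - clip; hist[b] = clip; }
      const double add = excess / 256.0;
      double cdf = 0.0;
      double* L = &lut[((size_t)tr * tiles_c + tc) * 256];
      for (int b = 0; b < 256; ++b) {
        cdf += hist[b] + add;
        L[b] = cdf * 255.0 / npix;
      }
    }
  }

  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j) {
    double gx = (j + 0.5) / tw - 0.5;
    int x0 = (int)std::floor(gx);
    double wx = gx - x0;
    int x1 = x0 + 1;
    if (x0 < 0) { x0 = 0; x1 = 0; wx = 0.0; }
    if (x1 > tiles_c - 1) { x1 = tiles_c - 1; if (x0 > x1) x0 = x1; }
    for (int i = 0; i < H; ++i) {
      double gy = (i + 0.5) / th - 0.5;
      int y0 = (int)std::floor(gy);
      double wy = gy - y0;
      int y1 = y0 + 1;
      if (y0 < 0) { y0 = 0; y1 = 0; wy = 0.0; }
      if (y1 > tiles_r - 1) { y1 = tiles_r - 1; if (y0 > y1) y0 = y1; }
      int v = (int)img(i, j);
      if (v < 0) v = 0;
      if (v > 255) v = 255;
      const double v00 = lut[((size_t)y0 * tiles_c + x0) * 256 + v];
      const double v01 = lut[((size_t)y0 * tiles_c + x1) * 256 + v];
      const double v10 = lut[((size_t)y1 * tiles_c + x0) * 256 + v];
      const double v11 = lut[((size_t)y1 * tiles_c + x1) * 256 + v];
      double val = (1 - wy) * ((1 - wx) * v00 + wx * v01) +
                   wy * ((1 - wx) * v10 + wx * v11);
      if (val < 0) val = 0;
      if (val > 255) val = 255;
      out(i, j) = std::floor(val + 0.5);
    }
  }
  return out;
}

// Morphological closing (dilation then erosion) with a disk structuring
// element.  Out-of-image neighbours are ignored for dilation and treated as
// foreground for erosion, so regions touching the border are preserved.
// [[Rcpp::export]]
LogicalMatrix binary_close_cpp(const LogicalMatrix& mask, int radius) {
  const int H = mask.nrow(), W = mask.ncol();
  std::vector<std::pair<int, int> > disk;
  for (int di = -radius; di <= radius; ++di)
    for (int dj = -radius; dj <= radius; ++dj)
      if (di * di + dj * dj <= radius * radius) disk.push_back({di, dj});
  LogicalMatrix dil(H, W), out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      bool any = false;
      for (size_t s = 0; s < disk.size() && !any; ++s) {
        const int ii = i + disk[s].first, jj = j + disk[s].second;
        if (ii >= 0 && ii < H && jj >= 0 && jj < W && mask(ii, jj)) any = true;
      }
      dil(i, j) = any;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      bool all = true;
      for (size_t s = 0; s < disk.size() && all; ++s) {
        const int ii = i + disk[s].first, jj = j + disk[s].second;
        if (ii >= 0 && ii < H && jj >= 0 && jj < W && !dil(ii, jj)) all = false;
      }
      out(i, j) = all;
    }
  return out;
}

// Largest 8-connected component of a binary mask; all-false if mask is empty.
// [[Rcpp::export]]
LogicalMatrix largest_component_cpp(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  std::vector<int> label((size_t)H * W, 0);
  int next = 0, best_lab = 0;
  size_t best_size = 0;
  std::vector<std::pair<int, int> > stack;
  for (int j0 = 0; j0 < W; ++j0)
    for (int i0 = 0; i0 < H; ++i0) {
      if (!mask(i0, j0) || label[(size_t)i0 + (size_t)H * j0]) continue;
      ++next;
      size_t sz = 0;
      stack.clear();
      stack.push_back({i0, j0});
      label[(size_t)i0 + (size_t)H * j0] = next;
      while (!stack.empty()) {
        const int i = stack.back().first, j = stack.back().second;
        stack.pop_back();
        ++sz;
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            const int ii = i + di, jj = j + dj;
            if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
            if (mask(ii, jj) && !label[(size_t)ii + (size_t)H * jj]) {
              label[(size_t)ii + (size_t)H * jj] = next;
              stack.push_back({ii, jj});
            }
          }
      }
      if (sz > best_size) { best_size = sz; best_lab = next; }
    }
  LogicalMatrix out(H, W);
  if (best_lab)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        out(i, j) = (label[(size_t)i + (size_t)H * j] == best_lab);
  return out;
}

// Bilinear resize with align-corners index mapping (identity when the size is
// unchanged; constants are preserved exactly).
// [[Rcpp::export]]
NumericMatrix bilinear_resize_cpp(const NumericMatrix& img, int out_h, int out_w) {
  const int H = img.nrow(), W = img.ncol();
  if (H < 1 || W < 1 || out_h < 1 || out_w < 1) stop("empty image or target");
  NumericMatrix out(out_h, out_w);
  const double sy = out_h > 1 ? (double)(H - 1) / (out_h - 1) : 0.0;
  const double sx = out_w > 1 ? (double)(W - 1) / (out_w - 1) : 0.0;
  for (int j = 0; j < out_w; ++j) {
    const double x = out_w > 1 ? j * sx : (W - 1) / 2.0;
    int x0 = (int)std::floor(x);
    if (x0 > W - 2) x0 = W > 1 ? W - 2 : 0;
    const int x1 = W > 1 ? x0 + 1 : 0;
    const double fx = x - x0;
    for (int i = 0; i < out_h; ++i) {
      const double y = out_h > 1 ? i * sy : (H - 1) / 2.0;
      int y0 = (int)std::floor(y);
      if (y0 > H - 2) y0 = H > 1 ? H - 2 : 0;
      const int y1 = H > 1 ? y0 + 1 : 0;
      const double fy = y - y0;
      out(i, j) = (1 - fy) * ((1 - fx) * img(y0, x0) + fx * img(y0, x1)) +
                  fy * ((1 - fx) * img(y1, x0) + fx * img(y1, x1));
    }
  }
  return out;
}

// Separable Gaussian blur (reflect borders); used by the phantom texture.
// [[Rcpp::export]]
NumericMatrix gaussian_blur_cpp(const NumericMatrix& img, double sigma) {
  if (sigma <= 0) return clone(img);
  const int H = img.nrow(), W = img.ncol();
  const int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * r + 1);
  double s = 0.0;
  for (int d = -r; d <= r; ++d) { ker[d + r] = std::exp(-0.5 * d * d / (sigma * sigma)); s += ker[d + r]; }
  for (double& k : ker) k /= s;
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d) acc += ker[d + r] * img(reflect_idx(i + d, H), j);
      tmp(i, j) = acc;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d) acc += ker[d + r] * tmp(i, reflect_idx(j + d, W));
      out(i, j) = acc;
    }
  return out;
}
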