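#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int mirror_index(int i, int n) {
  // reflect with edge duplication: -1 -> 0, n -> n-1, iterated for far indices
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Contrast-limited adaptive histogram equalization.
// The image is conceptually padded by mirroring so every block is full-size;
// per-block histograms (`bins` bins over [vmin, vmax]) are clipped at
// slope * block_px / bins with the clipped mass redistributed uniformly
// (single pass), turned into CDF mappings, and pixel values are mapped with
// bilinear interpolation between the four surrounding block centers.
// Blocks with a degenerate histogram (a single occupied bin) map identically.
// [[Rcpp::export]]
NumericMatrix cpp_clahe(const NumericMatrix& img, int block, int bins,
                        double slope, double vmin, double vmax) {
  const int H = img.nrow(), W = img.ncol();
  const int nby = (H + block - 1) / block;
  const int nbx = (W + block - 1) / block;
  const double range = vmax - vmin;
  NumericMatrix out(H, W);
  if (range <= 0) {  // constant image: nothing to equalize
    std::copy(img.begin(), img.end(), out.begin());
    return out;
  }
  const double clip = slope * (double)block * block / bins;
  // per-block mappings: map[b] for bin b, plus degeneracy flag
  std::vector<std::vector<double> > maps((size_t)nby * nbx,
                                         std::vector<double>(bins, 0.0));
  std::vector<char> degen((size_t)nby * nbx, 0);
  std::vector<double> hist(bins);
  for (int by = 0; by < nby; ++by)
    for (int bx = 0; bx < nbx; ++bx) {
      std::fill(hist.begin(), hist.end(), 0.0);
      for (int y = by * block; y < (by + 1) * block; ++y)
        for (int x = bx * block; x < (bx + 1) * block; ++x) {
          double v = img(mirror_index(y, H), mirror_index(x, W));
          int b = (int)((v - vmin) / range * bins);
          if (b < 0) b = 0;
          if (b >= bins) b = bins - 1;
          hist[b] += 1.0;
        }
      // clip and redistribute once
      if (R_finite(clip)) {
        double excess = 0.0;
        for (int b = 0; b < bins; ++b)
          if (hist[b] > clip) { excess += hist[b] - clip; hist[b] = clip; }
        double add = excess / bins;
        for (int b = 0; b < bins; ++b) hist[b] += add;
      }
      int occupied = 0;
      for (int b = 0; b < bins; ++b) if (hist[b] > 0) ++occupied;
      std::vector<double>& m = maps[(size_t)by * nbx + bx];
      double total = 0.0;
      for (int b = 0; b < bins; ++b) total += hist[b];
      // classical equalization with cdf-min anchoring
      double cdfmin = 0.0;
      for (int b = 0; b < bins; ++b)
        if (hist[b] > 0) { cdfmin = hist[b]; break; }
      if (occupied <= 1 || total - cdfmin <= 0) {
        degen[(size_t)by * nbx + bx] = 1;
        continue;
      }
      double cum = 0.0;
      for (int b = 0; b < bins; ++b) {
        cum += hist[b];
        double f = (cum - cdfmin) / (total - cdfmin);
        if (f < 0) f = 0;
        m[b] = vmin + f * range;
      }
    }
  // apply with bilinear interpolation between block centers
  for (int x = 0; x < W; ++x) {
    double gx = ((double)x + 0.5) / block - 0.5;
    int bx0 = (int)std::floor(gx);
    double fx = gx - bx0;
    int bxa = bx0 < 0 ? 0 : (bx0 >= nbx ? nbx - 1 : bx0);
    int bxb = bx0 + 1 < 0 ? 0 : (bx0 + 1 >= nbx ? nbx - 1 : bx0 + 1);
    if (bx0 < 0) fx = 1.0;
    if (bx0 + 1 > nbx - 1) fx = 0.0;
    for (int y = 0; y < H; ++y) {
      double gy = ((double)y + 0.5) / block - 0.5;
      int by0 = (int)std::floor(gy);
      double fy = gy - by0;
      int bya = by0 < 0 ? 0 : (by0 >= nby ? nby - 1 : by0);
      int byb = by0 + 1 < 0 ? 0 : (by0 + 1 >= nby ? nby - 1 : by0 + 1);
      if (by0 < 0) fy = 1.0;
      if (by0 + 1 > nby - 1) fy = 0.0;
      double v = img(y, x);
      int b = (int)((v - vmin) / range * bins);
      if (b < 0) b = 0;
      if (b >= bins) b = bins - 1;
      size_t i00 = (size_t)bya * nbx + bxa, i01 = (size_t)bya * nbx + bxb;
      size_t i10 = (size_t)byb * nbx + bxa, i11 = (size_t)byb * nbx + bxb;
      double m00 = degen[i00] ? v : maps[i00][b];
      double m01 = degen[i01] ? v : maps[i01][b];
      double m10 = degen[i10] ? v : maps[i10][b];
      double m11 = degen[i11] ? v : maps[i11][b];
      out(y, x) = (1 - fy) * ((1 - fx) * m00 + fx * m01) +
                  fy * ((1 - fx) * m10 + fx * m11);
    }
  }
  return out;
}
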