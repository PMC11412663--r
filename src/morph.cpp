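#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Grayscale opening with a non-flat ball (spherical cap) structuring element.
// Erosion/dilation restricted to in-bounds offsets so a constant image maps to
// itself and opening(x + c) == opening(x) + c for any constant c.
// [[Rcpp::export]]
NumericMatrix cpp_grey_open_ball(const NumericMatrix& img, double radius) {
  const int H = img.nrow(), W = img.ncol();
  const int R = (int)std::floor(radius);
  std::vector<int> dys, dxs;
  std::vector<double> hts;
  for (int dy = -R; dy <= R; ++dy)
    for (int dx = -R; dx <= R; ++dx) {
      double d2 = (double)dy * dy + (double)dx * dx;
      if (d2 <= radius * radius) {
        dys.push_back(dy);
        dxs.push_back(dx);
        hts.push_back(std::sqrt(radius * radius - d2));
      }
    }
  const int K = (int)dys.size();
  NumericMatrix ero(H, W), out(H, W);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      double m = R_PosInf;
      for (int k = 0; k < K; ++k) {
        int yy = y + dys[k], xx = x + dxs[k];
        if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
        double v = img(yy, xx) - hts[k];
        if (v < m) m = v;
      }
      ero(y, x) = m;
    }
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      double m = R_NegInf;
      for (int k = 0; k < K; ++k) {
        int yy = y + dys[k], xx = x + dxs[k];
        if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
        double v = ero(yy, xx) + hts[k];
        if (v > m) m = v;
      }
      out(y, x) = m;
    }
  return out;
}

// Connected-component labeling of a binary image, 4- or 8-connectivity,
// raster-scan seeding so labels are assigned in deterministic row-major
// (top-left first) order, already dense 1..N.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const IntegerMatrix& bin, int connectivity) {
  const int H = bin.nrow(), W = bin.ncol();
  IntegerMatrix lab(H, W);
  std::fill(lab.begin(), lab.end(), 0);
  static const int dy8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dx8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  static const int dy4[4] = {-1, 0, 0, 1};
  static const int dx4[4] = {0, -1, 1, 0};
  const int nn = (connectivity == 4) ? 4 : 8;
  const int* dy = (connectivity == 4) ? dy4 : dy8;
  const int* dx = (connectivity == 4) ? dx4 : dx8;
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      if (bin(y, x) == 0 || lab(y, x) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(y, x));
      lab(y, x) = next;
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int k = 0; k < nn; ++k) {
          int yy = p.first + dy[k], xx = p.second + dx[k];
          if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
          if (bin(yy, xx) != 0 && lab(yy, xx) == 0) {
            lab(yy, xx) = next;
            stack.push_back(std::make_pair(yy, xx));
          }
        }
      }
    }
  return lab;
}

// Fill interior holes of a binary mask: background is flood-filled from the
// border with 4-connectivity (the dual of 8-connected foreground); any zero
// pixel not reached is a hole and becomes foreground.
// [[Rcpp::export]]
IntegerMatrix cpp_fill_holes(const IntegerMatrix& bin) {
  const int H = bin.nrow(), W = bin.ncol();
  IntegerMatrix reach(H, W);
  std::fill(reach.begin(), reach.end(), 0);
  std::vector<std::pair<int, int> > stack;
  for (int x = 0; x < W; ++x) {
    if (bin(0, x) == 0 && !reach(0, x)) { reach(0, x) = 1; stack.push_back(std::make_pair(0, x)); }
    if (bin(H - 1, x) == 0 && !reach(H - 1, x)) { reach(H - 1, x) = 1; stack.push_back(std::make_pair(H - 1, x)); }
  }
  for (int y = 0; y < H; ++y) {
    if (bin(y, 0) == 0 && !reach(y, 0)) { reach(y, 0) = 1; stack.push_back(std::make_pair(y, 0)); }
    if (bin(y, W - 1) == 0 && !reach(y, W - 1)) { reach(y, W - 1) = 1; stack.push_back(std::make_pair(y, W - 1)); }
  }
  static const int dy4[4] = {-1, 0, 0, 1};
  static const int dx4[4] = {0, -1, 1, 0};
  while (!stack.empty()) {
    std::pair<int, int> p = stack.back();
    stack.pop_back();
    for (int k = 0; k < 4; ++k) {
      int yy = p.first + dy4[k], xx = p.second + dx4[k];
      if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
      if (bin(yy, xx) == 0 && !reach(yy, xx)) {
        reach(yy, xx) = 1;
        stack.push_back(std::make_pair(yy, xx));
      }
    }
  }
  IntegerMatrix out(H, W);
  for (int i = 0; i < H * W; ++i) out[i] = (bin[i] != 0 || !reach[i]) ? 1 : 0;
  return out;
}
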