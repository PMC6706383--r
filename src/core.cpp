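#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// 8-neighbourhood offsets; the first four entries are the 4-neighbourhood.
static const int DR[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
static const int DC[8] = {0, 0, -1, 1, -1, 1, -1, 1};

// Label connected foreground components.  Labels are assigned in scan order
// (column-major, matching R's storage) and are contiguous 1..K.
// [[Rcpp::export]]
IntegerMatrix cpp_label(const IntegerMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  const int nb = (connectivity == 4) ? 4 : 8;
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  stack.reserve(256);
  int next = 0;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * H);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int rr = idx % H, cc = idx / H;
        for (int k = 0; k < nb; ++k) {
          int nr = rr + DR[k], nc = cc + DC[k];
          if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
          if (mask(nr, nc) != 0 && lab(nr, nc) == 0) {
            lab(nr, nc) = next;
            stack.push_back(nr + nc * H);
          }
        }
      }
    }
  }
  return lab;
}

// Size of the 8-connected component containing (row0, col0), evaluated only
// among pixels inside the eps x eps window centred on the seed (window
// clipped at image borders).  row0/col0 are 0-based.
static int connected_mass_core(const IntegerMatrix& mask, int row0, int col0,
                               int eps) {
  const int H = mask.nrow(), W = mask.ncol();
  const int h = eps / 2;
  const int rlo = std::max(0, row0 - h), rhi = std::min(H - 1, row0 + h);
  const int clo = std::max(0, col0 - h), chi = std::min(W - 1, col0 + h);
  const int wh = rhi - rlo + 1, ww = chi - clo + 1;
  std::vector<char> seen(static_cast<size_t>(wh) * ww, 0);
  std::vector<int> stack;
  stack.reserve(static_cast<size_t>(wh) * ww);
  int count = 1;
  seen[(row0 - rlo) + (col0 - clo) * wh] = 1;
  stack.push_back((row0 - rlo) + (col0 - clo) * wh);
  while (!stack.empty()) {
    int idx = stack.back();
    stack.pop_back();
    int wr = idx % wh, wc = idx / wh;
    for (int k = 0; k < 8; ++k) {
      int nr = wr + DR[k], nc = wc + DC[k];
      if (nr < 0 || nr >= wh || nc < 0 || nc >= ww) continue;
      int lidx = nr + nc * wh;
      if (seen[lidx]) continue;
      if (mask(rlo + nr, clo + nc) != 0) {
        seen[lidx] = 1;
        ++count;
        stack.push_back(lidx);
      }
    }
  }
  return count;
}

// [[Rcpp::export]]
int cpp_connected_mass(const IntegerMatrix& mask, int row0, int col0,
                       int eps) {
  return connected_mass_core(mask, row0, col0, eps);
}

// Connected masses M(eps) at one seed pixel for a vector of window sides.
// [[Rcpp::export]]
IntegerVector cpp_masses(const IntegerMatrix& mask, int row0, int col0,
                         const IntegerVector& scales) {
  IntegerVector out(scales.size());
  for (int i = 0; i < scales.size(); ++i)
    out[i] = connected_mass_core(mask, row0, col0, scales[i]);
  return out;
}

// Per-pixel LCFD map: OLS slope of log M(eps) on log eps at every foreground
// pixel (windows clipped at the borders); background pixels are 0.
// [[Rcpp::export]]
NumericMatrix cpp_lcfd_map(const IntegerMatrix& mask,
                           const IntegerVector& scales) {
  const int H = mask.nrow(), W = mask.ncol();
  const int S = scales.size();
  std::vector<double> lx(S);
  double mlx = 0.0;
  for (int i = 0; i < S; ++i) {
    lx[i] = std::log(static_cast<double>(scales[i]));
    mlx += lx[i];
  }
  mlx /= S;
  double sxx = 0.0;
  for (int i = 0; i < S; ++i) sxx += (lx[i] - mlx) * (lx[i] - mlx);
  NumericMatrix out(H, W);
  std::vector<double> ly(S);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0) continue;
      double mly = 0.0;
      for (int i = 0; i < S; ++i) {
        ly[i] = std::log(
            static_cast<double>(connected_mass_core(mask, r, c, scales[i])));
        mly += ly[i];
      }
      mly /= S;
      double sxy = 0.0;
      for (int i = 0; i < S; ++i) sxy += (lx[i] - mlx) * (ly[i] - mly);
      out(r, c) = sxy / sxx;
    }
  }
  return out;
}
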