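#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// neighbor offsets for 6/18/26 3-D connectivity
static std::vector<std::array<int, 3>> neighbor_offsets(int connectivity) {
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int nz = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (nz == 0) continue;
        if (connectivity == 6 && nz > 1) continue;
        if (connectivity == 18 && nz > 2) continue;
        offs.push_back({dx, dy, dz});
      }
  return offs;
}

// Threshold-free cluster enhancement of a statistic volume.
// score(v) = sum over thresholds h = dh, 2dh, ... <= t(v) of
//            e_h(v)^E * h^H * dh,
// where e_h(v) is the voxel count of the connected component containing v in
// the suprathreshold set {t >= h}. Negative values score 0 (callers pass -t
// for the negative direction).
// [[Rcpp::export]]
NumericVector tfce_cpp(NumericVector t, IntegerVector dims, double E,
                       double H, double dh, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  NumericVector out(n);
  double tmax = 0.0;
  for (int i = 0; i < n; ++i) if (t[i] > tmax) tmax = t[i];
  if (tmax <= 0.0 || dh <= 0.0) return out;
  const int nsteps = (int)std::floor(tmax / dh + 1e-7);
  if (nsteps < 1) return out;
  auto offs = neighbor_offsets(connectivity);

  std::vector<int> label(n), stack(n), members(n);
  for (int s = 1; s <= nsteps; ++s) {
    const double h = s * dh;
    const double hpow = std::pow(h, H) * dh;
    std::fill(label.begin(), label.end(), 0);
    int next_label = 0;
    for (int seed = 0; seed < n; ++seed) {
      if (t[seed] < h || label[seed]) continue;
      ++next_label;
      int top = 0, nmem = 0;
      stack[top++] = seed;
      label[seed] = next_label;
      while (top > 0) {
        int v = stack[--top];
        members[nmem++] = v;
        int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
        for (auto &o : offs) {
          int xx = x + o[0], yy = y + o[1], zz = z + o[2];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          int u = xx + nx * (yy + ny * zz);
          if (t[u] >= h && !label[u]) {
            label[u] = next_label;
            stack[top++] = u;
          }
        }
      }
      const double add = std::pow((double)nmem, E) * hpow;
      for (int j = 0; j < nmem; ++j) out[members[j]] += add;
    }
  }
  return out;
}
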