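#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Neighbour offsets for 6/18/26 lattice connectivity.
static std::vector<std::array<int, 3>> conn_offsets(int connectivity) {
  std::vector<std::array<int, 3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int nz = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (nz == 0) continue;
        if (connectivity == 6 && nz > 1) continue;
        if (connectivity == 18 && nz > 2) continue;
        off.push_back({dx, dy, dz});
      }
  return off;
}

// Label connected components of `mask` (non-zero voxels). Labels are 1..k in
// discovery order; background is 0.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  std::vector<std::array<int, 3>> off = conn_offsets(connectivity);
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (size_t k = 0; k < off.size(); ++k) {
        int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int w = xx + nx * (yy + ny * zz);
        if (mask[w] && lab[w] == 0) {
          lab[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  return lab;
}

// One-sided TFCE on a non-negative map: for each voxel the Riemann sum over
// thresholds h = dh, 2dh, ... of extent(v,h)^E * h^H * dh, where extent is the
// size of the suprathreshold connected component containing v.
static std::vector<double> tfce_pos(const std::vector<double> &vol, int nx,
                                    int ny, int nz, double E, double H,
                                    double dh, int connectivity) {
  const int n = nx * ny * nz;
  std::vector<double> out(n, 0.0);
  double vmax = 0.0;
  for (int i = 0; i < n; ++i) vmax = std::max(vmax, vol[i]);
  if (vmax <= 0.0) return out;
  int nsteps = (int)std::floor(vmax / dh + 1e-9);
  std::vector<std::array<int, 3>> off = conn_offsets(connectivity);
  std::vector<int> lab(n), stack;
  std::vector<double> csize;
  for (int s = 1; s <= nsteps; ++s) {
    double h = s * dh;
    std::fill(lab.begin(), lab.end(), 0);
    csize.assign(1, 0.0); // csize[label], label 0 unused
    int next = 0;
    for (int i = 0; i < n; ++i) {
      if (vol[i] < h || lab[i] != 0) continue;
      ++next;
      csize.push_back(0.0);
      lab[i] = next;
      csize[next] += 1.0;
      stack.push_back(i);
      while (!stack.empty()) {
        int v = stack.back();
        stack.pop_back();
        int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
        for (size_t k = 0; k < off.size(); ++k) {
          int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          int w = xx + nx * (yy + ny * zz);
          if (vol[w] >= h && lab[w] == 0) {
            lab[w] = next;
            csize[next] += 1.0;
            stack.push_back(w);
          }
        }
      }
    }
    double hH = std::pow(h, H) * dh;
    for (int i = 0; i < n; ++i)
      if (lab[i] != 0) out[i] += std::pow(csize[lab[i]], E) * hH;
  }
  return out;
}

// Signed TFCE: positive and negative lobes enhanced separately on |map|.
// [[Rcpp::export(name = ".tfce_cpp")]]
NumericVector tfce_cpp(NumericVector vol, IntegerVector dim, double E,
                       double H, double dh, int connectivity) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  if (vol.size() != n) stop("volume length does not match dim");
  std::vector<double> pos(n, 0.0), neg(n, 0.0);
  bool any_neg = false;
  for (int i = 0; i < n; ++i) {
    double v = vol[i];
    pos[i] = v > 0 ? v : 0.0;
    neg[i] = v < 0 ? -v : 0.0;
    if (v < 0) any_neg = true;
  }
  std::vector<double> ep = tfce_pos(pos, nx, ny, nz, E, H, dh, connectivity);
  NumericVector out(n);
  if (any_neg) {
    std::vector<double> en = tfce_pos(neg, nx, ny, nz, E, H, dh, connectivity);
    for (int i = 0; i < n; ++i) out[i] = ep[i] - en[i];
  } else {
    for (int i = 0; i < n; ++i) out[i] = ep[i];
  }
  return out;
}

// Direct-form II transposed IIR filter, a[0]-normalised (single pass).
// [[Rcpp::export(name = ".iir_filter_cpp")]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x) {
  int nb = b.size(), na = a.size(), n = x.size();
  int m = std::max(nb, na);
  std::vector<double> bb(m, 0.0), aa(m, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a[0];
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a[0];
  std::vector<double> z(m, 0.0);
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + z[0];
    for (int j = 1; j < m; ++j) z[j - 1] = bb[j] * xi + z[j] - aa[j] * yi;
    y[i] = yi;
  }
  return y;
}

static double trimmed_mean(std::vector<double> &v, double trim) {
  int n = v.size();
  int g = (int)std::floor(n * trim);
  std::sort(v.begin(), v.end());
  double s = 0.0;
  for (int i = g; i < n - g; ++i) s += v[i];
  return s / (n - 2 * g);
}

// Null distribution for the paired fingerprint distance test: per permutation
// each subject's pair of fingerprints is exchanged between groups with
// probability 1/2, group trimmed means recomputed per target, and the
// Manhattan distance between them recorded. Uses R's RNG (honours set.seed).
// [[Rcpp::export(name = ".dist_perm_null_cpp")]]
NumericVector dist_perm_null_cpp(NumericMatrix A, NumericMatrix B, int nperm,
                                 double trim) {
  int n = A.nrow(), T = A.ncol();
  if (B.nrow() != n || B.ncol() != T) stop("group matrices must match");
  NumericVector out(nperm);
  std::vector<double> colA(n), colB(n);
  std::vector<int> flip(n);
  for (int p = 0; p < nperm; ++p) {
    for (int i = 0; i < n; ++i) flip[i] = unif_rand() < 0.5;
    double d = 0.0;
    for (int t = 0; t < T; ++t) {
      for (int i = 0; i < n; ++i) {
        double ai = A(i, t), bi = B(i, t);
        if (flip[i]) { colA[i] = bi; colB[i] = ai; }
        else { colA[i] = ai; colB[i] = bi; }
      }
      d += std::fabs(trimmed_mean(colA, trim) - trimmed_mean(colB, trim));
    }
    out[p] = d;
  }
  return out;
}

// Null distribution of the maximum TFCE statistic under sign-flipping.
// `signs` is nperm x n_subjects (+-1; enumerated or sampled in R so the
// exact/Monte-Carlo choice and the RNG stay on the R side). `mask_idx` are
// 1-based positions of the map's voxels inside the full grid. t statistics
// are capped at +-tcap; `onesided` keeps only positive t.
// [[Rcpp::export(name = ".signflip_max_tfce_cpp")]]
NumericVector signflip_max_tfce_cpp(NumericMatrix maps, NumericMatrix signs,
                                    IntegerVector mask_idx, IntegerVector dim,
                                    double E, double H, double dh,
                                    int connectivity, double tcap,
                                    bool onesided) {
  const int n = maps.nrow(), V = maps.ncol(), nperm = signs.nrow();
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ntot = nx * ny * nz;
  std::vector<double> ssq(V, 0.0);
  for (int v = 0; v < V; ++v)
    for (int i = 0; i < n; ++i) ssq[v] += maps(i, v) * maps(i, v);
  std::vector<double> vol(ntot, 0.0);
  NumericVector out(nperm);
  for (int p = 0; p < nperm; ++p) {
    std::fill(vol.begin(), vol.end(), 0.0);
    for (int v = 0; v < V; ++v) {
      double m = 0.0;
      for (int i = 0; i < n; ++i) m += signs(p, i) * maps(i, v);
      m /= n;
      double var = (ssq[v] - n * m * m) / (n - 1);
      double t;
      if (var <= 0.0) t = m == 0.0 ? 0.0 : (m > 0 ? tcap : -tcap);
      else t = m / std::sqrt(var / n);
      if (t > tcap) t = tcap;
      if (t < -tcap) t = -tcap;
      if (onesided) t = t > 0 ? t : 0.0;
      else t = std::fabs(t);
      vol[mask_idx[v] - 1] = t;
    }
    std::vector<double> enh = tfce_pos(vol, nx, ny, nz, E, H, dh, connectivity);
    double mx = 0.0;
    for (int v = 0; v < V; ++v) mx = std::max(mx, enh[mask_idx[v] - 1]);
    out[p] = mx;
    if (p % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
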