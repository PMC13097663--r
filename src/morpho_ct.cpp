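#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared-distance transform (lower envelope of parabolas),
// Felzenszwalb & Huttenlocher.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    if (f[q] == INF && f[v[k]] == INF) { // both empty: keep envelope stable
      v[k] = q;
      continue;
    }
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (k > 0 && s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double fv = f[v[k]];
    d[q] = (fv == INF) ? INF : (double)(q - v[k]) * (q - v[k]) + fv;
  }
}

// Exact squared Euclidean distance transform (in voxel units) of a 3D
// feature mask: for every voxel, squared distance to the nearest TRUE voxel.
// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(LogicalVector feature, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t N = (R_xlen_t)nx * ny * nz;
  NumericVector out(no_init(N));
  for (R_xlen_t i = 0; i < N; i++) out[i] = feature[i] ? 0.0 : INF;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // pass along x
  for (int zz = 0; zz < nz; zz++)
    for (int y = 0; y < ny; y++) {
      R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * zz);
      for (int x = 0; x < nx; x++) f[x] = out[base + x];
      dt1d(f, d, v, z, nx);
      for (int x = 0; x < nx; x++) out[base + x] = d[x];
    }
  // pass along y
  for (int zz = 0; zz < nz; zz++)
    for (int x = 0; x < nx; x++) {
      R_xlen_t base = x + (R_xlen_t)nx * ny * zz;
      for (int y = 0; y < ny; y++) f[y] = out[base + (R_xlen_t)nx * y];
      dt1d(f, d, v, z, ny);
      for (int y = 0; y < ny; y++) out[base + (R_xlen_t)nx * y] = d[y];
    }
  // pass along z
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; y++)
    for (int x = 0; x < nx; x++) {
      R_xlen_t base = x + (R_xlen_t)nx * y;
      for (int zz = 0; zz < nz; zz++) f[zz] = out[base + nxy * zz];
      dt1d(f, d, v, z, nz);
      for (int zz = 0; zz < nz; zz++) out[base + nxy * zz] = d[zz];
    }
  return out;
}

// Otsu threshold bin on a 256-bin histogram: the bin index t maximizing
// between-class variance when classes are {bins <= t} and {bins > t}.
// Also reports the effectiveness metric eta = sigma_B^2 / sigma_T^2 of the
// optimal split. Returns -1 when no valid split exists.
static int otsu_bin(const std::vector<double> &hist, double &eta) {
  double total = 0, sum_all = 0;
  for (int b = 0; b < 256; b++) {
    total += hist[b];
    sum_all += b * hist[b];
  }
  eta = 0.0;
  if (total <= 0) return -1;
  double mu = sum_all / total, sigT = 0;
  for (int b = 0; b < 256; b++) sigT += hist[b] * (b - mu) * (b - mu);
  sigT /= total;
  double w0 = 0, sum0 = 0, best = -1.0;
  int best_t = -1;
  for (int t = 0; t < 255; t++) {
    w0 += hist[t];
    sum0 += t * hist[t];
    double w1 = total - w0;
    if (w0 <= 0 || w1 <= 0) continue;
    double mu0 = sum0 / w0, mu1 = (sum_all - sum0) / w1;
    double bc = (w0 / total) * (w1 / total) * (mu0 - mu1) * (mu0 - mu1);
    if (bc > best) {
      best = bc;
      best_t = t;
    }
  }
  if (best_t >= 0 && sigT > 0) eta = best / sigT;
  return best_t;
}

// Slice-wise local Otsu thresholding: each pixel of each 2D slice (slices
// along the third axis) is thresholded by the Otsu criterion computed on the
// 256-bin histogram (equal-width bins over the slice's intensity range) of
// its square neighborhood of half-width `radius`, clipped at the slice
// border. Unimodal regions are resolved by a bimodality cascade on Otsu's
// effectiveness metric eta (neighborhood -> slice -> whole volume): a
// neighborhood with eta below `eta_min` is not genuinely two-material, so
// its pixel falls back to the slice-global Otsu threshold, and a slice that
// is itself unimodal falls back to the volume-global threshold. Thresholds
// are carried as intensity values (upper edge of the Otsu bin) so the
// levels of the cascade are comparable. Pixels whose neighborhood holds a
// single gray level are background.
// [[Rcpp::export(name = ".local_otsu_cpp")]]
LogicalVector local_otsu_cpp(NumericVector vol, IntegerVector dim, int radius,
                             double eta_min) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  R_xlen_t N = nxy * nz;
  LogicalVector out(N);
  std::vector<double> hist(256);
  // volume-level threshold (fallback of last resort)
  double vmin = R_PosInf, vmax = R_NegInf;
  for (R_xlen_t i = 0; i < N; i++) {
    if (vol[i] < vmin) vmin = vol[i];
    if (vol[i] > vmax) vmax = vol[i];
  }
  if (!(vmax > vmin)) return out; // constant volume: all background
  double vbw = (vmax - vmin) / 256.0;
  std::fill(hist.begin(), hist.end(), 0.0);
  for (R_xlen_t i = 0; i < N; i++) {
    int b = (int)((vol[i] - vmin) / vbw);
    if (b > 255) b = 255;
    hist[b] += 1.0;
  }
  // The volume-global Otsu threshold is the fallback of last resort and is
  // used unconditionally: scanned volumes contain both materials, and the
  // Otsu split stays between the material means even when bone occupies a
  // small fraction of the voxels (where an eta gate would misfire).
  double eta_v;
  int t_v = otsu_bin(hist, eta_v);
  double thr_vol = vmin + (t_v + 1) * vbw;
  for (int zz = 0; zz < nz; zz++) {
    R_xlen_t base = nxy * zz;
    double smin = R_PosInf, smax = R_NegInf;
    for (R_xlen_t i = 0; i < nxy; i++) {
      double v = vol[base + i];
      if (v < smin) smin = v;
      if (v > smax) smax = v;
    }
    if (!(smax > smin)) { // constant slice
      for (R_xlen_t i = 0; i < nxy; i++)
        out[base + i] = (vol[base + i] > thr_vol);
      continue;
    }
    double bw = (smax - smin) / 256.0;
    // slice-global histogram and threshold
    std::fill(hist.begin(), hist.end(), 0.0);
    for (R_xlen_t i = 0; i < nxy; i++) {
      int b = (int)((vol[base + i] - smin) / bw);
      if (b > 255) b = 255;
      if (b < 0) b = 0;
      hist[b] += 1.0;
    }
    double eta_s;
    int t_s = otsu_bin(hist, eta_s);
    bool slice_bimodal = (t_s >= 0 && eta_s >= eta_min);
    // fallback threshold for unimodal neighborhoods
    double thr_fallback;
    bool have_fallback;
    if (slice_bimodal) {
      thr_fallback = smin + (t_s + 1) * bw;
      have_fallback = true;
    } else {
      thr_fallback = thr_vol;
      have_fallback = true;
    }
    for (int y = 0; y < ny; y++) {
      int y0 = std::max(0, y - radius), y1 = std::min(ny - 1, y + radius);
      for (int x = 0; x < nx; x++) {
        int x0 = std::max(0, x - radius), x1 = std::min(nx - 1, x + radius);
        std::fill(hist.begin(), hist.end(), 0.0);
        double nmin = R_PosInf, nmax = R_NegInf;
        for (int yy = y0; yy <= y1; yy++)
          for (int xx = x0; xx <= x1; xx++) {
            double v = vol[base + xx + (R_xlen_t)nx * yy];
            if (v < nmin) nmin = v;
            if (v > nmax) nmax = v;
            int b = (int)((v - smin) / bw);
            if (b > 255) b = 255;
            if (b < 0) b = 0;
            hist[b] += 1.0;
          }
        R_xlen_t ci = base + x + (R_xlen_t)nx * y;
        if (!(nmax > nmin)) {
          out[ci] = FALSE; // uniform neighborhood
          continue;
        }
        double eta_l;
        int t = otsu_bin(hist, eta_l);
        double vc = vol[ci];
        if (t >= 0 && eta_l >= eta_min) {
          out[ci] = (vc > smin + (t + 1) * bw);
        } else {
          out[ci] = have_fallback && (vc > thr_fallback);
        }
      }
    }
  }
  return out;
}
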