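#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// ---- counter-based RNG -----------------------------------------------------
// splitmix64 finalizer; draws are keyed by (run seed, stream, agent id,
// counter + draw index) so every agent owns an independent substream and
// adding/removing agents cannot shift any other agent's randomness.

static inline uint64_t mix64(uint64_t z) {
  z += 0x9e3779b97f4a7c15ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

// [[Rcpp::export]]
NumericMatrix hash_runif(double run_seed, double stream, NumericVector id,
                         NumericVector counter, int k) {
  int n = id.size();
  NumericMatrix out(n, k);
  uint64_t base = mix64(((uint64_t)(int64_t)run_seed) * 0x9E3779B97F4A7C15ULL ^
                        mix64((uint64_t)(int64_t)stream + 0x1234ULL));
  for (int i = 0; i < n; i++) {
    uint64_t h = mix64(base ^ mix64((uint64_t)(int64_t)id[i]));
    uint64_t c0 = (uint64_t)(int64_t)counter[i];
    for (int j = 0; j < k; j++) {
      uint64_t v = mix64(h + c0 + (uint64_t)j);
      out(i, j) = ((v >> 11) + 0.5) * (1.0 / 9007199254740992.0);
    }
  }
  return out;
}

// ---- spatial grid helpers --------------------------------------------------

struct CellGrid {
  double x0, y0, cs;
  int nx, ny;
  std::vector<std::vector<int>> cells;
  CellGrid(const NumericVector &x, const NumericVector &y, double cell_size,
           double xmin, double xmax, double ymin, double ymax) {
    x0 = xmin; y0 = ymin; cs = cell_size;
    nx = std::max(1, (int)std::ceil((xmax - xmin) / cs));
    ny = std::max(1, (int)std::ceil((ymax - ymin) / cs));
    cells.assign((size_t)nx * ny, {});
    for (int i = 0; i < x.size(); i++) cells[index(x[i], y[i])].push_back(i);
  }
  inline int clampi(int v, int hi) const { return v < 0 ? 0 : (v >= hi ? hi - 1 : v); }
  inline size_t index(double x, double y) const {
    int ix = clampi((int)std::floor((x - x0) / cs), nx);
    int iy = clampi((int)std::floor((y - y0) / cs), ny);
    return (size_t)iy * nx + ix;
  }
};

// Exact contact pairs (center distance <= r_i + r_j + tol). If `focal` is
// non-empty (1-based indices) only pairs touching a focal agent are returned;
// pairs between two focal agents are reported once.
// [[Rcpp::export]]
NumericMatrix grid_contacts(NumericVector x, NumericVector y, NumericVector r,
                            double tol, IntegerVector focal) {
  int n = x.size();
  NumericMatrix empty(0, 3);
  if (n < 2) return empty;
  double rmax = 0, xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < n; i++) {
    if (r[i] > rmax) rmax = r[i];
    if (x[i] < xmin) xmin = x[i];
    if (x[i] > xmax) xmax = x[i];
    if (y[i] < ymin) ymin = y[i];
    if (y[i] > ymax) ymax = y[i];
  }
  double cs = 2 * rmax + tol + 1e-9;
  CellGrid g(x, y, cs, xmin, xmax + 1e-9, ymin, ymax + 1e-9);
  std::vector<bool> isFocal(n, focal.size() == 0);
  for (int i = 0; i < focal.size(); i++) isFocal[focal[i] - 1] = true;
  std::vector<int> query;
  if (focal.size() == 0) { for (int i = 0; i < n; i++) query.push_back(i); }
  else { for (int i = 0; i < focal.size(); i++) query.push_back(focal[i] - 1); }
  std::vector<double> oi, oj, od;
  for (size_t qi = 0; qi < query.size(); qi++) {
    int i = query[qi];
    int cx = g.clampi((int)std::floor((x[i] - g.x0) / g.cs), g.nx);
    int cy = g.clampi((int)std::floor((y[i] - g.y0) / g.cs), g.ny);
    for (int dy = -1; dy <= 1; dy++) {
      int yy = cy + dy; if (yy < 0 || yy >= g.ny) continue;
      for (int dx = -1; dx <= 1; dx++) {
        int xx = cx + dx; if (xx < 0 || xx >= g.nx) continue;
        const std::vector<int> &bucket = g.cells[(size_t)yy * g.nx + xx];
        for (size_t b = 0; b < bucket.size(); b++) {
          int j = bucket[b];
          if (j == i) continue;
          // dedupe: if both focal report once (i<j); if only i focal report
          if (isFocal[j] && j < i) continue;
          double ddx = x[i] - x[j], ddy = y[i] - y[j];
          double d = std::sqrt(ddx * ddx + ddy * ddy);
          if (d <= r[i] + r[j] + tol) { oi.push_back(i + 1); oj.push_back(j + 1); od.push_back(d); }
        }
      }
    }
  }
  NumericMatrix out(oi.size(), 3);
  for (size_t k = 0; k < oi.size(); k++) { out(k, 0) = oi[k]; out(k, 1) = oj[k]; out(k, 2) = od[k]; }
  colnames(out) = CharacterVector::create("i", "j", "dist");
  return out;
}

// Iterative pairwise separation of overlapping discs: each overlapping pair
// is pushed apart along the center line, half each; positions clamped to the
// arena. Returns updated coordinates and the max residual overlap.
// [[Rcpp::export]]
List relax_collisions(NumericVector x, NumericVector y, NumericVector r,
                      int iters, double xmin, double xmax, double ymin,
                      double ymax, bool residual_scan = true) {
  int n = x.size();
  NumericVector nx_ = clone(x), ny_ = clone(y);
  double maxov = 0;
  for (int it = 0; it < iters; it++) {
    double rmax = 0;
    for (int i = 0; i < n; i++) if (r[i] > rmax) rmax = r[i];
    double cs = 2 * rmax + 1e-9;
    CellGrid g(nx_, ny_, cs, xmin, xmax + 1e-9, ymin, ymax + 1e-9);
    maxov = 0;
    for (int i = 0; i < n; i++) {
      int cx = g.clampi((int)std::floor((nx_[i] - g.x0) / g.cs), g.nx);
      int cy = g.clampi((int)std::floor((ny_[i] - g.y0) / g.cs), g.ny);
      for (int dy = -1; dy <= 1; dy++) {
        int yy = cy + dy; if (yy < 0 || yy >= g.ny) continue;
        for (int dx = -1; dx <= 1; dx++) {
          int xx = cx + dx; if (xx < 0 || xx >= g.nx) continue;
          const std::vector<int> &bucket = g.cells[(size_t)yy * g.nx + xx];
          for (size_t b = 0; b < bucket.size(); b++) {
            int j = bucket[b];
            if (j <= i) continue;
            double ddx = nx_[i] - nx_[j], ddy = ny_[i] - ny_[j];
            double d2 = ddx * ddx + ddy * ddy, rsum = r[i] + r[j];
            if (d2 >= rsum * rsum) continue;
            double d = std::sqrt(d2);
            double ov = rsum - d;
            if (ov > maxov) maxov = ov;
            double ux, uy;
            if (d > 1e-12) { ux = ddx / d; uy = ddy / d; }
            else { // coincident centers: deterministic split
              ux = 1.0; uy = 0.0;
            }
            nx_[i] += 0.5 * ov * ux; ny_[i] += 0.5 * ov * uy;
            nx_[j] -= 0.5 * ov * ux; ny_[j] -= 0.5 * ov * uy;
          }
        }
      }
    }
    for (int i = 0; i < n; i++) {
      if (nx_[i] < xmin) nx_[i] = xmin; if (nx_[i] > xmax) nx_[i] = xmax;
      if (ny_[i] < ymin) ny_[i] = ymin; if (ny_[i] > ymax) ny_[i] = ymax;
    }
    if (maxov <= 0) break;
  }
  // final residual scan (skippable in the hot path)
  if (residual_scan) {
  maxov = 0;
  {
    double rmax = 0;
    for (int i = 0; i < n; i++) if (r[i] > rmax) rmax = r[i];
    double cs = 2 * rmax + 1e-9;
    CellGrid g(nx_, ny_, cs, xmin, xmax + 1e-9, ymin, ymax + 1e-9);
    for (int i = 0; i < n; i++) {
      int cx = g.clampi((int)std::floor((nx_[i] - g.x0) / g.cs), g.nx);
      int cy = g.clampi((int)std::floor((ny_[i] - g.y0) / g.cs), g.ny);
      for (int dy = -1; dy <= 1; dy++) {
        int yy = cy + dy; if (yy < 0 || yy >= g.ny) continue;
        for (int dx = -1; dx <= 1; dx++) {
          int xx = cx + dx; if (xx < 0 || xx >= g.nx) continue;
          const std::vector<int> &bucket = g.cells[(size_t)yy * g.nx + xx];
          for (size_t b = 0; b < bucket.size(); b++) {
            int j = bucket[b];
            if (j <= i) continue;
            double ddx = nx_[i] - nx_[j], ddy = ny_[i] - ny_[j];
            double d = std::sqrt(ddx * ddx + ddy * ddy);
            double ov = r[i] + r[j] - d;
            if (ov > maxov) maxov = ov;
          }
        }
      }
    }
  }
  }
  return List::create(_["x"] = nx_, _["y"] = ny_, _["max_overlap"] = maxov);
}

// Explicit 5-point diffusion with zero-flux boundaries and first-order decay.
// Substeps chosen so D*dt_sub/h^2 <= 0.25 (stability + positivity).
// [[Rcpp::export]]
NumericMatrix diffuse_field(NumericMatrix conc, double D, double h, double dt_s,
                            double decay_per_h) {
  int nr = conc.nrow(), nc = conc.ncol();
  int nsub = 1;
  if (D > 0) nsub = std::max(1, (int)std::ceil(D * dt_s / (0.25 * h * h)));
  double dts = dt_s / nsub;
  double alpha = D * dts / (h * h);
  NumericMatrix a = clone(conc), b(nr, nc);
  for (int s = 0; s < nsub; s++) {
    for (int j = 0; j < nc; j++) {
      for (int i = 0; i < nr; i++) {
        double c = a(i, j);
        double up = (i > 0) ? a(i - 1, j) : c;
        double dn = (i < nr - 1) ? a(i + 1, j) : c;
        double lf = (j > 0) ? a(i, j - 1) : c;
        double rt = (j < nc - 1) ? a(i, j + 1) : c;
        b(i, j) = c + alpha * (up + dn + lf + rt - 4 * c);
      }
    }
    NumericMatrix tmp = a; a = b; b = tmp;
  }
  double fac = std::exp(-decay_per_h * dt_s / 3600.0);
  if (fac != 1.0) for (int j = 0; j < nc; j++) for (int i = 0; i < nr; i++) a(i, j) *= fac;
  return a;
}
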