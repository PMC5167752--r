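#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Spatiotemporal local-extrema detection and half-maximum parcel extraction
// on a (left-right x anterior-posterior x time) amplitude volume.  The
// neighbourhood is the full 26-connected (3x3x3 minus centre) one; voxels
// outside the head mask are NA and never participate.

static inline bool valid_voxel(int x, int y, int t,
                               int nx, int ny, int nt) {
  return x >= 0 && x < nx && y >= 0 && y < ny && t >= 0 && t < nt;
}

// [[Rcpp::export]]
List cpp_local_extrema(NumericVector vol, IntegerVector dims,
                       double min_abs) {
  int nx = dims[0], ny = dims[1], nt = dims[2];
  const double *v = REAL(vol);
  std::vector<int> out_idx;   // 0-based linear indices
  std::vector<int> out_pol;
  long n = (long)nx * ny * nt;
  std::vector<unsigned char> in_plateau(n, 0);

  for (int t = 0; t < nt; ++t) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        long i = (long)x + (long)nx * (y + (long)ny * t);
        double vi = v[i];
        if (ISNAN(vi) || std::fabs(vi) < min_abs || vi == 0.0) continue;
        bool pos = vi > 0;
        bool is_max = true, has_tie = false;
        for (int dt = -1; dt <= 1 && is_max; ++dt)
          for (int dy = -1; dy <= 1 && is_max; ++dy)
            for (int dx = -1; dx <= 1 && is_max; ++dx) {
              if (!dx && !dy && !dt) continue;
              int xx = x + dx, yy = y + dy, tt = t + dt;
              if (!valid_voxel(xx, yy, tt, nx, ny, nt)) continue;
              double vn = v[(long)xx + (long)nx * (yy + (long)ny * tt)];
              if (ISNAN(vn)) continue;
              if (pos ? (vn > vi) : (vn < vi)) is_max = false;
              else if (vn == vi) has_tie = true;
            }
        if (!is_max) continue;
        if (!has_tie) {
          out_idx.push_back((int)i);
          out_pol.push_back(pos ? 1 : -1);
          continue;
        }
        // plateau: flood equal-valued voxels; the plateau is an extremum
        // only if every outside neighbour is strictly dominated; keep one
        // representative voxel (earliest t, then lowest linear index).
        if (in_plateau[i]) continue;
        std::vector<long> plat;
        std::queue<long> q;
        q.push(i);
        in_plateau[i] = 1;
        bool strict = true;
        long rep = i;
        int rep_t = t;
        while (!q.empty()) {
          long c = q.front(); q.pop();
          plat.push_back(c);
          int cx = (int)(c % nx);
          int cy = (int)((c / nx) % ny);
          int ct = (int)(c / ((long)nx * ny));
          if (ct < rep_t || (ct == rep_t && c < rep)) { rep = c; rep_t = ct; }
          for (int dt = -1; dt <= 1; ++dt)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (!dx && !dy && !dt) continue;
                int xx = cx + dx, yy = cy + dy, tt = ct + dt;
                if (!valid_voxel(xx, yy, tt, nx, ny, nt)) continue;
                long j = (long)xx + (long)nx * (yy + (long)ny * tt);
                double vn = v[j];
                if (ISNAN(vn)) continue;
                if (vn == vi) {
                  if (!in_plateau[j]) { in_plateau[j] = 1; q.push(j); }
                } else if (pos ? (vn > vi) : (vn < vi)) {
                  strict = false;
                }
              }
        }
        if (strict) {
          out_idx.push_back((int)rep);
          out_pol.push_back(pos ? 1 : -1);
        }
      }
    }
  }
  return List::create(_["idx"] = wrap(out_idx), _["polarity"] = wrap(out_pol));
}

// 26-connected component containing `peak_idx` (0-based) within the set of
// voxels sharing the peak's sign with |amplitude| >= |peak| / 2.
// [[Rcpp::export]]
IntegerVector cpp_half_component(NumericVector vol, IntegerVector dims,
                                 int peak_idx) {
  int nx = dims[0], ny = dims[1], nt = dims[2];
  const double *v = REAL(vol);
  double vp = v[peak_idx];
  if (ISNAN(vp) || vp == 0.0)
    stop("peak voxel is NA or zero");
  bool pos = vp > 0;
  double thr = std::fabs(vp) / 2.0;
  long n = (long)nx * ny * nt;
  std::vector<unsigned char> seen(n, 0);
  std::vector<int> comp;
  std::queue<long> q;
  q.push(peak_idx);
  seen[peak_idx] = 1;
  while (!q.empty()) {
    long c = q.front(); q.pop();
    comp.push_back((int)c);
    int cx = (int)(c % nx);
    int cy = (int)((c / nx) % ny);
    int ct = (int)(c / ((long)nx * ny));
    for (int dt = -1; dt <= 1; ++dt)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dt) continue;
          int xx = cx + dx, yy = cy + dy, tt = ct + dt;
          if (!valid_voxel(xx, yy, tt, nx, ny, nt)) continue;
          long j = (long)xx + (long)nx * (yy + (long)ny * tt);
          if (seen[j]) continue;
          double vn = v[j];
          if (ISNAN(vn)) continue;
          bool in = pos ? (vn > 0 && vn >= thr) : (vn < 0 && -vn >= thr);
          if (in) { seen[j] = 1; q.push(j); }
        }
  }
  return wrap(comp);
}
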