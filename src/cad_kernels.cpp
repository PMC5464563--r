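#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

// Column-major linear index helpers for 3D arrays (0-based).
static inline int lin(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// Sliding normalized cross-correlation of a volume against a template
// kernel.  `tnorm` is the mean-centred template (t - t_mean), `t_sd` its
// population SD; both precomputed in R.  NCC is evaluated only at voxels
// where `mask` is true and the full template window fits inside the
// volume; everywhere else the output is NA.  Flat windows (zero variance)
// score 0 by convention.
// [[Rcpp::export]]
NumericVector ncc_sweep_cpp(NumericVector vol, LogicalVector mask,
                            IntegerVector dim, NumericVector tnorm,
                            IntegerVector tdim, double t_sd) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int tx = tdim[0], ty = tdim[1], tz = tdim[2];
  const int hx = tx / 2, hy = ty / 2, hz = tz / 2;
  const int n = tx * ty * tz;
  NumericVector out(vol.size(), NA_REAL);

  // Precompute window offsets paired with centred template weights.
  std::vector<int> off(n);
  {
    int m = 0;
    for (int dk = -hz; dk <= hz; ++dk)
      for (int dj = -hy; dj <= hy; ++dj)
        for (int di = -hx; di <= hx; ++di)
          off[m++] = lin(di, dj, dk, nx, ny);
  }

  const double *v = vol.begin();
  const double *u = tnorm.begin();
  for (int k = hz; k < nz - hz; ++k) {
    for (int j = hy; j < ny - hy; ++j) {
      for (int i = hx; i < nx - hx; ++i) {
        const int c = lin(i, j, k, nx, ny);
        if (!mask[c]) continue;
        double s1 = 0.0, s2 = 0.0, sp = 0.0;
        for (int m = 0; m < n; ++m) {
          const double f = v[c + off[m]];
          s1 += f;
          s2 += f * f;
          sp += f * u[m];
        }
        const double mean = s1 / n;
        const double varf = s2 / n - mean * mean;
        if (varf <= 0.0) {
          out[c] = 0.0;  // flat patch convention
        } else {
          // sum((f - fbar) * u) == sp because sum(u) == 0
          out[c] = sp / (n * std::sqrt(varf) * t_sd);
        }
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Seed region growing with an optional spherical acceptance test.  A
// frontier voxel is accepted when every in-bounds voxel whose centre lies
// within `sphere_offsets` of it satisfies |I - ref| <= tol (offsets are an
// m x 3 matrix of voxel displacements; a single zero row reduces to plain
// SRG).  Growth proceeds under 26-connectivity from the seed.
// [[Rcpp::export]]
LogicalVector region_grow_cpp(NumericVector vol, IntegerVector dim,
                              IntegerVector seed, double ref, double tol,
                              IntegerMatrix sphere_offsets) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ns = sphere_offsets.nrow();
  LogicalVector out(vol.size(), false);
  std::vector<char> visited(vol.size(), 0);
  const double *v = vol.begin();

  auto pred = [&](int i, int j, int k) {
    return std::fabs(v[lin(i, j, k, nx, ny)] - ref) <= tol;
  };
  auto accept = [&](int i, int j, int k) {
    for (int m = 0; m < ns; ++m) {
      const int si = i + sphere_offsets(m, 0);
      const int sj = j + sphere_offsets(m, 1);
      const int sk = k + sphere_offsets(m, 2);
      if (si < 0 || si >= nx || sj < 0 || sj >= ny || sk < 0 || sk >= nz)
        continue;  // out-of-bounds sphere voxels are ignored
      if (!pred(si, sj, sk)) return false;
    }
    return true;
  };

  const int s0 = seed[0], s1 = seed[1], s2 = seed[2];
  if (!accept(s0, s1, s2))
    stop("seed sphere violates the intensity condition; choose a different seed, tolerance, or radius");

  std::vector<int> queue;
  queue.reserve(1024);
  const int sidx = lin(s0, s1, s2, nx, ny);
  out[sidx] = true;
  visited[sidx] = 1;
  queue.push_back(sidx);

  while (!queue.empty()) {
    const int c = queue.back();
    queue.pop_back();
    const int ck = c / (nx * ny);
    const int cj = (c - ck * nx * ny) / nx;
    const int ci = c - nx * (cj + ny * ck);
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0 && dk == 0) continue;
          const int i = ci + di, j = cj + dj, k = ck + dk;
          if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz)
            continue;
          const int idx = lin(i, j, k, nx, ny);
          if (visited[idx]) continue;
          visited[idx] = 1;
          if (accept(i, j, k)) {
            out[idx] = true;
            queue.push_back(idx);
          }
        }
  }
  out.attr("dim") = dim;
  return out;
}

// Connected-component labelling of a logical 3D array under 6- or
// 26-connectivity.  Labels are positive integers in first-encounter
// order (column-major scan); background is 0.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector x, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector out(x.size(), 0);
  std::vector<int> queue;
  int next = 0;

  std::vector<std::array<int, 3>> nb;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        const int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && manh != 1) continue;
        nb.push_back({di, dj, dk});
      }

  for (int start = 0; start < (int)x.size(); ++start) {
    if (!x[start] || out[start] != 0) continue;
    ++next;
    out[start] = next;
    queue.clear();
    queue.push_back(start);
    while (!queue.empty()) {
      const int c = queue.back();
      queue.pop_back();
      const int ck = c / (nx * ny);
      const int cj = (c - ck * nx * ny) / nx;
      const int ci = c - nx * (cj + ny * ck);
      for (const auto &d : nb) {
        const int i = ci + d[0], j = cj + d[1], k = ck + d[2];
        if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz)
          continue;
        const int idx = lin(i, j, k, nx, ny);
        if (x[idx] && out[idx] == 0) {
          out[idx] = next;
          queue.push_back(idx);
        }
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Binary dilation of a logical 3D array by an explicit offset set
// (m x 3 voxel displacements).  Erosion is dilation of the complement.
// [[Rcpp::export]]
LogicalVector dilate_mask_cpp(LogicalVector x, IntegerVector dim,
                              IntegerMatrix offsets) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int m = offsets.nrow();
  LogicalVector out(x.size(), false);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int c = lin(i, j, k, nx, ny);
        if (!x[c]) continue;
        for (int r = 0; r < m; ++r) {
          const int di = i + offsets(r, 0);
          const int dj = j + offsets(r, 1);
          const int dk = k + offsets(r, 2);
          if (di < 0 || di >= nx || dj < 0 || dj >= ny || dk < 0 || dk >= nz)
            continue;
          out[lin(di, dj, dk, nx, ny)] = true;
        }
      }
  out.attr("dim") = dim;
  return out;
}
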