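#include <Rcpp.h>
#include <vector>
#include <queue>
#include <array>
#include <cmath>
using namespace Rcpp;

// Grid label codes shared with the R side:
// 0 = SOLVENT, 1 = PROTEIN, 2 = SURFACE, 3 = SURFACE_POCKET, 4 = DEEP_POCKET

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// Label points PROTEIN (1) if within the vdW radius of any heavy-atom
// centre, else SOLVENT (0); then relabel PROTEIN points with at least one
// solvent-class 26-neighbour as SURFACE (2).  Points outside the box are
// treated as solvent-class for the surface rule.
// [[Rcpp::export]]
IntegerVector cpp_label_grid(NumericMatrix xyz, NumericVector radius,
                             NumericVector origin, double spacing,
                             IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  IntegerVector lab(n, 0);

  // occupancy: per atom, visit only grid cells inside its bounding cube
  for (int a = 0; a < xyz.nrow(); ++a) {
    const double r = radius[a];
    if (r <= 0) continue;
    const double ax = xyz(a, 0), ay = xyz(a, 1), az = xyz(a, 2);
    const double r2 = r * r;
    int i0 = (int)std::ceil((ax - r - origin[0]) / spacing);
    int i1 = (int)std::floor((ax + r - origin[0]) / spacing);
    int j0 = (int)std::ceil((ay - r - origin[1]) / spacing);
    int j1 = (int)std::floor((ay + r - origin[1]) / spacing);
    int k0 = (int)std::ceil((az - r - origin[2]) / spacing);
    int k1 = (int)std::floor((az + r - origin[2]) / spacing);
    if (i0 < 0) i0 = 0; if (i1 >= nx) i1 = nx - 1;
    if (j0 < 0) j0 = 0; if (j1 >= ny) j1 = ny - 1;
    if (k0 < 0) k0 = 0; if (k1 >= nz) k1 = nz - 1;
    for (int k = k0; k <= k1; ++k) {
      const double dz = origin[2] + k * spacing - az;
      for (int j = j0; j <= j1; ++j) {
        const double dy = origin[1] + j * spacing - ay;
        const double dyz2 = dy * dy + dz * dz;
        if (dyz2 > r2) continue;
        for (int i = i0; i <= i1; ++i) {
          const double dx = origin[0] + i * spacing - ax;
          if (dx * dx + dyz2 <= r2) lab[idx3(i, j, k, nx, ny)] = 1;
        }
      }
    }
  }

  // surface relabel
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int p = idx3(i, j, k, nx, ny);
        if (lab[p] != 1) continue;
        bool surf = false;
        for (int dk = -1; dk <= 1 && !surf; ++dk)
          for (int dj = -1; dj <= 1 && !surf; ++dj)
            for (int di = -1; di <= 1 && !surf; ++di) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              const int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || ii >= nx || jj < 0 || jj >= ny ||
                  kk < 0 || kk >= nz) { surf = true; break; }
              if (lab[idx3(ii, jj, kk, nx, ny)] == 0) surf = true;
            }
        if (surf) lab[p] = 2;
      }
  return lab;
}

// Scan-line Surface-Solvent-Surface events.  For each direction, every
// maximal run of SOLVENT points flanked on both ends by SURFACE points,
// with flank-to-flank Euclidean length <= max_span, increments the event
// count of each run point.  Runs containing a boundary point never count.
// Directions: n x 3 integer steps (7-direction set = axes + body
// diagonals; the 13-set adds face diagonals).
// [[Rcpp::export]]
IntegerVector cpp_scan_sss(IntegerVector lab, IntegerVector dims,
                           double spacing, IntegerMatrix directions,
                           double max_span) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector ev(lab.size(), 0);

  for (int d = 0; d < directions.nrow(); ++d) {
    const int di = directions(d, 0), dj = directions(d, 1),
              dk = directions(d, 2);
    const double step_len =
        spacing * std::sqrt((double)(di * di + dj * dj + dk * dk));
    std::vector<int> line;
    line.reserve(std::max(std::max(nx, ny), nz));
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          // start of a line: predecessor is outside the box
          const int pi = i - di, pj = j - dj, pk = k - dk;
          if (pi >= 0 && pi < nx && pj >= 0 && pj < ny && pk >= 0 && pk < nz)
            continue;
          line.clear();
          int ci = i, cj = j, ck = k;
          while (ci >= 0 && ci < nx && cj >= 0 && cj < ny &&
                 ck >= 0 && ck < nz) {
            line.push_back(idx3(ci, cj, ck, nx, ny));
            ci += di; cj += dj; ck += dk;
          }
          const int L = (int)line.size();
          int t = 0;
          while (t < L) {
            if (lab[line[t]] != 0) { ++t; continue; }
            int s = t;            // solvent run [s, e]
            while (t < L && lab[line[t]] == 0) ++t;
            int e = t - 1;
            if (s == 0 || e == L - 1) continue;         // touches line end
            if (lab[line[s - 1]] != 2 || lab[line[e + 1]] != 2) continue;
            const double span = (e - s + 2) * step_len; // flank to flank
            if (span > max_span) continue;
            // boundary exclusion: any run point on a box face
            bool boundary = false;
            for (int q = s; q <= e && !boundary; ++q) {
              const int p = line[q];
              const int qi = p % nx, qj = (p / nx) % ny, qk = p / (nx * ny);
              if (qi == 0 || qi == nx - 1 || qj == 0 || qj == ny - 1 ||
                  qk == 0 || qk == nz - 1) boundary = true;
            }
            if (boundary) continue;
            for (int q = s; q <= e; ++q) ev[line[q]] += 1;
          }
        }
  }
  return ev;
}

// Pocket marking: SOLVENT points with event_count >= min_events become
// candidates; a candidate within deep_cutoff (Euclidean, point-to-point)
// of any bulk solvent point (SOLVENT non-candidate, or any point outside
// the box) becomes SURFACE_POCKET (3), the rest DEEP_POCKET (4).
// [[Rcpp::export]]
IntegerVector cpp_mark_pockets(IntegerVector lab, IntegerVector ev,
                               IntegerVector dims, double spacing,
                               int min_events, double deep_cutoff) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out = clone(lab);
  const int n = out.size();
  std::vector<char> cand(n, 0);
  for (int p = 0; p < n; ++p)
    if (lab[p] == 0 && ev[p] >= min_events) cand[p] = 1;

  const int m = (int)std::floor(deep_cutoff / spacing);
  // precompute neighbour offsets with Euclidean norm <= deep_cutoff
  std::vector<std::array<int, 3>> offs;
  const double cut2 = (deep_cutoff / spacing) * (deep_cutoff / spacing);
  for (int dk = -m; dk <= m; ++dk)
    for (int dj = -m; dj <= m; ++dj)
      for (int di = -m; di <= m; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        if ((double)(di * di + dj * dj + dk * dk) <= cut2)
          offs.push_back({di, dj, dk});
      }

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int p = idx3(i, j, k, nx, ny);
        if (!cand[p]) continue;
        bool near_bulk = false;
        for (size_t o = 0; o < offs.size() && !near_bulk; ++o) {
          const int ii = i + offs[o][0], jj = j + offs[o][1],
                    kk = k + offs[o][2];
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny ||
              kk < 0 || kk >= nz) { near_bulk = true; break; }
          const int q = idx3(ii, jj, kk, nx, ny);
          if (lab[q] == 0 && !cand[q]) near_bulk = true;
        }
        out[p] = near_bulk ? 3 : 4;
      }
  return out;
}

// Connected components over pocket-labelled points (labels 3 and 4).
// Returns a component id per grid point (0 = not pocket), numbered in
// order of first (lowest linear index) appearance.
// [[Rcpp::export]]
IntegerVector cpp_pocket_components(IntegerVector lab, IntegerVector dims,
                                    int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = (int)lab.size();
  IntegerVector comp(n, 0);
  std::vector<std::array<int, 3>> offs;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        const int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({di, dj, dk});
      }
  int next_id = 0;
  std::queue<int> bfs;
  for (int p = 0; p < n; ++p) {
    if ((lab[p] != 3 && lab[p] != 4) || comp[p] != 0) continue;
    comp[p] = ++next_id;
    bfs.push(p);
    while (!bfs.empty()) {
      const int q = bfs.front(); bfs.pop();
      const int qi = q % nx, qj = (q / nx) % ny, qk = q / (nx * ny);
      for (size_t o = 0; o < offs.size(); ++o) {
        const int ii = qi + offs[o][0], jj = qj + offs[o][1],
                  kk = qk + offs[o][2];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny ||
            kk < 0 || kk >= nz) continue;
        const int w = idx3(ii, jj, kk, nx, ny);
        if ((lab[w] == 3 || lab[w] == 4) && comp[w] == 0) {
          comp[w] = next_id;
          bfs.push(w);
        }
      }
    }
  }
  return comp;
}

// Minimum squared distance from each grid point in `points` (0-based
// linear indices) to any row of `xyz`.
// [[Rcpp::export]]
NumericVector cpp_min_dist2_to_atoms(IntegerVector points, NumericVector origin,
                                     double spacing, IntegerVector dims,
                                     NumericMatrix xyz) {
  const int nx = dims[0], ny = dims[1];
  NumericVector out(points.size());
  for (int t = 0; t < points.size(); ++t) {
    const int p = points[t];
    const double px = origin[0] + (p % nx) * spacing;
    const double py = origin[1] + ((p / nx) % ny) * spacing;
    const double pz = origin[2] + (p / (nx * ny)) * spacing;
    double best = R_PosInf;
    for (int a = 0; a < xyz.nrow(); ++a) {
      const double dx = px - xyz(a, 0), dy = py - xyz(a, 1),
                   dz = pz - xyz(a, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[t] = best;
  }
  return out;
}

// Soft-sphere clash + contact reward over heavy-atom pairs.
// clash: d < f*(ri+rj)          -> k_clash * (f*(ri+rj) - d)^2
// contact: f*(ri+rj) <= d <= ri+rj+contact_pad -> contact_reward (signed)
// Pairs within one residue, or between sequence-adjacent residues with
// both atoms backbone-named, are excluded.
// [[Rcpp::export]]
List cpp_pair_energy(NumericMatrix xyz, NumericVector radius,
                     IntegerVector res_ord, LogicalVector is_bb,
                     double f, double k_clash, double contact_reward,
                     double contact_pad) {
  const int n = xyz.nrow();
  double clash = 0.0, contact = 0.0;
  long n_contacts = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const int dres = res_ord[j] - res_ord[i];
      if (dres == 0) continue;
      if ((dres == 1 || dres == -1) && is_bb[i] && is_bb[j]) continue;
      const double dx = xyz(i, 0) - xyz(j, 0);
      const double dy = xyz(i, 1) - xyz(j, 1);
      const double dz = xyz(i, 2) - xyz(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      const double rsum = radius[i] + radius[j];
      const double outer = rsum + contact_pad;
      if (d2 > outer * outer) continue;
      const double d = std::sqrt(d2);
      const double dclash = f * rsum;
      if (d < dclash) {
        clash += k_clash * (dclash - d) * (dclash - d);
      } else {
        contact += contact_reward;
        ++n_contacts;
      }
    }
  }
  return List::create(_["clash"] = clash, _["contact"] = contact,
                      _["n_contacts"] = (double)n_contacts);
}

// Fused fast path for Monte Carlo: grid spec + labels + scan + mark +
// connected components + target contact, returning only the deep volume
// of the largest-deep-volume pocket in contact with the target residue.
// Mirrors the R-level pipeline (build_grid -> scan_sss -> mark_pockets ->
// cluster_pockets -> deep volume) with identical parameters.
// [[Rcpp::export]]
double cpp_deep_volume(NumericMatrix xyz, NumericVector radius,
                       IntegerVector target_rows,  // 1-based rows into xyz
                       double spacing, double max_span, double deep_cutoff,
                       int min_events, int connectivity,
                       IntegerMatrix directions, double contact_radius,
                       double capture_radius, double padding) {
  const int n = xyz.nrow();
  const int nt = target_rows.size();
  // target centroid (matches colMeans over target heavy atoms)
  double cx = 0, cy = 0, cz = 0;
  for (int t = 0; t < nt; ++t) {
    const int r = target_rows[t] - 1;
    cx += xyz(r, 0); cy += xyz(r, 1); cz += xyz(r, 2);
  }
  cx /= nt; cy /= nt; cz /= nt;
  // capture box half-extent
  double half = 0.0;
  bool any_cap = false;
  const double cap2 = capture_radius * capture_radius;
  for (int i = 0; i < n; ++i) {
    const double dx = xyz(i, 0) - cx, dy = xyz(i, 1) - cy,
                 dz = xyz(i, 2) - cz;
    if (dx * dx + dy * dy + dz * dz <= cap2) {
      any_cap = true;
      double m = std::fabs(dx);
      if (std::fabs(dy) > m) m = std::fabs(dy);
      if (std::fabs(dz) > m) m = std::fabs(dz);
      if (m > half) half = m;
    }
  }
  if (!any_cap) {
    for (int t = 0; t < nt; ++t) {
      const int r = target_rows[t] - 1;
      double m = std::fabs(xyz(r, 0) - cx);
      if (std::fabs(xyz(r, 1) - cy) > m) m = std::fabs(xyz(r, 1) - cy);
      if (std::fabs(xyz(r, 2) - cz) > m) m = std::fabs(xyz(r, 2) - cz);
      if (m > half) half = m;
    }
  }
  half += padding;
  const int h = (int)std::ceil(half / spacing);
  IntegerVector dims = IntegerVector::create(2 * h + 1, 2 * h + 1, 2 * h + 1);
  NumericVector origin = NumericVector::create(cx - h * spacing,
                                               cy - h * spacing,
                                               cz - h * spacing);
  IntegerVector lab = cpp_label_grid(xyz, radius, origin, spacing, dims);
  IntegerVector ev = cpp_scan_sss(lab, dims, spacing, directions, max_span);
  lab = cpp_mark_pockets(lab, ev, dims, spacing, min_events, deep_cutoff);
  IntegerVector comp = cpp_pocket_components(lab, dims, connectivity);

  int ncomp = 0;
  for (int p = 0; p < comp.size(); ++p) if (comp[p] > ncomp) ncomp = comp[p];
  if (ncomp == 0) return 0.0;
  std::vector<int> deep(ncomp + 1, 0);
  std::vector<char> contact(ncomp + 1, 0);
  const int nx = dims[0], ny = dims[1];
  const double cr2 = contact_radius * contact_radius;
  for (int p = 0; p < comp.size(); ++p) {
    const int c = comp[p];
    if (c == 0) continue;
    if (lab[p] == 4) deep[c] += 1;
    if (!contact[c]) {
      const double px = origin[0] + (p % nx) * spacing;
      const double py = origin[1] + ((p / nx) % ny) * spacing;
      const double pz = origin[2] + (p / (nx * ny)) * spacing;
      for (int t = 0; t < nt; ++t) {
        const int r = target_rows[t] - 1;
        const double dx = px - xyz(r, 0), dy = py - xyz(r, 1),
                     dz = pz - xyz(r, 2);
        if (dx * dx + dy * dy + dz * dz <= cr2) { contact[c] = 1; break; }
      }
    }
  }
  int best = 0;
  for (int c = 1; c <= ncomp; ++c)
    if (contact[c] && deep[c] > best) best = deep[c];
  return best * spacing * spacing * spacing;
}
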