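#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Connected-component labelling of a logical matrix by breadth-first
// flood fill. connectivity is 4 or 8. Labels are assigned in raster
// (column-major, as stored by R) order of first encounter, starting at 1.
// [[Rcpp::export]]
IntegerMatrix cc_label_cpp(const LogicalMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);

  static const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  static const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int ndir = (connectivity == 4) ? 4 : 8;

  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int k = 0; k < ndir; ++k) {
          int r2 = rr + dr8[k], c2 = cc + dc8[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

// One-dimensional squared distance transform (lower envelope of
// parabolas, Felzenszwalb & Huttenlocher 2012).
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (k > 0 && s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    if (k == 0 && s <= z[0]) { v[0] = q; continue; }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance of every true pixel to the nearest
// false pixel. False pixels get 0. Pixels beyond the border are NOT
// treated as background, matching the usual image-analysis convention.
// A large finite sentinel (not infinity) keeps the parabola envelope
// arithmetic well defined on all-foreground scanlines.
// [[Rcpp::export]]
NumericMatrix edt_sq_cpp(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e15;
  NumericMatrix out(nr, nc);

  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  std::vector<int> v(std::max(nr, nc));
  std::vector<double> z(std::max(nr, nc) + 1);

  // pass 1: along columns
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = mask(r, c) ? INF : 0.0;
    f.resize(nr); d.resize(nr);
    dt1d(f, d, v, z);
    for (int r = 0; r < nr; ++r) out(r, c) = d[r];
    f.resize(std::max(nr, nc)); d.resize(std::max(nr, nc));
  }
  // pass 2: along rows
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = out(r, c);
    f.resize(nc); d.resize(nc);
    dt1d(f, d, v, z);
    for (int c = 0; c < nc; ++c) out(r, c) = d[c];
    f.resize(std::max(nr, nc)); d.resize(std::max(nr, nc));
  }
  return out;
}

static inline int nbr_count(const LogicalMatrix& m, int r, int c) {
  int n = 0;
  for (int dr = -1; dr <= 1; ++dr)
    for (int dc = -1; dc <= 1; ++dc) {
      if (dr == 0 && dc == 0) continue;
      int r2 = r + dr, c2 = c + dc;
      if (r2 >= 0 && r2 < m.nrow() && c2 >= 0 && c2 < m.ncol() && m(r2, c2))
        ++n;
    }
  return n;
}

// Crossing number: number of distinct connected runs of foreground
// pixels around the 8-neighbour ring. 1 = endpoint, 2 = path pixel,
// >= 3 = branch point. Robust on staircase skeletons where the raw
// neighbour count misclassifies corner pixels as branches.
static inline int nbr_runs(const LogicalMatrix& m, int r, int c) {
  static const int rr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  static const int cc[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  int p[8];
  for (int k = 0; k < 8; ++k) {
    int r2 = r + rr[k], c2 = c + cc[k];
    p[k] = (r2 >= 0 && r2 < m.nrow() && c2 >= 0 && c2 < m.ncol() &&
            m(r2, c2)) ? 1 : 0;
  }
  int runs = 0;
  for (int k = 0; k < 8; ++k)
    if (p[k] == 0 && p[(k + 1) % 8] == 1) ++runs;
  return runs;
}

// Crossing number of every pixel (0 where mask is false).
// [[Rcpp::export]]
IntegerMatrix nbr_runs_cpp(const LogicalMatrix& mask) {
  IntegerMatrix out(mask.nrow(), mask.ncol());
  for (int c = 0; c < mask.ncol(); ++c)
    for (int r = 0; r < mask.nrow(); ++r)
      out(r, c) = mask(r, c) ? nbr_runs(mask, r, c) : 0;
  return out;
}

// Zhang-Suen thinning to a one-pixel-wide, 8-connected skeleton.
// [[Rcpp::export]]
LogicalMatrix thin_cpp(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix img(clone(mask));

  auto P = [&](int r, int c) -> int {
    if (r < 0 || r >= nr || c < 0 || c >= nc) return 0;
    return img(r, c) ? 1 : 0;
  };

  bool changed = true;
  std::vector<int> kill;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      kill.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!img(r, c)) continue;
          // neighbours P2..P9 clockwise from north
          int p2 = P(r - 1, c),     p3 = P(r - 1, c + 1);
          int p4 = P(r, c + 1),     p5 = P(r + 1, c + 1);
          int p6 = P(r + 1, c),     p7 = P(r + 1, c - 1);
          int p8 = P(r, c - 1),     p9 = P(r - 1, c - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (sub == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(r + c * nr);
        }
      }
      if (!kill.empty()) changed = true;
      for (int idx : kill) img(idx % nr, idx / nr) = false;
    }
  }
  return img;
}

// Remove spurs: endpoint-to-branch paths strictly shorter (in pixel
// count) than min_spur_px. Iterates until stable. Isolated short paths
// with no branch point (whole components) are kept: they may be genuine
// small roots and debris rejection is the cleaning stage's job.
// [[Rcpp::export]]
LogicalMatrix prune_spurs_cpp(const LogicalMatrix& skel, int min_spur_px) {
  const int nr = skel.nrow(), nc = skel.ncol();
  LogicalMatrix img(clone(skel));
  if (min_spur_px <= 1) return img;

  static const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  static const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};

  bool changed = true;
  int guard = 0;
  while (changed && ++guard < 100) {
    changed = false;
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        if (!img(r, c) || nbr_runs(img, r, c) != 1 ||
            nbr_count(img, r, c) == 0) continue;
        // walk from the endpoint until a branch point (crossing number
        // >= 3); axial steps tried before diagonal so staircase pixels
        // are traversed in path order
        std::vector<int> path;
        std::vector<int> visited;
        int pr = r, pc = c;
        bool hit_branch = false;
        while ((int)path.size() < min_spur_px) {
          path.push_back(pr + pc * nr);
          visited.push_back(pr + pc * nr);
          int nxt_r = -1, nxt_c = -1;
          for (int k = 0; k < 8; ++k) {
            int r2 = pr + dr8[k], c2 = pc + dc8[k];
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            if (!img(r2, c2)) continue;
            int id = r2 + c2 * nr;
            bool seen = false;
            for (int vv : visited) if (vv == id) { seen = true; break; }
            if (seen) continue;
            nxt_r = r2; nxt_c = c2;
            break; // dr8/dc8 lists axial directions first
          }
          if (nxt_r < 0) break; // isolated path: keep
          if (nbr_runs(img, nxt_r, nxt_c) >= 3) { hit_branch = true; break; }
          pr = nxt_r; pc = nxt_c;
        }
        if (hit_branch && (int)path.size() < min_spur_px) {
          for (int idx : path) img(idx % nr, idx / nr) = false;
          changed = true;
        }
      }
    }
  }
  return img;
}

// Decompose a 1-px skeleton into maximal ordered paths between nodes
// (endpoints and branch points, by crossing number). Returns a list of
// integer vectors of 1-based column-major pixel indices; node pixels
// appear in every path they terminate. Node-free cycles are returned as
// closed paths. Isolated pixels are returned as length-1 paths.
// [[Rcpp::export]]
List skeleton_paths_cpp(const LogicalMatrix& skel) {
  const int nr = skel.nrow(), nc = skel.ncol();
  // axial directions first so staircases are traversed in path order
  static const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  static const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};

  std::vector<int> px;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (skel(r, c)) px.push_back(r + c * nr);

  std::vector<char> is_node(nr * nc, 0), consumed(nr * nc, 0);
  for (int idx : px) {
    int r = idx % nr, c = idx / nr;
    int runs = nbr_runs(skel, r, c);
    int deg = nbr_count(skel, r, c);
    if (deg == 0 || runs != 2) is_node[idx] = 1;
  }

  std::vector<std::vector<int> > paths;
  std::vector<long long> seen_pairs; // dedupe node-node 2-pixel paths

  auto walk = [&](int start, int first) {
    std::vector<int> path;
    path.push_back(start);
    int prev = start, cur = first;
    while (true) {
      path.push_back(cur);
      if (is_node[cur]) break;
      consumed[cur] = 1;
      int cr = cur % nr, cc = cur / nr;
      int nxt = -1;
      for (int k = 0; k < 8; ++k) {
        int r2 = cr + dr8[k], c2 = cc + dc8[k];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        if (!skel(r2, c2)) continue;
        int id = r2 + c2 * nr;
        if (id == prev || id == cur) continue;
        if (!is_node[id] && consumed[id]) continue;
        nxt = id;
        break;
      }
      if (nxt < 0) break; // dead end (shouldn't happen on clean skeletons)
      prev = cur;
      cur = nxt;
      if (cur == start) { path.push_back(start); break; } // cycle guard
    }
    return path;
  };

  for (int idx : px) {
    if (!is_node[idx]) continue;
    int r = idx % nr, c = idx / nr;
    if (nbr_count(skel, r, c) == 0) {
      paths.push_back(std::vector<int>(1, idx));
      continue;
    }
    for (int k = 0; k < 8; ++k) {
      int r2 = r + dr8[k], c2 = c + dc8[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (!skel(r2, c2)) continue;
      int id = r2 + c2 * nr;
      if (is_node[id]) {
        long long key = (long long)std::min(idx, id) * (nr * (long long)nc) +
                        std::max(idx, id);
        bool dup = false;
        for (long long s : seen_pairs) if (s == key) { dup = true; break; }
        if (!dup) {
          seen_pairs.push_back(key);
          std::vector<int> p; p.push_back(idx); p.push_back(id);
          paths.push_back(p);
        }
        continue;
      }
      if (consumed[id]) continue;
      paths.push_back(walk(idx, id));
    }
  }
  // node-free cycles
  for (int idx : px) {
    if (is_node[idx] || consumed[idx]) continue;
    int r = idx % nr, c = idx / nr;
    int first = -1;
    for (int k = 0; k < 8; ++k) {
      int r2 = r + dr8[k], c2 = c + dc8[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (skel(r2, c2)) { first = r2 + c2 * nr; break; }
    }
    if (first < 0) continue;
    consumed[idx] = 1;
    paths.push_back(walk(idx, first));
  }

  List out(paths.size());
  for (size_t i = 0; i < paths.size(); ++i) {
    IntegerVector v(paths[i].size());
    for (size_t j = 0; j < paths[i].size(); ++j) v[j] = paths[i][j] + 1;
    out[i] = v;
  }
  return out;
}

// Rasterise circular brush strokes: for sample points (x, y) in pixel
// coordinates (1-based, x = column, y = row) with radii r, set each
// pixel's coverage to the maximum over samples of
// clamp(r + 0.5 - dist(pixel centre, sample), 0, 1),
// which anti-aliases the stroke edge over ~1 px. Updates canvas in place
// semantics via returned copy.
// [[Rcpp::export]]
NumericMatrix stamp_disks_cpp(NumericMatrix canvas,
                              const NumericVector& x,
                              const NumericVector& y,
                              const NumericVector& r) {
  const int nr = canvas.nrow(), nc = canvas.ncol();
  NumericMatrix out(clone(canvas));
  const int n = x.size();
  for (int i = 0; i < n; ++i) {
    const double xi = x[i], yi = y[i], ri = r[i];
    const double reach = ri + 1.0;
    int c0 = std::max(0, (int)std::floor(xi - reach) - 1);
    int c1 = std::min(nc - 1, (int)std::ceil(xi + reach));
    int r0 = std::max(0, (int)std::floor(yi - reach) - 1);
    int r1 = std::min(nr - 1, (int)std::ceil(yi + reach));
    for (int cc = c0; cc <= c1; ++cc) {
      const double dx = (cc + 1) - xi;
      for (int rr = r0; rr <= r1; ++rr) {
        const double dy = (rr + 1) - yi;
        double cov = ri + 0.5 - std::sqrt(dx * dx + dy * dy);
        if (cov <= 0) continue;
        if (cov > 1) cov = 1;
        if (cov > out(rr, cc)) out(rr, cc) = cov;
      }
    }
  }
  return out;
}
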