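#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Topology-preserving thinning (Zhang-Suen). Input/output: logical matrix,
// TRUE = foreground. Border pixels are handled as if padded with FALSE.
// [[Rcpp::export(name = ".thin_zs")]]
LogicalMatrix thin_zs(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<char> img(nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      img[i + j * nr] = mask(i, j) ? 1 : 0;

  auto at = [&](int i, int j) -> char {
    if (i < 0 || j < 0 || i >= nr || j >= nc) return 0;
    return img[i + j * nr];
  };

  // Guo-Hall thinning: preserves connectivity and, unlike Zhang-Suen,
  // does not erase 2-px-wide diagonal runs. Neighbours n1..n8 clockwise
  // from north.
  std::vector<int> del;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      del.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!img[i + j * nr]) continue;
          char n1 = at(i - 1, j),     n2 = at(i - 1, j + 1);
          char n3 = at(i, j + 1),     n4 = at(i + 1, j + 1);
          char n5 = at(i + 1, j),     n6 = at(i + 1, j - 1);
          char n7 = at(i, j - 1),     n8 = at(i - 1, j - 1);
          int C = ((!n1) & (n2 | n3)) + ((!n3) & (n4 | n5)) +
                  ((!n5) & (n6 | n7)) + ((!n7) & (n8 | n1));
          int N1 = (n1 | n2) + (n3 | n4) + (n5 | n6) + (n7 | n8);
          int N2 = (n2 | n3) + (n4 | n5) + (n6 | n7) + (n8 | n1);
          int Nm = N1 < N2 ? N1 : N2;
          int m = (pass == 0) ? ((n1 | n2 | !n4) & n3)
                              : ((n5 | n6 | !n8) & n7);
          if (C == 1 && Nm >= 2 && Nm <= 3 && m == 0)
            del.push_back(i + j * nr);
        }
      }
      if (!del.empty()) changed = true;
      for (size_t k = 0; k < del.size(); ++k) img[del[k]] = 0;
    }
  }

  // staircase removal (Holt-style templates): Zhang-Suen leaves redundant
  // corner pixels on diagonal runs, which masquerade as branch points.
  // The templates delete exactly those corners and cannot retract line
  // ends or break connectivity.
  changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      del.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!img[i + j * nr]) continue;
          char N = at(i - 1, j), NE = at(i - 1, j + 1), E = at(i, j + 1);
          char SE = at(i + 1, j + 1), S = at(i + 1, j), SW = at(i + 1, j - 1);
          char W = at(i, j - 1), NW = at(i - 1, j - 1);
          bool hit;
          if (pass == 0)
            hit = N && ((E && !NE && !SW && (!W || !S)) ||
                        (W && !NW && !SE && (!E || !S)));
          else
            hit = S && ((E && !SE && !NW && (!W || !N)) ||
                        (W && !SW && !NE && (!E || !N)));
          if (hit) del.push_back(i + j * nr);
        }
      }
      if (!del.empty()) changed = true;
      for (size_t k = 0; k < del.size(); ++k) img[del[k]] = 0;
    }
  }

  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = img[i + j * nr] != 0;
  return out;
}

// Uniform-cost search on the pixel grid, 8-connected. Entering a skeleton
// pixel costs 0, entering any other pixel costs 1 (node weights, as in the
// tracking formulation); geometric step length (1 or sqrt(2)) breaks ties.
// Returns the weight, full geometric length, parent pointer (0-based linear
// index, -1 at the source/unreached) per pixel, for a single source.
// [[Rcpp::export(name = ".grid_route")]]
List grid_route(LogicalMatrix skel, int r0, int c0) {
  const double SQ2 = std::sqrt(2.0);
  int nr = skel.nrow(), nc = skel.ncol(), n = nr * nc;
  if (r0 < 1 || r0 > nr || c0 < 1 || c0 > nc)
    stop("route source outside the grid");
  std::vector<int> wcost(n, INT_MAX);
  std::vector<double> glen(n, R_PosInf);
  std::vector<int> parent(n, -1);
  // key: lexicographic (weight, geometric length) folded into one double;
  // geometric length < 2*(nr+nc) <= ~1e5, so 1e7 separates weight levels.
  typedef std::pair<double, int> QN;
  std::priority_queue<QN, std::vector<QN>, std::greater<QN> > pq;
  int s = (r0 - 1) + (c0 - 1) * nr;
  wcost[s] = 0; glen[s] = 0.0;
  pq.push(QN(0.0, s));
  const int di[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dj[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  while (!pq.empty()) {
    QN top = pq.top(); pq.pop();
    int u = top.second;
    double key = (double)wcost[u] * 1e7 + glen[u];
    if (top.first > key + 1e-9) continue;
    int ui = u % nr, uj = u / nr;
    for (int k = 0; k < 8; ++k) {
      int vi = ui + di[k], vj = uj + dj[k];
      if (vi < 0 || vj < 0 || vi >= nr || vj >= nc) continue;
      int v = vi + vj * nr;
      int w2 = wcost[u] + (skel(vi, vj) ? 0 : 1);
      double g2 = glen[u] + ((di[k] != 0 && dj[k] != 0) ? SQ2 : 1.0);
      if (w2 < wcost[v] || (w2 == wcost[v] && g2 < glen[v] - 1e-9)) {
        wcost[v] = w2; glen[v] = g2; parent[v] = u;
        pq.push(QN((double)w2 * 1e7 + g2, v));
      }
    }
  }
  IntegerMatrix W(nr, nc), P(nr, nc);
  NumericMatrix G(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int u = i + j * nr;
      W(i, j) = (wcost[u] == INT_MAX) ? NA_INTEGER : wcost[u];
      G(i, j) = glen[u];
      P(i, j) = parent[u];
    }
  return List::create(_["weight"] = W, _["glen"] = G, _["parent"] = P);
}

// Reconstruct the route to (r1, c1) from a parent-pointer matrix produced by
// .grid_route. Returns an m x 2 matrix of 1-based (row, col), source first.
// [[Rcpp::export(name = ".route_path")]]
IntegerMatrix route_path(IntegerMatrix parent, int r1, int c1) {
  int nr = parent.nrow();
  std::vector<int> rev;
  int u = (r1 - 1) + (c1 - 1) * nr;
  rev.push_back(u);
  while (parent[u] >= 0) {
    u = parent[u];
    rev.push_back(u);
    if ((int)rev.size() > parent.nrow() * parent.ncol())
      stop("cycle in parent pointers");
  }
  int m = rev.size();
  IntegerMatrix path(m, 2);
  for (int k = 0; k < m; ++k) {
    int v = rev[m - 1 - k];
    path(k, 0) = v % nr + 1;
    path(k, 1) = v / nr + 1;
  }
  return path;
}

// Count of 8-neighbours that are TRUE, per pixel.
// [[Rcpp::export(name = ".nbr_count")]]
IntegerMatrix nbr_count(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int cnt = 0;
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0) continue;
          int vi = i + di, vj = j + dj;
          if (vi < 0 || vj < 0 || vi >= nr || vj >= nc) continue;
          if (mask(vi, vj)) ++cnt;
        }
      out(i, j) = cnt;
    }
  return out;
}

// 8-connected component labelling (BFS), labels 1..k in scan order.
// [[Rcpp::export(name = ".label8")]]
IntegerMatrix label8(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  const int di[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dj[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int u = stack.back(); stack.pop_back();
        int ui = u % nr, uj = u / nr;
        for (int k = 0; k < 8; ++k) {
          int vi = ui + di[k], vj = uj + dj[k];
          if (vi < 0 || vj < 0 || vi >= nr || vj >= nc) continue;
          if (mask(vi, vj) && !lab(vi, vj)) {
            lab(vi, vj) = next;
            stack.push_back(vi + vj * nr);
          }
        }
      }
    }
  return lab;
}

// In-place rasterisation of a thick segment into a label matrix: pixels
// within halfwidth of the segment p0-p1 whose current label is in `over`
// are set to `value`. Mutates m (callers own the buffer).
// [[Rcpp::export(name = ".draw_segment_ip")]]
void draw_segment_ip(IntegerMatrix m, NumericVector p0, NumericVector p1,
                     double halfwidth, int value, IntegerVector over) {
  int nr = m.nrow(), nc = m.ncol();
  double r0d = std::min(p0[0], p1[0]) - halfwidth - 1;
  double r1d = std::max(p0[0], p1[0]) + halfwidth + 1;
  double c0d = std::min(p0[1], p1[1]) - halfwidth - 1;
  double c1d = std::max(p0[1], p1[1]) + halfwidth + 1;
  int r0 = std::max(0, (int)std::floor(r0d) - 1);
  int r1 = std::min(nr - 1, (int)std::ceil(r1d));
  int c0 = std::max(0, (int)std::floor(c0d) - 1);
  int c1 = std::min(nc - 1, (int)std::ceil(c1d));
  double vr = p1[0] - p0[0], vc = p1[1] - p0[1];
  double L2 = vr * vr + vc * vc;
  double h2 = halfwidth * halfwidth;
  for (int j = c0; j <= c1; ++j) {
    for (int i = r0; i <= r1; ++i) {
      double dr = (i + 1) - p0[0], dc = (j + 1) - p0[1];  // 1-based coords
      double t = L2 < 1e-12 ? 0.0 : (dr * vr + dc * vc) / L2;
      if (t < 0) t = 0; if (t > 1) t = 1;
      double er = dr - t * vr, ec = dc - t * vc;
      if (er * er + ec * ec > h2) continue;
      int cur = m(i, j);
      bool ok = false;
      for (int k = 0; k < over.size(); ++k) if (cur == over[k]) { ok = true; break; }
      if (ok) m(i, j) = value;
    }
  }
}

// In-place rasterisation of a (rotated) filled ellipse; `over` empty =
// overwrite any label.
// [[Rcpp::export(name = ".draw_ellipse_ip")]]
void draw_ellipse_ip(IntegerMatrix m, NumericVector center, NumericVector axes,
                     double theta, int value, IntegerVector over) {
  int nr = m.nrow(), nc = m.ncol();
  double rad = std::max(axes[0], axes[1]) + 2;
  int r0 = std::max(0, (int)std::floor(center[0] - rad) - 1);
  int r1 = std::min(nr - 1, (int)std::ceil(center[0] + rad));
  int c0 = std::max(0, (int)std::floor(center[1] - rad) - 1);
  int c1 = std::min(nc - 1, (int)std::ceil(center[1] + rad));
  double e1r = -std::cos(theta), e1c = std::sin(theta);
  double e2r = std::sin(theta),  e2c = std::cos(theta);
  for (int j = c0; j <= c1; ++j) {
    for (int i = r0; i <= r1; ++i) {
      double dr = (i + 1) - center[0], dc = (j + 1) - center[1];
      double q1 = (dr * e1r + dc * e1c) / axes[0];
      double q2 = (dr * e2r + dc * e2c) / axes[1];
      if (q1 * q1 + q2 * q2 > 1) continue;
      if (over.size()) {
        int cur = m(i, j);
        bool ok = false;
        for (int k = 0; k < over.size(); ++k) if (cur == over[k]) { ok = true; break; }
        if (!ok) continue;
      }
      m(i, j) = value;
    }
  }
}
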