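// Incremental Bowyer-Watson Delaunay triangulation in 2-D and 3-D.
//
// Hull handling uses a single symbolic vertex at infinity: cells incident
// to it represent hull facets, and a new point falls "inside their
// circumsphere" exactly when it is visible from the facet. This avoids the
// classic finite-super-simplex artifact where a real cell with a very
// large circumsphere swallows a bounding vertex and leaves a hole in the
// hull. In/circumsphere membership for finite cells uses the determinant
// (insphere/incircle) predicates, which stay well-conditioned where the
// naive |p - centre|^2 < r^2 test cancels catastrophically. Inputs are
// expected to be pre-conditioned by the caller (moderate scale, symbolic
// jitter), so plain double-precision predicates suffice; cell location is
// a linear scan, O(n^2) overall, adequate for the few thousand tracked
// nodes this package meshes.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <map>
#include <array>
#include <algorithm>

using namespace Rcpp;

namespace {

typedef std::array<double, 3> P3;
typedef std::array<double, 2> P2;

inline double det3(double a, double b, double c,
                   double d, double e, double f,
                   double g, double h, double i) {
  return a * (e * i - f * h) - b * (d * i - f * g) + c * (d * h - e * g);
}

double orient3d(const P3 &a, const P3 &b, const P3 &c, const P3 &d) {
  return det3(a[0] - d[0], a[1] - d[1], a[2] - d[2],
              b[0] - d[0], b[1] - d[1], b[2] - d[2],
              c[0] - d[0], c[1] - d[1], c[2] - d[2]);
}

// > 0 when p lies inside the circumsphere of (a,b,c,d) with
// orient3d(a,b,c,d) > 0; multiply by the orientation sign otherwise
double insphere(const P3 &a, const P3 &b, const P3 &c, const P3 &d, const P3 &p) {
  double m[4][4];
  const P3 *v[4] = {&a, &b, &c, &d};
  for (int r = 0; r < 4; ++r) {
    double n2 = 0;
    for (int col = 0; col < 3; ++col) {
      m[r][col] = (*v[r])[col] - p[col];
      n2 += m[r][col] * m[r][col];
    }
    m[r][3] = n2;
  }
  double det = 0;
  for (int r = 0; r < 4; ++r) {
    int rows[3], q = 0;
    for (int s = 0; s < 4; ++s) if (s != r) rows[q++] = s;
    const double minor = det3(m[rows[0]][0], m[rows[0]][1], m[rows[0]][2],
                              m[rows[1]][0], m[rows[1]][1], m[rows[1]][2],
                              m[rows[2]][0], m[rows[2]][1], m[rows[2]][2]);
    det += ((r % 2) ? 1.0 : -1.0) * m[r][3] * minor;
  }
  return det;
}

double orient2d(const P2 &a, const P2 &b, const P2 &c) {
  return (b[0] - a[0]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[0] - a[0]);
}

// > 0 when p lies inside the circumcircle of counter-clockwise (a,b,c)
double incircle2(const P2 &a, const P2 &b, const P2 &c, const P2 &p) {
  const double ax = a[0] - p[0], ay = a[1] - p[1];
  const double bx = b[0] - p[0], by = b[1] - p[1];
  const double cx = c[0] - p[0], cy = c[1] - p[1];
  return det3(ax, ay, ax * ax + ay * ay,
              bx, by, bx * bx + by * by,
              cx, cy, cx * cx + cy * cy);
}

}  // namespace

// [[Rcpp::export(name = "cpp_delaunay3")]]
IntegerMatrix cpp_delaunay3(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) Rcpp::stop("need at least 4 points");
  std::vector<P3> P(n);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf}, hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) {
      P[i][c] = pts(i, c);
      lo[c] = std::min(lo[c], P[i][c]);
      hi[c] = std::max(hi[c], P[i][c]);
    }
  double L = 0;
  for (int c = 0; c < 3; ++c) L = std::max(L, hi[c] - lo[c]);
  if (L <= 0) Rcpp::stop("all points coincide");
  const int INF = n;
  const double eps_len = 1e-12 * L, eps_area = 1e-12 * L * L,
               eps_vol = 1e-12 * L * L * L;

  // initial simplex: the best-conditioned tetrahedron reachable by greedy
  // extremal choices (farthest point, largest area, largest volume) so that
  // the interior reference point is robustly interior
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  double best = 0;
  for (int j = 1; j < n; ++j) {
    double d2 = 0;
    for (int c = 0; c < 3; ++c) d2 += (P[j][c] - P[i0][c]) * (P[j][c] - P[i0][c]);
    if (d2 > best) { best = d2; i1 = j; }
  }
  if (i1 < 0 || !(std::sqrt(best) > eps_len)) Rcpp::stop("all points coincide");
  best = 0;
  for (int j = 1; j < n; ++j) {
    if (j == i1) continue;
    double u[3], v[3], cr[3];
    for (int c = 0; c < 3; ++c) { u[c] = P[i1][c] - P[i0][c]; v[c] = P[j][c] - P[i0][c]; }
    cr[0] = u[1] * v[2] - u[2] * v[1];
    cr[1] = u[2] * v[0] - u[0] * v[2];
    cr[2] = u[0] * v[1] - u[1] * v[0];
    const double a2 = cr[0] * cr[0] + cr[1] * cr[1] + cr[2] * cr[2];
    if (a2 > best) { best = a2; i2 = j; }
  }
  if (i2 < 0 || !(std::sqrt(best) > eps_area))
    Rcpp::stop("points are collinear: no tetrahedra possible");
  best = 0;
  double best_abs = 0;
  for (int j = 1; j < n; ++j) {
    if (j == i1 || j == i2) continue;
    const double o = std::fabs(orient3d(P[i0], P[i1], P[i2], P[j]));
    if (o > best_abs) { best_abs = o; i3 = j; }
  }
  if (i3 < 0 || !(best_abs > eps_vol))
    Rcpp::stop("points are coplanar: no tetrahedra possible (use 2-D mode)");

  P3 Q;  // strictly interior reference point of the growing hull
  for (int c = 0; c < 3; ++c)
    Q[c] = (P[i0][c] + P[i1][c] + P[i2][c] + P[i3][c]) / 4.0;

  struct Cell { int v[4]; bool alive; };
  std::vector<Cell> cells;
  auto push_cell = [&](int a, int b, int c, int d) {
    Cell t; t.v[0] = a; t.v[1] = b; t.v[2] = c; t.v[3] = d; t.alive = true;
    cells.push_back(t);
  };
  push_cell(i0, i1, i2, i3);
  static const int fidx[4][3] = {{1, 2, 3}, {0, 3, 2}, {0, 1, 3}, {0, 2, 1}};
  {
    const int base[4] = {i0, i1, i2, i3};
    for (int f = 0; f < 4; ++f)
      push_cell(base[fidx[f][0]], base[fidx[f][1]], base[fidx[f][2]], INF);
  }

  auto cell_bad = [&](const Cell &t, const P3 &p) -> bool {
    int fin[4], nf = 0;
    bool inf = false;
    for (int k = 0; k < 4; ++k) {
      if (t.v[k] == INF) inf = true; else fin[nf++] = t.v[k];
    }
    if (!inf) {
      const double o = orient3d(P[t.v[0]], P[t.v[1]], P[t.v[2]], P[t.v[3]]);
      const double s = insphere(P[t.v[0]], P[t.v[1]], P[t.v[2]], P[t.v[3]], p);
      return s * (o >= 0 ? 1.0 : -1.0) > 0;
    }
    // hull cell: "inside the circumsphere" means visible from the facet,
    // strictly beyond its supporting plane (the symbolic jitter applied by
    // the caller keeps genuinely coplanar configurations off the boundary)
    const P3 &a = P[fin[0]], &b = P[fin[1]], &c = P[fin[2]];
    return orient3d(a, b, c, p) * orient3d(a, b, c, Q) < 0;
  };

  std::vector<int> order;
  order.reserve(n);
  for (int j = 0; j < n; ++j)
    if (j != i0 && j != i1 && j != i2 && j != i3) order.push_back(j);

  for (int ip : order) {
    const P3 &p = P[ip];
    std::vector<int> bad;
    for (std::size_t t = 0; t < cells.size(); ++t)
      if (cells[t].alive && cell_bad(cells[t], p)) bad.push_back((int)t);
    if (bad.empty())
      Rcpp::stop("point %d could not be inserted (duplicate or degenerate input?)",
                 ip + 1);
    std::map<std::array<int, 3>, std::pair<int, std::array<int, 3>>> faces;
    for (int t : bad) {
      for (int f = 0; f < 4; ++f) {
        std::array<int, 3> fv = {cells[t].v[fidx[f][0]], cells[t].v[fidx[f][1]],
                                 cells[t].v[fidx[f][2]]};
        std::array<int, 3> key = fv;
        std::sort(key.begin(), key.end());
        auto it = faces.find(key);
        if (it == faces.end()) faces[key] = {1, fv};
        else it->second.first += 1;
      }
      cells[t].alive = false;
    }
    for (auto &kv : faces) {
      if (kv.second.first != 1) continue;
      push_cell(kv.second.second[0], kv.second.second[1], kv.second.second[2], ip);
    }
#ifdef DELAUNAY_VALIDATE
    {
      std::map<std::array<int, 3>, int> cnt;
      for (auto &t : cells) {
        if (!t.alive) continue;
        for (int f = 0; f < 4; ++f) {
          std::array<int, 3> key = {t.v[fidx[f][0]], t.v[fidx[f][1]],
                                    t.v[fidx[f][2]]};
          std::sort(key.begin(), key.end());
          cnt[key] += 1;
        }
      }
      for (auto &kv : cnt)
        if (kv.second > 2)
          Rcpp::stop("structure broken after inserting point %d (face %d %d %d in %d cells)",
                     ip + 1, kv.first[0] + 1, kv.first[1] + 1, kv.first[2] + 1,
                     kv.second);
    }
#endif
  }

  std::vector<std::array<int, 4>> keep;
  for (auto &t : cells) {
    if (!t.alive) continue;
    if (t.v[0] == INF || t.v[1] == INF || t.v[2] == INF || t.v[3] == INF) continue;
    const double o = orient3d(P[t.v[0]], P[t.v[1]], P[t.v[2]], P[t.v[3]]);
    if (std::fabs(o) <= 6.0 * 1e-13 * L * L * L) continue;
    // edge-matrix signed volume det(b-a, c-a, d-a) = -orient3d(a,b,c,d)
    if (o < 0) keep.push_back({t.v[0], t.v[1], t.v[2], t.v[3]});
    else keep.push_back({t.v[0], t.v[1], t.v[3], t.v[2]});
  }
  IntegerMatrix out((int)keep.size(), 4);
  for (std::size_t i = 0; i < keep.size(); ++i)
    for (int c = 0; c < 4; ++c) out((int)i, c) = keep[i][c] + 1;  // 1-based
  return out;
}

// [[Rcpp::export(name = "cpp_delaunay2")]]
IntegerMatrix cpp_delaunay2(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 3) Rcpp::stop("need at least 3 points");
  std::vector<P2> P(n);
  double lo[2] = {R_PosInf, R_PosInf}, hi[2] = {R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 2; ++c) {
      P[i][c] = pts(i, c);
      lo[c] = std::min(lo[c], P[i][c]);
      hi[c] = std::max(hi[c], P[i][c]);
    }
  double L = 0;
  for (int c = 0; c < 2; ++c) L = std::max(L, hi[c] - lo[c]);
  if (L <= 0) Rcpp::stop("all points coincide");
  const int INF = n;
  const double eps_len = 1e-12 * L, eps_area = 1e-12 * L * L;

  int i0 = 0, i1 = -1, i2 = -1;
  double best = 0;
  for (int j = 1; j < n; ++j) {
    const double dx = P[j][0] - P[i0][0], dy = P[j][1] - P[i0][1];
    const double d2 = dx * dx + dy * dy;
    if (d2 > best) { best = d2; i1 = j; }
  }
  if (i1 < 0 || !(std::sqrt(best) > eps_len)) Rcpp::stop("all points coincide");
  best = 0;
  for (int j = 1; j < n; ++j) {
    if (j == i1) continue;
    const double o = std::fabs(orient2d(P[i0], P[i1], P[j]));
    if (o > best) { best = o; i2 = j; }
  }
  if (i2 < 0 || !(best > eps_area))
    Rcpp::stop("points are collinear: no triangles possible");

  P2 Q = {(P[i0][0] + P[i1][0] + P[i2][0]) / 3.0,
          (P[i0][1] + P[i1][1] + P[i2][1]) / 3.0};

  struct Cell { int v[3]; bool alive; };
  std::vector<Cell> cells;
  auto push_cell = [&](int a, int b, int c) {
    Cell t; t.v[0] = a; t.v[1] = b; t.v[2] = c; t.alive = true;
    cells.push_back(t);
  };
  push_cell(i0, i1, i2);
  push_cell(i0, i1, INF);
  push_cell(i1, i2, INF);
  push_cell(i2, i0, INF);

  auto cell_bad = [&](const Cell &t, const P2 &p) -> bool {
    int fin[3], nf = 0;
    bool inf = false;
    for (int k = 0; k < 3; ++k) {
      if (t.v[k] == INF) inf = true; else fin[nf++] = t.v[k];
    }
    if (!inf) {
      const double o = orient2d(P[t.v[0]], P[t.v[1]], P[t.v[2]]);
      const double s = incircle2(P[t.v[0]], P[t.v[1]], P[t.v[2]], p);
      return s * (o >= 0 ? 1.0 : -1.0) > 0;
    }
    const P2 &a = P[fin[0]], &b = P[fin[1]];
    return orient2d(a, b, p) * orient2d(a, b, Q) < 0;
  };

  static const int eidx[3][2] = {{0, 1}, {1, 2}, {2, 0}};
  std::vector<int> order;
  for (int j = 0; j < n; ++j)
    if (j != i0 && j != i1 && j != i2) order.push_back(j);

  for (int ip : order) {
    const P2 &p = P[ip];
    std::vector<int> bad;
    for (std::size_t t = 0; t < cells.size(); ++t)
      if (cells[t].alive && cell_bad(cells[t], p)) bad.push_back((int)t);
    if (bad.empty())
      Rcpp::stop("point %d could not be inserted (duplicate or degenerate input?)",
                 ip + 1);
    std::map<std::array<int, 2>, std::pair<int, std::array<int, 2>>> edges;
    for (int t : bad) {
      for (int e = 0; e < 3; ++e) {
        std::array<int, 2> ev = {cells[t].v[eidx[e][0]], cells[t].v[eidx[e][1]]};
        std::array<int, 2> key = ev;
        std::sort(key.begin(), key.end());
        auto it = edges.find(key);
        if (it == edges.end()) edges[key] = {1, ev};
        else it->second.first += 1;
      }
      cells[t].alive = false;
    }
    for (auto &kv : edges) {
      if (kv.second.first != 1) continue;
      push_cell(kv.second.second[0], kv.second.second[1], ip);
    }
  }

  std::vector<std::array<int, 3>> keep;
  for (auto &t : cells) {
    if (!t.alive) continue;
    if (t.v[0] == INF || t.v[1] == INF || t.v[2] == INF) continue;
    const double o = orient2d(P[t.v[0]], P[t.v[1]], P[t.v[2]]);
    if (std::fabs(o) <= 2.0 * 1e-13 * L * L) continue;
    if (o > 0) keep.push_back({t.v[0], t.v[1], t.v[2]});
    else keep.push_back({t.v[0], t.v[2], t.v[1]});
  }
  IntegerMatrix out((int)keep.size(), 3);
  for (std::size_t i = 0; i < keep.size(); ++i)
    for (int c = 0; c < 3; ++c) out((int)i, c) = keep[i][c] + 1;
  return out;
}
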