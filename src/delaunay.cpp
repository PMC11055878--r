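// Delaunay triangulation (Bowyer-Watson) with Voronoi cell areas and the
// Delaunay edge list, used for density-based segmentation of localization
// point clouds. Points are assumed to be in general position (continuous
// coordinates); exact duplicates must be removed by the caller.
#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <array>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Tri {
  int a, b, c;          // vertex ids, CCW
  double ccx, ccy, r2;  // circumcircle (normalized coordinates)
  bool alive;
};

inline int64_t ekey(int u, int v) {
  if (u > v) std::swap(u, v);
  return (int64_t)u * 10000000LL + (int64_t)v;
}

struct Mesh {
  std::vector<double> px, py;
  std::vector<Tri> tris;
  std::unordered_map<int64_t, std::array<int, 2>> emap;

  double orient(int a, int b, double qx, double qy) const {
    return (px[b] - px[a]) * (qy - py[a]) - (py[b] - py[a]) * (qx - px[a]);
  }

  void reg(int u, int v, int t) {
    int64_t k = ekey(u, v);
    auto it = emap.find(k);
    if (it == emap.end()) {
      emap[k] = {t, -1};
    } else {
      if (it->second[0] == -1) it->second[0] = t; else it->second[1] = t;
    }
  }

  void unreg(int u, int v, int t) {
    int64_t k = ekey(u, v);
    auto it = emap.find(k);
    if (it == emap.end()) return;
    if (it->second[0] == t) it->second[0] = -1;
    if (it->second[1] == t) it->second[1] = -1;
    if (it->second[0] == -1 && it->second[1] == -1) emap.erase(it);
  }

  int neighbor(int u, int v, int t) const {
    auto it = emap.find(ekey(u, v));
    if (it == emap.end()) return -1;
    if (it->second[0] != t && it->second[0] != -1) return it->second[0];
    if (it->second[1] != t && it->second[1] != -1) return it->second[1];
    return -1;
  }

  int addTri(int a, int b, int c) {
    if (orient(a, b, px[c], py[c]) < 0) std::swap(b, c);
    Tri t;
    t.a = a; t.b = b; t.c = c; t.alive = true;
    double ax = px[a], ay = py[a], bx = px[b], by = py[b], cx = px[c], cy = py[c];
    double d = 2.0 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by));
    if (std::fabs(d) < 1e-300) {
      t.ccx = (ax + bx + cx) / 3.0; t.ccy = (ay + by + cy) / 3.0; t.r2 = 1e300;
    } else {
      double a2 = ax * ax + ay * ay, b2 = bx * bx + by * by, c2 = cx * cx + cy * cy;
      t.ccx = (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d;
      t.ccy = (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d;
      double dx = t.ccx - ax, dy = t.ccy - ay;
      t.r2 = dx * dx + dy * dy;
    }
    tris.push_back(t);
    int id = (int)tris.size() - 1;
    reg(a, b, id); reg(b, c, id); reg(c, a, id);
    return id;
  }

  bool inCircle(int t, double qx, double qy) const {
    double dx = qx - tris[t].ccx, dy = qy - tris[t].ccy;
    return dx * dx + dy * dy <= tris[t].r2 * (1.0 + 1e-12);
  }

  int locate(double qx, double qy, int hint) const {
    int t = hint;
    int maxit = (int)tris.size() * 4 + 64;
    for (int it = 0; it < maxit; ++it) {
      const Tri &T = tris[t];
      int vs[3] = {T.a, T.b, T.c};
      int moved = -1;
      for (int e = 0; e < 3; ++e) {
        int u = vs[e], v = vs[(e + 1) % 3];
        if (orient(u, v, qx, qy) < 0) {
          int nb = neighbor(u, v, t);
          if (nb >= 0) { moved = nb; break; }
        }
      }
      if (moved < 0) return t;
      t = moved;
    }
    // fallback: any alive triangle whose circumcircle contains the point
    for (int i = (int)tris.size() - 1; i >= 0; --i)
      if (tris[i].alive && inCircle(i, qx, qy)) return i;
    return -1;
  }

  int insert(int i, int hint) {
    double qx = px[i], qy = py[i];
    int t0 = locate(qx, qy, hint);
    if (t0 < 0 || !inCircle(t0, qx, qy)) {
      t0 = -1;
      for (int t = (int)tris.size() - 1; t >= 0; --t)
        if (tris[t].alive && inCircle(t, qx, qy)) { t0 = t; break; }
      if (t0 < 0) return hint;  // degenerate / duplicate: skip
    }
    std::unordered_set<int> bad;
    std::vector<int> stack{t0};
    bad.insert(t0);
    while (!stack.empty()) {
      int t = stack.back(); stack.pop_back();
      const Tri &T = tris[t];
      int vs[3] = {T.a, T.b, T.c};
      for (int e = 0; e < 3; ++e) {
        int nb = neighbor(vs[e], vs[(e + 1) % 3], t);
        if (nb >= 0 && !bad.count(nb) && inCircle(nb, qx, qy)) {
          bad.insert(nb);
          stack.push_back(nb);
        }
      }
    }
    // boundary edges of the cavity, oriented CCW w.r.t. their bad triangle
    std::vector<std::pair<int, int>> boundary;
    for (int t : bad) {
      const Tri &T = tris[t];
      int vs[3] = {T.a, T.b, T.c};
      for (int e = 0; e < 3; ++e) {
        int u = vs[e], v = vs[(e + 1) % 3];
        int nb = neighbor(u, v, t);
        if (nb < 0 || !bad.count(nb)) boundary.emplace_back(u, v);
      }
    }
    for (int t : bad) {
      const Tri &T = tris[t];
      unreg(T.a, T.b, t); unreg(T.b, T.c, t); unreg(T.c, T.a, t);
      tris[t].alive = false;
    }
    int last = hint;
    for (auto &e : boundary) last = addTri(e.first, e.second, i);
    return last;
  }
};

}  // namespace

// [[Rcpp::export]]
List delaunay_info_cpp(NumericVector x, NumericVector y) {
  int n = x.size();
  if (n < 3) stop("need at least 3 points");
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
    ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
  }
  double cx = 0.5 * (xmin + xmax), cy = 0.5 * (ymin + ymax);
  double span = std::max({xmax - xmin, ymax - ymin, 1e-9});

  Mesh m;
  m.px.resize(n + 3); m.py.resize(n + 3);
  for (int i = 0; i < n; ++i) {
    m.px[i] = (x[i] - cx) / span;
    m.py[i] = (y[i] - cy) / span;
  }
  const double M = 1e4;  // far super-triangle; real hull points are flagged unbounded
  m.px[n] = -3 * M; m.py[n] = -M;
  m.px[n + 1] = 3 * M; m.py[n + 1] = -M;
  m.px[n + 2] = 0; m.py[n + 2] = 3 * M;
  m.tris.reserve(2 * n + 16);
  m.addTri(n, n + 1, n + 2);

  // insert in spatially coherent (grid snake) order so the walk stays local
  int ng = std::max(1, (int)std::sqrt((double)n / 2.0));
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    int gxa = (int)((m.px[a] + 0.6) * ng), gxb = (int)((m.px[b] + 0.6) * ng);
    if (gxa != gxb) return gxa < gxb;
    double ya = (gxa % 2 == 0) ? m.py[a] : -m.py[a];
    double yb = (gxb % 2 == 0) ? m.py[b] : -m.py[b];
    if (ya != yb) return ya < yb;
    return a < b;
  });
  int hint = 0;
  for (int k = 0; k < n; ++k) hint = m.insert(ord[k], hint);

  // collect Delaunay edges between real points and per-point circumcenter fans
  std::unordered_set<int64_t> eset;
  std::vector<std::vector<double>> fanx(n), fany(n);
  std::vector<char> unbounded(n, 0);
  for (const Tri &t : m.tris) {
    if (!t.alive) continue;
    int vs[3] = {t.a, t.b, t.c};
    bool super = (t.a >= n || t.b >= n || t.c >= n);
    for (int e = 0; e < 3; ++e) {
      int u = vs[e], v = vs[(e + 1) % 3];
      if (u < n && v < n) eset.insert(ekey(u, v));
      if (u < n) {
        if (super) unbounded[u] = 1;
        else { fanx[u].push_back(t.ccx); fany[u].push_back(t.ccy); }
      }
    }
  }

  NumericVector area(n);
  for (int i = 0; i < n; ++i) {
    if (unbounded[i] || fanx[i].size() < 3) { area[i] = R_PosInf; continue; }
    int k = (int)fanx[i].size();
    std::vector<int> idx(k);
    for (int j = 0; j < k; ++j) idx[j] = j;
    double ox = m.px[i], oy = m.py[i];
    std::vector<double> ang(k);
    for (int j = 0; j < k; ++j) ang[j] = std::atan2(fany[i][j] - oy, fanx[i][j] - ox);
    std::sort(idx.begin(), idx.end(), [&](int a, int b) { return ang[a] < ang[b]; });
    double A = 0;
    for (int j = 0; j < k; ++j) {
      int p = idx[j], q = idx[(j + 1) % k];
      A += fanx[i][p] * fany[i][q] - fanx[i][q] * fany[i][p];
    }
    area[i] = 0.5 * std::fabs(A) * span * span;
  }

  IntegerMatrix edges((int)eset.size(), 2);
  int r = 0;
  for (int64_t k : eset) {
    edges(r, 0) = (int)(k / 10000000LL) + 1;
    edges(r, 1) = (int)(k % 10000000LL) + 1;
    ++r;
  }
  return List::create(_["edges"] = edges, _["area"] = area);
}
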