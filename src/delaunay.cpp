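// Incremental Bowyer-Watson Delaunay triangulation of 2D point sets.
//
// Canopy scans carry 1e5+ points per sector, so the triangulation backing the
// 2.5D surface reconstruction has to run in roughly linear time: points are
// inserted in a spatially coherent order and located by walking from the last
// triangle touched. Predicates use double arithmetic on coordinates carrying a
// deterministic sub-micrometre symbolic jitter, which keeps exactly cocircular
// configurations (raster-grid scans) away from zero determinants; triangle
// indices refer to the caller's unperturbed coordinates.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
#include <unordered_map>
using namespace Rcpp;

namespace {

struct Tri {
  int v[3];   // vertex ids, CCW
  int n[3];   // n[i] = triangle opposite v[i] (across edge v[i+1]-v[i+2]), -1 if none
  bool alive;
};

// splitmix64-style hash mapped to [-0.5, 0.5)
inline double hash_jitter(uint64_t i) {
  uint64_t z = i + 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  z = z ^ (z >> 31);
  return static_cast<double>(z >> 11) / 9007199254740992.0 - 0.5;
}

struct Mesh {
  std::vector<double> px, py;
  std::vector<Tri> tris;
  int nreal = 0;  // vertex ids >= nreal are super-triangle corners

  double orient(int a, int b, int c) const {
    return (px[b] - px[a]) * (py[c] - py[a]) - (py[b] - py[a]) * (px[c] - px[a]);
  }

  // > 0 iff p strictly inside circumcircle of CCW triangle (a, b, c)
  double incircle(int a, int b, int c, int p) const {
    const double ax = px[a] - px[p], ay = py[a] - py[p];
    const double bx = px[b] - px[p], by = py[b] - py[p];
    const double cx = px[c] - px[p], cy = py[c] - py[p];
    const double a2 = ax * ax + ay * ay;
    const double b2 = bx * bx + by * by;
    const double c2 = cx * cx + cy * cy;
    return ax * (by * c2 - b2 * cy) - ay * (bx * c2 - b2 * cx) + a2 * (bx * cy - by * cx);
  }

  // Is p inside the circumdisk of triangle t? The super-triangle corners sit
  // ~3000 bounding boxes away, so only hull slivers of negligible relative
  // area are ever absorbed by super-adjacent triangles.
  bool in_disk(int t, int p) const {
    const Tri& T = tris[t];
    return incircle(T.v[0], T.v[1], T.v[2], p) > 0.0;
  }

  bool contains(int t, int p) const {
    const Tri& T = tris[t];
    for (int i = 0; i < 3; ++i)
      if (orient(T.v[(i + 1) % 3], T.v[(i + 2) % 3], p) < 0.0) return false;
    return true;
  }
};

}  // namespace

// [[Rcpp::export(name = ".delaunay_xy")]]
IntegerMatrix delaunay_xy(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (n < 3) return IntegerMatrix(0, 3);

  double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, (double)x[i]); xmax = std::max(xmax, (double)x[i]);
    ymin = std::min(ymin, (double)y[i]); ymax = std::max(ymax, (double)y[i]);
  }
  const double R = std::max({xmax - xmin, ymax - ymin, 1e-9});
  const double cx = 0.5 * (xmin + xmax), cy = 0.5 * (ymin + ymax);
  const double eps = 1e-7 * R;  // symbolic perturbation scale

  Mesh m;
  m.nreal = n;
  m.px.resize(n + 3); m.py.resize(n + 3);
  for (int i = 0; i < n; ++i) {
    m.px[i] = x[i] + eps * hash_jitter(2 * (uint64_t)i);
    m.py[i] = y[i] + eps * hash_jitter(2 * (uint64_t)i + 1);
  }
  // enclosing super-triangle, far outside the data
  const double S = 3000.0 * R;
  m.px[n]     = cx - S;  m.py[n]     = cy - 0.7 * S;
  m.px[n + 1] = cx + S;  m.py[n + 1] = cy - 0.7 * S;
  m.px[n + 2] = cx;      m.py[n + 2] = cy + S;

  Tri t0; t0.v[0] = n; t0.v[1] = n + 1; t0.v[2] = n + 2;
  t0.n[0] = t0.n[1] = t0.n[2] = -1; t0.alive = true;
  m.tris.push_back(t0);

  // serpentine cell order for locality of the walk
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  const int ncell = std::max(1, (int)std::floor(std::sqrt((double)n)));
  std::vector<int64_t> key(n);
  for (int i = 0; i < n; ++i) {
    int ix = std::min(ncell - 1, (int)((m.px[i] - xmin) / R * ncell));
    int iy = std::min(ncell - 1, (int)((m.py[i] - ymin) / R * ncell));
    ix = std::max(0, ix); iy = std::max(0, iy);
    if (iy & 1) ix = ncell - 1 - ix;
    key[i] = (int64_t)iy * ncell + ix;
  }
  std::stable_sort(order.begin(), order.end(),
                   [&](int a, int b) { return key[a] < key[b]; });

  std::vector<int> stamp;          // per-triangle "bad for point p" marks
  std::vector<int> stack, bad;
  int last = 0;

  for (int oi = 0; oi < n; ++oi) {
    const int p = order[oi];

    // locate by walking
    int t = last, steps = 0;
    const int max_steps = (int)m.tris.size() * 2 + 64;
    while (true) {
      if (!m.tris[t].alive) { t = (int)m.tris.size() - 1; continue; }
      const Tri& T = m.tris[t];
      int moved = -1;
      for (int i = 0; i < 3; ++i) {
        if (m.orient(T.v[(i + 1) % 3], T.v[(i + 2) % 3], p) < 0.0) { moved = T.n[i]; break; }
      }
      if (moved < 0) break;
      t = moved;
      if (++steps > max_steps) {  // numerical trouble: exhaustive fallback
        t = -1;
        for (int j = 0; j < (int)m.tris.size(); ++j)
          if (m.tris[j].alive && m.contains(j, p)) { t = j; break; }
        if (t < 0) stop("point location failed");
        break;
      }
    }

    // grow the cavity of circumcircle-violating triangles
    stamp.resize(m.tris.size(), -1);
    bad.clear(); stack.clear();
    stack.push_back(t); stamp[t] = p;
    while (!stack.empty()) {
      int b = stack.back(); stack.pop_back();
      bad.push_back(b);
      const Tri& B = m.tris[b];
      for (int i = 0; i < 3; ++i) {
        int nb = B.n[i];
        if (nb >= 0 && stamp[nb] != p && m.tris[nb].alive && m.in_disk(nb, p)) {
          stamp[nb] = p;
          stack.push_back(nb);
        }
      }
    }

    // boundary edges of the cavity, directed so the new triangle (p, a, b) is CCW
    struct BEdge { int a, b, outer, from; };
    std::vector<BEdge> edges;
    for (int b : bad) {
      const Tri& B = m.tris[b];
      for (int i = 0; i < 3; ++i) {
        int nb = B.n[i];
        if (nb < 0 || stamp[nb] != p)
          edges.push_back({B.v[(i + 1) % 3], B.v[(i + 2) % 3], nb, b});
      }
    }
    for (int b : bad) m.tris[b].alive = false;

    std::unordered_map<int, int> byStart, byEnd;
    byStart.reserve(edges.size() * 2); byEnd.reserve(edges.size() * 2);
    std::vector<int> created;
    created.reserve(edges.size());
    for (const BEdge& e : edges) {
      Tri nt;
      nt.v[0] = p; nt.v[1] = e.a; nt.v[2] = e.b;
      nt.n[0] = e.outer; nt.n[1] = -1; nt.n[2] = -1;
      nt.alive = true;
      const int idx = (int)m.tris.size();
      m.tris.push_back(nt);
      stamp.push_back(-1);
      if (e.outer >= 0) {
        Tri& O = m.tris[e.outer];
        for (int i = 0; i < 3; ++i) if (O.n[i] == e.from) { O.n[i] = idx; break; }
      }
      byStart[e.a] = idx; byEnd[e.b] = idx;
      created.push_back(idx);
    }
    for (int idx : created) {
      Tri& T = m.tris[idx];
      T.n[1] = byStart[T.v[2]];  // across edge (b, p): triangle starting at b
      T.n[2] = byEnd[T.v[1]];    // across edge (p, a): triangle ending at a
    }
    last = created.empty() ? last : created.back();
  }

  int count = 0;
  for (const Tri& T : m.tris)
    if (T.alive && T.v[0] < n && T.v[1] < n && T.v[2] < n) ++count;
  IntegerMatrix out(count, 3);
  int r = 0;
  for (const Tri& T : m.tris) {
    if (T.alive && T.v[0] < n && T.v[1] < n && T.v[2] < n) {
      out(r, 0) = T.v[0] + 1; out(r, 1) = T.v[1] + 1; out(r, 2) = T.v[2] + 1;
      ++r;
    }
  }
  return out;
}
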