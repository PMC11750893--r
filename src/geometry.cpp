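// Computational-geometry kernels: incremental 3D convex hull volume and a
// grid-accelerated triangle-triangle self-intersection test. Written from
// scratch; both are O(n)-ish for the point counts used here.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <unordered_map>

using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 sub(const Vec3& a, const Vec3& b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double dot(const Vec3& a, const Vec3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }

struct Facet {
  int a, b, c;      // vertex indices, outward orientation
  Vec3 n;           // unit-ish normal (not normalized)
  double d;         // plane offset: dot(n, p) = d
  bool alive;
};

inline Facet make_facet(int a, int b, int c, const std::vector<Vec3>& P,
                        const Vec3& inside) {
  Facet f{a, b, c, {0, 0, 0}, 0.0, true};
  f.n = cross(sub(P[b], P[a]), sub(P[c], P[a]));
  f.d = dot(f.n, P[a]);
  if (dot(f.n, inside) > f.d) {  // flip to point away from the interior
    std::swap(f.b, f.c);
    f.n = {-f.n.x, -f.n.y, -f.n.z};
    f.d = -f.d;
  }
  return f;
}

}  // namespace

// Volume of the convex hull of a 3D point set (incremental algorithm).
// Degenerate inputs (fewer than 4 points, coplanar) return 0.
// [[Rcpp::export(name = "convhull_volume_cpp")]]
double convhull_volume_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) return 0.0;
  std::vector<Vec3> P(n);
  double scale = 0.0;
  for (int i = 0; i < n; ++i) {
    P[i] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    scale = std::max(scale, std::fabs(P[i].x));
    scale = std::max(scale, std::fabs(P[i].y));
    scale = std::max(scale, std::fabs(P[i].z));
  }
  const double eps = 1e-9 * std::max(scale, 1.0);

  // initial tetrahedron: two extreme points, then max-distance to line, then
  // max-distance to plane
  int i0 = 0, i1 = 0;
  for (int i = 1; i < n; ++i) {
    if (P[i].x < P[i0].x) i0 = i;
    if (P[i].x > P[i1].x) i1 = i;
  }
  if (norm(sub(P[i1], P[i0])) < eps) return 0.0;
  int i2 = -1;
  double best = eps;
  Vec3 dir = sub(P[i1], P[i0]);
  for (int i = 0; i < n; ++i) {
    double d = norm(cross(dir, sub(P[i], P[i0]))) / norm(dir);
    if (d > best) { best = d; i2 = i; }
  }
  if (i2 < 0) return 0.0;
  Vec3 nrm = cross(sub(P[i1], P[i0]), sub(P[i2], P[i0]));
  int i3 = -1;
  best = eps;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(dot(nrm, sub(P[i], P[i0]))) / norm(nrm);
    if (d > best) { best = d; i3 = i; }
  }
  if (i3 < 0) return 0.0;  // coplanar

  Vec3 inside = {(P[i0].x + P[i1].x + P[i2].x + P[i3].x) / 4.0,
                 (P[i0].y + P[i1].y + P[i2].y + P[i3].y) / 4.0,
                 (P[i0].z + P[i1].z + P[i2].z + P[i3].z) / 4.0};

  std::vector<Facet> facets;
  facets.push_back(make_facet(i0, i1, i2, P, inside));
  facets.push_back(make_facet(i0, i1, i3, P, inside));
  facets.push_back(make_facet(i0, i2, i3, P, inside));
  facets.push_back(make_facet(i1, i2, i3, P, inside));

  for (int p = 0; p < n; ++p) {
    if (p == i0 || p == i1 || p == i2 || p == i3) continue;
    // collect facets visible from P[p]
    std::vector<int> visible;
    for (size_t f = 0; f < facets.size(); ++f) {
      if (!facets[f].alive) continue;
      if (dot(facets[f].n, P[p]) - facets[f].d > eps * norm(facets[f].n))
        visible.push_back((int)f);
    }
    if (visible.empty()) continue;  // interior point
    // horizon = edges bounding the visible region (edges seen exactly once)
    std::unordered_map<long long, std::pair<int, int>> edge_count;
    auto add_edge = [&](int u, int v) {
      long long key = (long long)std::min(u, v) * 1000000007LL + std::max(u, v);
      auto it = edge_count.find(key);
      if (it == edge_count.end()) edge_count[key] = {u, v};
      else edge_count.erase(it);  // shared edge between two visible facets
    };
    for (int f : visible) {
      add_edge(facets[f].a, facets[f].b);
      add_edge(facets[f].b, facets[f].c);
      add_edge(facets[f].c, facets[f].a);
      facets[f].alive = false;
    }
    for (auto& kv : edge_count)
      facets.push_back(make_facet(kv.second.first, kv.second.second, p, P, inside));
  }

  double vol6 = 0.0;
  for (const auto& f : facets) {
    if (!f.alive) continue;
    // signed tetra volume w.r.t. the interior point (outward normals -> +)
    Vec3 a = sub(P[f.a], inside), b = sub(P[f.b], inside), c = sub(P[f.c], inside);
    vol6 += dot(a, cross(b, c));
  }
  return std::fabs(vol6) / 6.0;
}

namespace {

// Moller's triangle-triangle intersection test (no epsilon shrinking).
bool tri_tri_overlap(const Vec3* T1, const Vec3* T2, double eps) {
  Vec3 n1 = cross(sub(T1[1], T1[0]), sub(T1[2], T1[0]));
  double d1 = -dot(n1, T1[0]);
  double du[3], dv[3];
  for (int i = 0; i < 3; ++i) du[i] = dot(n1, T2[i]) + d1;
  for (int i = 0; i < 3; ++i) if (std::fabs(du[i]) < eps) du[i] = 0.0;
  if ((du[0] > 0 && du[1] > 0 && du[2] > 0) ||
      (du[0] < 0 && du[1] < 0 && du[2] < 0)) return false;

  Vec3 n2 = cross(sub(T2[1], T2[0]), sub(T2[2], T2[0]));
  double d2 = -dot(n2, T2[0]);
  for (int i = 0; i < 3; ++i) dv[i] = dot(n2, T1[i]) + d2;
  for (int i = 0; i < 3; ++i) if (std::fabs(dv[i]) < eps) dv[i] = 0.0;
  if ((dv[0] > 0 && dv[1] > 0 && dv[2] > 0) ||
      (dv[0] < 0 && dv[1] < 0 && dv[2] < 0)) return false;

  // coplanar triangles: treat as non-intersecting (adjacent mesh faces share
  // planes legitimately; true coplanar overlap is caught by the normal test)
  if (du[0] == 0 && du[1] == 0 && du[2] == 0) return false;

  Vec3 D = cross(n1, n2);
  // project onto the dominant axis of D
  double ax = std::fabs(D.x), ay = std::fabs(D.y), az = std::fabs(D.z);
  auto proj = [&](const Vec3& p) {
    if (ax >= ay && ax >= az) return p.x;
    if (ay >= az) return p.y;
    return p.z;
  };

  auto interval = [&](const Vec3* T, const double* dd, double& t0, double& t1) -> bool {
    // find the vertex alone on one side
    int alone = -1;
    if (dd[0] * dd[1] > 0) alone = 2;
    else if (dd[0] * dd[2] > 0) alone = 1;
    else if (dd[1] * dd[2] > 0) alone = 0;
    else {
      // some zero distances; pick a nonzero-alone configuration
      if (dd[0] != 0) alone = 0;
      else if (dd[1] != 0) alone = 1;
      else if (dd[2] != 0) alone = 2;
      else return false;
    }
    int j = (alone + 1) % 3, k = (alone + 2) % 3;
    double pa = proj(T[alone]), pj = proj(T[j]), pk = proj(T[k]);
    double denom_j = dd[alone] - dd[j], denom_k = dd[alone] - dd[k];
    t0 = (std::fabs(denom_j) < 1e-300) ? pj : pj + (pa - pj) * dd[j] / (dd[j] - dd[alone]);
    t1 = (std::fabs(denom_k) < 1e-300) ? pk : pk + (pa - pk) * dd[k] / (dd[k] - dd[alone]);
    if (t0 > t1) std::swap(t0, t1);
    return true;
  };

  double s0, s1, u0, u1;
  if (!interval(T1, dv, s0, s1)) return false;
  if (!interval(T2, du, u0, u1)) return false;
  return std::max(s0, u0) < std::min(s1, u1) - eps;
}

}  // namespace

// Self-intersection test for a triangle mesh: returns true when any pair of
// non-adjacent (no shared vertex) triangles intersects. Candidate pairs come
// from a uniform spatial hash grid over triangle bounding boxes.
// [[Rcpp::export(name = "mesh_self_intersects_cpp")]]
bool mesh_self_intersects_cpp(NumericMatrix pts, IntegerMatrix faces) {
  const int nf = faces.nrow();
  std::vector<std::array<Vec3, 3>> tri(nf);
  std::vector<std::array<double, 6>> box(nf);  // xmin xmax ymin ymax zmin zmax
  double diag = 0.0;
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int f = 0; f < nf; ++f) {
    for (int v = 0; v < 3; ++v) {
      int idx = faces(f, v) - 1;
      tri[f][v] = {pts(idx, 0), pts(idx, 1), pts(idx, 2)};
    }
    box[f] = {std::min({tri[f][0].x, tri[f][1].x, tri[f][2].x}),
              std::max({tri[f][0].x, tri[f][1].x, tri[f][2].x}),
              std::min({tri[f][0].y, tri[f][1].y, tri[f][2].y}),
              std::max({tri[f][0].y, tri[f][1].y, tri[f][2].y}),
              std::min({tri[f][0].z, tri[f][1].z, tri[f][2].z}),
              std::max({tri[f][0].z, tri[f][1].z, tri[f][2].z})};
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], box[f][2 * d]);
      hi[d] = std::max(hi[d], box[f][2 * d + 1]);
    }
  }
  for (int d = 0; d < 3; ++d) diag += (hi[d] - lo[d]) * (hi[d] - lo[d]);
  diag = std::sqrt(diag);
  const double eps = 1e-9 * std::max(diag, 1.0);

  // grid cell ~ median triangle size; use mean bbox extent as a cheap proxy
  double mean_ext = 0.0;
  for (int f = 0; f < nf; ++f)
    mean_ext += (box[f][1] - box[f][0]) + (box[f][3] - box[f][2]) + (box[f][5] - box[f][4]);
  mean_ext = std::max(mean_ext / (3.0 * nf), diag * 1e-6);
  const double cell = 2.0 * mean_ext;

  std::unordered_map<long long, std::vector<int>> grid;
  auto cell_key = [&](long long cx, long long cy, long long cz) {
    return (cx * 73856093LL) ^ (cy * 19349663LL) ^ (cz * 83492791LL);
  };
  for (int f = 0; f < nf; ++f) {
    long long x0 = (long long)std::floor((box[f][0] - lo[0]) / cell);
    long long x1 = (long long)std::floor((box[f][1] - lo[0]) / cell);
    long long y0 = (long long)std::floor((box[f][2] - lo[1]) / cell);
    long long y1 = (long long)std::floor((box[f][3] - lo[1]) / cell);
    long long z0 = (long long)std::floor((box[f][4] - lo[2]) / cell);
    long long z1 = (long long)std::floor((box[f][5] - lo[2]) / cell);
    for (long long cx = x0; cx <= x1; ++cx)
      for (long long cy = y0; cy <= y1; ++cy)
        for (long long cz = z0; cz <= z1; ++cz)
          grid[cell_key(cx, cy, cz)].push_back(f);
  }

  auto share_vertex = [&](int f, int g) {
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        if (faces(f, i) == faces(g, j)) return true;
    return false;
  };
  auto boxes_overlap = [&](int f, int g) {
    return box[f][0] <= box[g][1] + eps && box[g][0] <= box[f][1] + eps &&
           box[f][2] <= box[g][3] + eps && box[g][2] <= box[f][3] + eps &&
           box[f][4] <= box[g][5] + eps && box[g][4] <= box[f][5] + eps;
  };

  for (auto& kv : grid) {
    const std::vector<int>& cellfaces = kv.second;
    for (size_t i = 0; i < cellfaces.size(); ++i) {
      for (size_t j = i + 1; j < cellfaces.size(); ++j) {
        int f = cellfaces[i], g = cellfaces[j];
        if (share_vertex(f, g)) continue;
        if (!boxes_overlap(f, g)) continue;
        if (tri_tri_overlap(tri[f].data(), tri[g].data(), eps)) return true;
      }
    }
  }
  return false;
}
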