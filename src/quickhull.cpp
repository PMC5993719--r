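// 3D convex hull (quickhull with global visible-face search).
//
// Returns the hull as 0-based triangle indices into the input point matrix.
// Points within `eps` of a face plane are treated as on/inside it, so every
// input point is guaranteed to lie on the non-positive side of every output
// face plane up to eps.  Designed for the sizes this package meets: up to a
// few hundred thousand boundary voxels of a digitized spheroid.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <map>
#include <cmath>

using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 sub(const Vec3& a, const Vec3& b) {
  return Vec3{a.x - b.x, a.y - b.y, a.z - b.z};
}
inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3{a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
              a.x * b.y - a.y * b.x};
}
inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }

struct Face {
  int a, b, c;            // vertex indices into the point set
  Vec3 n;                 // unit outward normal
  double off;             // plane offset: dot(n, p) - off is signed distance
  std::vector<int> outside;
  bool alive = true;
};

// Plane through face vertices, oriented away from `interior`.
void set_plane(Face& f, const std::vector<Vec3>& P, const Vec3& interior) {
  Vec3 nn = cross(sub(P[f.b], P[f.a]), sub(P[f.c], P[f.a]));
  double L = norm(nn);
  if (L <= 0) stop("degenerate hull face (collinear vertices)");
  nn.x /= L; nn.y /= L; nn.z /= L;
  double off = dot(nn, P[f.a]);
  if (dot(nn, interior) - off > 0) {  // flip to point outward
    std::swap(f.b, f.c);
    nn.x = -nn.x; nn.y = -nn.y; nn.z = -nn.z;
    off = -off;
  }
  f.n = nn;
  f.off = off;
}

inline double sdist(const Face& f, const Vec3& p) {
  return dot(f.n, p) - f.off;
}

}  // namespace

// [[Rcpp::export(name = ".qhull3d")]]
List qhull3d(NumericMatrix pts, double eps) {
  const int n = pts.nrow();
  if (pts.ncol() != 3) stop("points must be an n x 3 matrix");
  if (n < 4) stop("need at least 4 points for a 3D hull");

  std::vector<Vec3> P(n);
  for (int i = 0; i < n; ++i) P[i] = Vec3{pts(i, 0), pts(i, 1), pts(i, 2)};

  // Initial simplex from extreme points.
  int lo[3] = {0, 0, 0}, hi[3] = {0, 0, 0};
  for (int i = 1; i < n; ++i) {
    const double c[3] = {P[i].x, P[i].y, P[i].z};
    double cl[3], ch[3];
    cl[0] = P[lo[0]].x; cl[1] = P[lo[1]].y; cl[2] = P[lo[2]].z;
    ch[0] = P[hi[0]].x; ch[1] = P[hi[1]].y; ch[2] = P[hi[2]].z;
    for (int d = 0; d < 3; ++d) {
      if (c[d] < cl[d]) lo[d] = i;
      if (c[d] > ch[d]) hi[d] = i;
    }
  }
  int cand[6] = {lo[0], lo[1], lo[2], hi[0], hi[1], hi[2]};
  int i0 = -1, i1 = -1;
  double best = -1;
  for (int s = 0; s < 6; ++s)
    for (int t = s + 1; t < 6; ++t) {
      double d = norm(sub(P[cand[s]], P[cand[t]]));
      if (d > best) { best = d; i0 = cand[s]; i1 = cand[t]; }
    }
  if (best <= eps) stop("all points coincide (within tolerance)");

  Vec3 dir = sub(P[i1], P[i0]);
  int i2 = -1;
  best = -1;
  for (int i = 0; i < n; ++i) {
    double d = norm(cross(dir, sub(P[i], P[i0]))) / norm(dir);
    if (d > best) { best = d; i2 = i; }
  }
  if (best <= eps) stop("points are collinear (within tolerance)");

  Vec3 nrm = cross(dir, sub(P[i2], P[i0]));
  double nl = norm(nrm);
  nrm.x /= nl; nrm.y /= nl; nrm.z /= nl;
  int i3 = -1;
  best = -1;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(dot(nrm, sub(P[i], P[i0])));
    if (d > best) { best = d; i3 = i; }
  }
  if (best <= eps) stop("points are coplanar (within tolerance)");

  Vec3 interior{(P[i0].x + P[i1].x + P[i2].x + P[i3].x) / 4.0,
                (P[i0].y + P[i1].y + P[i2].y + P[i3].y) / 4.0,
                (P[i0].z + P[i1].z + P[i2].z + P[i3].z) / 4.0};

  std::vector<Face> faces;
  faces.reserve(256);
  {
    int tet[4][3] = {{i0, i1, i2}, {i0, i1, i3}, {i0, i2, i3}, {i1, i2, i3}};
    for (auto& t : tet) {
      Face f; f.a = t[0]; f.b = t[1]; f.c = t[2];
      set_plane(f, P, interior);
      faces.push_back(f);
    }
  }

  // Assign every point to the first face it is outside of.
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    for (auto& f : faces)
      if (sdist(f, P[i]) > eps) { f.outside.push_back(i); break; }
  }

  std::vector<int> pending;
  for (int fi = 0; fi < (int)faces.size(); ++fi)
    if (!faces[fi].outside.empty()) pending.push_back(fi);

  while (!pending.empty()) {
    int fi = pending.back();
    pending.pop_back();
    Face& f0 = faces[fi];
    if (!f0.alive || f0.outside.empty()) continue;

    // Farthest outside point of this face.
    int far = -1;
    double fd = -1;
    for (int i : f0.outside) {
      double d = sdist(f0, P[i]);
      if (d > fd) { fd = d; far = i; }
    }
    const Vec3 fp = P[far];

    // All faces visible from it (global scan keeps the region exact even when
    // near-coplanar faces would break a local BFS).
    std::vector<int> visible;
    for (int k = 0; k < (int)faces.size(); ++k)
      if (faces[k].alive && sdist(faces[k], fp) > eps) visible.push_back(k);

    // Horizon: directed edges of visible faces whose reverse is not visible.
    std::map<std::pair<int, int>, int> edge_count;
    for (int k : visible) {
      const Face& f = faces[k];
      int e[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
      for (auto& ed : e) edge_count[{ed[0], ed[1]}]++;
    }
    std::vector<std::pair<int, int>> horizon;
    for (auto& kv : edge_count) {
      auto rev = std::make_pair(kv.first.second, kv.first.first);
      if (edge_count.find(rev) == edge_count.end()) horizon.push_back(kv.first);
    }

    // Collect orphaned outside points, retire visible faces.
    std::vector<int> orphans;
    for (int k : visible) {
      faces[k].alive = false;
      for (int i : faces[k].outside)
        if (i != far) orphans.push_back(i);
      faces[k].outside.clear();
      faces[k].outside.shrink_to_fit();
    }

    // New cone of faces from the horizon to the far point.
    std::vector<int> fresh;
    for (auto& ed : horizon) {
      Face nf; nf.a = ed.first; nf.b = ed.second; nf.c = far;
      set_plane(nf, P, interior);
      faces.push_back(nf);
      fresh.push_back((int)faces.size() - 1);
    }
    for (int i : orphans)
      for (int k : fresh)
        if (sdist(faces[k], P[i]) > eps) { faces[k].outside.push_back(i); break; }
    for (int k : fresh)
      if (!faces[k].outside.empty()) pending.push_back(k);
  }

  // Compact output: remap used vertices.
  std::vector<int> vmap(n, -1);
  std::vector<int> verts;
  int nf = 0;
  for (auto& f : faces) if (f.alive) ++nf;
  IntegerMatrix F(nf, 3);
  int r = 0;
  for (auto& f : faces) {
    if (!f.alive) continue;
    int idx[3] = {f.a, f.b, f.c};
    for (int d = 0; d < 3; ++d) {
      if (vmap[idx[d]] < 0) {
        vmap[idx[d]] = (int)verts.size();
        verts.push_back(idx[d]);
      }
      F(r, d) = vmap[idx[d]];
    }
    ++r;
  }
  return List::create(_["faces"] = F,
                      _["vertex_index"] = wrap(verts));
}
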