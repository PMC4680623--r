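#include <Rcpp.h>
#include <vector>
#include <map>
#include <set>
#include <utility>
#include <cstdint>

using namespace Rcpp;

// 3D convex hull of integer lattice points (incremental insertion with exact
// int64 orientation predicates) followed by half-space classification of all
// voxel centres of a grid. Coordinates stay small (voxel indices), so every
// determinant fits comfortably in 64 bits.

typedef int64_t i64;

struct P3 { i64 x, y, z; };

static inline P3 sub(const P3& a, const P3& b) {
  P3 r = { a.x - b.x, a.y - b.y, a.z - b.z };
  return r;
}
static inline P3 cross(const P3& a, const P3& b) {
  P3 r = { a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x };
  return r;
}
static inline i64 dot(const P3& a, const P3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
// det(b-a, c-a, p-a); > 0 when p is on the outward side of face (a,b,c)
static inline i64 orient(const P3& a, const P3& b, const P3& c, const P3& p) {
  return dot(cross(sub(b, a), sub(c, a)), sub(p, a));
}

struct Face { int a, b, c; bool alive; };

static inline i64 floor_div(i64 a, i64 b) { // b > 0
  return (a >= 0) ? a / b : -((-a + b - 1) / b);
}
static inline i64 ceil_div(i64 a, i64 b) { // b > 0
  return floor_div(a + b - 1, b);
}
static inline i64 gcd64(i64 a, i64 b) {
  if (a < 0) a = -a;
  if (b < 0) b = -b;
  while (b) { i64 t = a % b; a = b; b = t; }
  return a;
}

// [[Rcpp::export(name = ".hull_classify_cpp")]]
LogicalVector hull_classify_cpp(IntegerMatrix pts, IntegerVector dims) {
  const int n = pts.nrow();
  if (n < 4)
    stop("convex hull is degenerate: fewer than 4 candidate voxels");
  std::vector<P3> p(n);
  for (int i = 0; i < n; ++i) {
    p[i].x = pts(i, 0);
    p[i].y = pts(i, 1);
    p[i].z = pts(i, 2);
  }

  // initial simplex: two extreme points, farthest from their line, farthest
  // from their plane
  int i0 = 0, i1 = -1;
  for (int i = 1; i < n; ++i)
    if (p[i].x != p[i0].x || p[i].y != p[i0].y || p[i].z != p[i0].z) { i1 = i; break; }
  if (i1 < 0) stop("convex hull is degenerate: all voxels coincide");
  int i2 = -1;
  i64 best = 0;
  for (int i = 0; i < n; ++i) {
    P3 cr = cross(sub(p[i1], p[i0]), sub(p[i], p[i0]));
    i64 m = dot(cr, cr);
    if (m > best) { best = m; i2 = i; }
  }
  if (i2 < 0) stop("convex hull is degenerate: construct voxels are collinear");
  int i3 = -1;
  best = 0;
  for (int i = 0; i < n; ++i) {
    i64 o = orient(p[i0], p[i1], p[i2], p[i]);
    i64 m = (o >= 0) ? o : -o;
    if (m > best) { best = m; i3 = i; }
  }
  if (i3 < 0) stop("convex hull is degenerate: construct voxels are coplanar");
  if (orient(p[i0], p[i1], p[i2], p[i3]) > 0) std::swap(i1, i2);

  std::vector<Face> faces;
  Face f1 = { i0, i1, i2, true }; faces.push_back(f1);
  Face f2 = { i0, i3, i1, true }; faces.push_back(f2);
  Face f3 = { i0, i2, i3, true }; faces.push_back(f3);
  Face f4 = { i1, i3, i2, true }; faces.push_back(f4);

  std::vector<int> visible;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    visible.clear();
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      if (orient(p[faces[f].a], p[faces[f].b], p[faces[f].c], p[i]) > 0)
        visible.push_back((int)f);
    }
    if (visible.empty()) continue;
    // horizon = directed edges of the visible region whose reverse edge is
    // not itself part of a visible face
    std::set<std::pair<int, int> > edges;
    for (size_t v = 0; v < visible.size(); ++v) {
      const Face& f = faces[visible[v]];
      edges.insert(std::make_pair(f.a, f.b));
      edges.insert(std::make_pair(f.b, f.c));
      edges.insert(std::make_pair(f.c, f.a));
    }
    for (size_t v = 0; v < visible.size(); ++v) faces[visible[v]].alive = false;
    for (std::set<std::pair<int, int> >::iterator e = edges.begin();
         e != edges.end(); ++e) {
      if (edges.count(std::make_pair(e->second, e->first))) continue;
      Face nf = { e->first, e->second, i, true };
      faces.push_back(nf);
    }
  }

  // collect distinct supporting half-spaces n.q <= off (normals reduced by
  // their gcd so coplanar triangles collapse to one plane)
  std::set<std::pair<std::pair<i64, i64>, std::pair<i64, i64> > > seen;
  std::vector<P3> nrm;
  std::vector<i64> off;
  for (size_t f = 0; f < faces.size(); ++f) {
    if (!faces[f].alive) continue;
    P3 nv = cross(sub(p[faces[f].b], p[faces[f].a]),
                  sub(p[faces[f].c], p[faces[f].a]));
    i64 ov = dot(nv, p[faces[f].a]);
    i64 g = gcd64(gcd64(nv.x, nv.y), gcd64(nv.z, ov));
    if (g > 1) { nv.x /= g; nv.y /= g; nv.z /= g; ov /= g; }
    std::pair<std::pair<i64, i64>, std::pair<i64, i64> > key =
      std::make_pair(std::make_pair(nv.x, nv.y), std::make_pair(nv.z, ov));
    if (seen.count(key)) continue;
    seen.insert(key);
    nrm.push_back(nv);
    off.push_back(ov);
  }
  const int nf = (int)nrm.size();

  // classify voxel centres (1-based coordinates) column by column: the
  // feasible first-index range per column is an interval by convexity
  const int d0 = dims[0], d1 = dims[1], d2 = dims[2];
  LogicalVector out((R_xlen_t)d0 * d1 * d2, FALSE);
  i64 xmin = p[0].x, xmax = p[0].x;
  for (int i = 1; i < n; ++i) {
    if (p[i].x < xmin) xmin = p[i].x;
    if (p[i].x > xmax) xmax = p[i].x;
  }
  for (int k2 = 1; k2 <= d2; ++k2) {
    for (int k1 = 1; k1 <= d1; ++k1) {
      i64 lo = xmin, hi = xmax;
      bool empty = false;
      for (int f = 0; f < nf && !empty; ++f) {
        i64 rhs = off[f] - nrm[f].y * (i64)k1 - nrm[f].z * (i64)k2;
        if (nrm[f].x > 0) {
          i64 b = floor_div(rhs, nrm[f].x);
          if (b < hi) hi = b;
        } else if (nrm[f].x < 0) {
          i64 b = ceil_div(-rhs, -nrm[f].x); // k0 >= rhs / n.x, n.x < 0
          if (b > lo) lo = b;
        } else if (rhs < 0) {
          empty = true;
        }
        if (lo > hi) empty = true;
      }
      if (empty) continue;
      if (lo < 1) lo = 1;
      if (hi > d0) hi = d0;
      R_xlen_t base = (R_xlen_t)d0 * ((k1 - 1) + (R_xlen_t)d1 * (k2 - 1));
      for (i64 k0 = lo; k0 <= hi; ++k0) out[base + (k0 - 1)] = TRUE;
    }
  }
  return out;
}
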