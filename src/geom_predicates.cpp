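// Geometric predicates for watertight surface meshes: parity ray casting
// for point containment (with deterministic direction re-jitter on
// degenerate hits), point-to-surface distance, and pairwise
// segment-triangle crossing tests for surface-surface intersection.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct V3 { double x, y, z; };
inline V3 operator-(V3 a, V3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline V3 operator+(V3 a, V3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
inline V3 operator*(double s, V3 a) { return {s * a.x, s * a.y, s * a.z}; }
inline double dot(V3 a, V3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline V3 cross(V3 a, V3 b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double norm(V3 a) { return std::sqrt(dot(a, a)); }
inline V3 row(const NumericMatrix& m, int i) {
  return {m(i, 0), m(i, 1), m(i, 2)};
}

// Moeller-Trumbore; returns 1 hit, 0 miss, -1 degenerate (grazing).
int ray_tri(V3 o, V3 d, V3 v0, V3 v1, V3 v2, double scale) {
  const double eps = 1e-12 * scale;
  V3 e1 = v1 - v0, e2 = v2 - v0;
  V3 p = cross(d, e2);
  double det = dot(e1, p);
  if (std::fabs(det) < 1e-14 * scale * scale) return -1;  // parallel/grazing
  double inv = 1.0 / det;
  V3 t = o - v0;
  double u = dot(t, p) * inv;
  if (u < -1e-10 || u > 1 + 1e-10) return 0;
  V3 q = cross(t, e1);
  double v = dot(d, q) * inv;
  if (v < -1e-10 || u + v > 1 + 1e-10) return 0;
  double tt = dot(e2, q) * inv;
  if (tt <= eps) return 0;  // behind or at origin
  // near an edge/vertex or near the origin plane: ambiguous, ask for re-jitter
  if (u < 1e-9 || v < 1e-9 || u + v > 1 - 1e-9) return -1;
  return 1;
}

// squared distance point to triangle (Ericson, Real-Time Collision Detection)
double pt_tri_d2(V3 p, V3 a, V3 b, V3 c) {
  V3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) return dot(p - a, p - a);
  V3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) return dot(p - b, p - b);
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    V3 q = a + v * ab;
    return dot(p - q, p - q);
  }
  V3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) return dot(p - c, p - c);
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    V3 q = a + w * ac;
    return dot(p - q, p - q);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    V3 q = b + w * (c - b);
    return dot(p - q, p - q);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  V3 q = a + v * ab + w * ac;
  return dot(p - q, p - q);
}

// segment pq vs triangle abc proper crossing
bool seg_tri(V3 p, V3 q, V3 a, V3 b, V3 c) {
  V3 d = q - p;
  V3 e1 = b - a, e2 = c - a;
  V3 h = cross(d, e2);
  double det = dot(e1, h);
  if (std::fabs(det) < 1e-14) return false;  // parallel (coplanar handled elsewhere)
  double inv = 1.0 / det;
  V3 s = p - a;
  double u = dot(s, h) * inv;
  if (u < 0 || u > 1) return false;
  V3 qv = cross(s, e1);
  double v = dot(d, qv) * inv;
  if (v < 0 || u + v > 1) return false;
  double t = dot(e2, qv) * inv;
  return t > 0 && t < 1;
}

}  // namespace

// Containment status per point: 1 inside, 0 outside, 2 on surface.
// [[Rcpp::export(name = ".pts_in_mesh")]]
IntegerVector pts_in_mesh(NumericMatrix pts, NumericMatrix nodes,
                          IntegerMatrix faces, double on_tol) {
  const int np = pts.nrow(), nf = faces.nrow();
  IntegerVector out(np);
  std::vector<V3> v(nodes.nrow());
  for (int i = 0; i < nodes.nrow(); ++i) v[i] = row(nodes, i);
  double scale = 0.0;
  for (int i = 0; i < nodes.nrow(); ++i)
    scale = std::max(scale, std::fabs(v[i].x) + std::fabs(v[i].y) + std::fabs(v[i].z));
  if (scale <= 0) scale = 1.0;
  const double tol2 = on_tol * on_tol;

  // deterministic direction sequence (simple LCG on a seed)
  unsigned long long state = 88172645463325252ULL;
  auto next_dir = [&]() -> V3 {
    auto rnd = [&]() {
      state ^= state << 13; state ^= state >> 7; state ^= state << 17;
      return (double)(state % 1000003) / 1000003.0 - 0.5;
    };
    V3 d = {rnd(), rnd(), rnd()};
    double n = norm(d);
    return (n > 1e-6) ? (1.0 / n) * d : V3{0.57735, 0.57735, 0.57735};
  };

  for (int i = 0; i < np; ++i) {
    V3 p = row(pts, i);
    bool onsurf = false;
    for (int f = 0; f < nf && !onsurf; ++f) {
      if (pt_tri_d2(p, v[faces(f, 0) - 1], v[faces(f, 1) - 1],
                    v[faces(f, 2) - 1]) < tol2)
        onsurf = true;
    }
    if (onsurf) { out[i] = 2; continue; }
    int attempts = 0;
    for (;;) {
      V3 d = next_dir();
      int hits = 0;
      bool degen = false;
      for (int f = 0; f < nf; ++f) {
        int r = ray_tri(p, d, v[faces(f, 0) - 1], v[faces(f, 1) - 1],
                        v[faces(f, 2) - 1], scale);
        if (r < 0) { degen = true; break; }
        hits += r;
      }
      if (!degen) { out[i] = hits % 2; break; }
      if (++attempts > 50) { out[i] = 0; break; }  // give up: call it outside
    }
  }
  return out;
}

// [[Rcpp::export(name = ".any_tri_intersect")]]
bool any_tri_intersect(NumericMatrix nodesA, IntegerMatrix facesA,
                       NumericMatrix nodesB, IntegerMatrix facesB) {
  const int na = facesA.nrow(), nb = facesB.nrow();
  std::vector<V3> va(nodesA.nrow()), vb(nodesB.nrow());
  for (int i = 0; i < nodesA.nrow(); ++i) va[i] = row(nodesA, i);
  for (int i = 0; i < nodesB.nrow(); ++i) vb[i] = row(nodesB, i);
  // per-face bounding boxes for cheap rejection
  std::vector<double> loA(3 * na), hiA(3 * na), loB(3 * nb), hiB(3 * nb);
  auto boxify = [](const std::vector<V3>& v, const IntegerMatrix& f, int k,
                   std::vector<double>& lo, std::vector<double>& hi) {
    V3 p0 = v[f(k, 0) - 1], p1 = v[f(k, 1) - 1], p2 = v[f(k, 2) - 1];
    lo[3 * k + 0] = std::min(p0.x, std::min(p1.x, p2.x));
    lo[3 * k + 1] = std::min(p0.y, std::min(p1.y, p2.y));
    lo[3 * k + 2] = std::min(p0.z, std::min(p1.z, p2.z));
    hi[3 * k + 0] = std::max(p0.x, std::max(p1.x, p2.x));
    hi[3 * k + 1] = std::max(p0.y, std::max(p1.y, p2.y));
    hi[3 * k + 2] = std::max(p0.z, std::max(p1.z, p2.z));
  };
  for (int k = 0; k < na; ++k) boxify(va, facesA, k, loA, hiA);
  for (int k = 0; k < nb; ++k) boxify(vb, facesB, k, loB, hiB);

  for (int i = 0; i < na; ++i) {
    V3 a0 = va[facesA(i, 0) - 1], a1 = va[facesA(i, 1) - 1], a2 = va[facesA(i, 2) - 1];
    for (int j = 0; j < nb; ++j) {
      bool sep = false;
      for (int k = 0; k < 3; ++k)
        if (loA[3 * i + k] > hiB[3 * j + k] || loB[3 * j + k] > hiA[3 * i + k])
          sep = true;
      if (sep) continue;
      V3 b0 = vb[facesB(j, 0) - 1], b1 = vb[facesB(j, 1) - 1], b2 = vb[facesB(j, 2) - 1];
      if (seg_tri(a0, a1, b0, b1, b2) || seg_tri(a1, a2, b0, b1, b2) ||
          seg_tri(a2, a0, b0, b1, b2) || seg_tri(b0, b1, a0, a1, a2) ||
          seg_tri(b1, b2, a0, a1, a2) || seg_tri(b2, b0, a0, a1, a2))
        return true;
    }
  }
  return false;
}

// [[Rcpp::export(name = ".pts_surface_dist")]]
NumericVector pts_surface_dist(NumericMatrix pts, NumericMatrix nodes,
                               IntegerMatrix faces) {
  const int np = pts.nrow(), nf = faces.nrow();
  NumericVector out(np);
  std::vector<V3> v(nodes.nrow());
  for (int i = 0; i < nodes.nrow(); ++i) v[i] = row(nodes, i);
  for (int i = 0; i < np; ++i) {
    V3 p = row(pts, i);
    double best = R_PosInf;
    for (int f = 0; f < nf; ++f)
      best = std::min(best, pt_tri_d2(p, v[faces(f, 0) - 1],
                                      v[faces(f, 1) - 1], v[faces(f, 2) - 1]));
    out[i] = std::sqrt(best);
  }
  return out;
}
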