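// Boundary-element kernels for the epicardial-to-torso transfer problem.
//
// Double layer: analytic integration of linear (vertex) shape functions
// against the solid-angle kernel over flat triangles.  With ytilde = y - x
// and n the (outward) unit normal of the triangle, (ytilde . n) = h is
// constant over the triangle, so
//   int_T N_k (ytilde.n)/r^3 dS = a_k * Omega + h * (g_k . J1),
// where Omega is the van Oosterom & Strackee signed solid angle,
// J1 = n*Omega - sum_e m_e * L_e with L_e the analytic edge integral of 1/r,
// g_k the in-plane shape-function gradient and a_k its affine offset.
// Triangles incident to the collocation vertex contribute exactly zero
// (h = 0 for a flat triangle through x) and are skipped.
//
// Single layer: Duffy-transformed tensor Gauss quadrature when the
// collocation point is a vertex of the triangle (the 1/r singularity is
// removed exactly by the u-Jacobian), distance-adaptive subdivided 7-point
// symmetric rules otherwise.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct V3 {
  double x, y, z;
};
inline V3 v3(double x, double y, double z) { return {x, y, z}; }
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

const double PI4 = 4.0 * M_PI;

// 7-point degree-5 symmetric rule on the unit triangle (barycentric).
const double QW[7] = {0.225,
                      0.132394152788506, 0.132394152788506, 0.132394152788506,
                      0.125939180544827, 0.125939180544827, 0.125939180544827};
const double QB[7][3] = {
    {1.0 / 3, 1.0 / 3, 1.0 / 3},
    {0.059715871789770, 0.470142064105115, 0.470142064105115},
    {0.470142064105115, 0.059715871789770, 0.470142064105115},
    {0.470142064105115, 0.470142064105115, 0.059715871789770},
    {0.797426985353087, 0.101286507323456, 0.101286507323456},
    {0.101286507323456, 0.797426985353087, 0.101286507323456},
    {0.101286507323456, 0.101286507323456, 0.797426985353087}};

// 8-point Gauss-Legendre on [0, 1].
const double GX[8] = {0.019855071751232, 0.101666761293187, 0.237233795041836,
                      0.408282678752175, 0.591717321247825, 0.762766204958164,
                      0.898333238706813, 0.980144928248768};
const double GW[8] = {0.050614268145188, 0.111190517226687, 0.156853322938944,
                      0.181341891689181, 0.181341891689181, 0.156853322938944,
                      0.111190517226687, 0.050614268145188};

// Accumulate single-layer integrals of the three parent barycentric shape
// functions over a (sub)triangle, recursing while the collocation point is
// close relative to the subtriangle size.
void sl_recurse(V3 x, const V3 v[3], const double bc[3][3], int depth,
                double acc[3]) {
  V3 c[3];
  for (int j = 0; j < 3; ++j)
    c[j] = bc[j][0] * v[0] + bc[j][1] * v[1] + bc[j][2] * v[2];
  V3 cen = (1.0 / 3.0) * (c[0] + c[1] + c[2]);
  double size = std::max(norm(c[1] - c[0]),
                         std::max(norm(c[2] - c[1]), norm(c[0] - c[2])));
  double d = norm(cen - x);
  if (depth < 2 && d < 2.0 * size) {
    double m01[3], m12[3], m02[3];
    for (int k = 0; k < 3; ++k) {
      m01[k] = 0.5 * (bc[0][k] + bc[1][k]);
      m12[k] = 0.5 * (bc[1][k] + bc[2][k]);
      m02[k] = 0.5 * (bc[0][k] + bc[2][k]);
    }
    double sub[4][3][3];
    for (int k = 0; k < 3; ++k) {
      sub[0][0][k] = bc[0][k]; sub[0][1][k] = m01[k]; sub[0][2][k] = m02[k];
      sub[1][0][k] = bc[1][k]; sub[1][1][k] = m12[k]; sub[1][2][k] = m01[k];
      sub[2][0][k] = bc[2][k]; sub[2][1][k] = m02[k]; sub[2][2][k] = m12[k];
      sub[3][0][k] = m01[k];   sub[3][1][k] = m12[k]; sub[3][2][k] = m02[k];
    }
    for (int s = 0; s < 4; ++s) sl_recurse(x, v, sub[s], depth + 1, acc);
    return;
  }
  double area2 = norm(cross(c[1] - c[0], c[2] - c[0]));
  for (int q = 0; q < 7; ++q) {
    V3 y = QB[q][0] * c[0] + QB[q][1] * c[1] + QB[q][2] * c[2];
    double r = norm(y - x);
    for (int k = 0; k < 3; ++k) {
      double lam = QB[q][0] * bc[0][k] + QB[q][1] * bc[1][k] + QB[q][2] * bc[2][k];
      acc[k] += QW[q] * 0.5 * area2 * lam / r;
    }
  }
}

}  // namespace

// [[Rcpp::export(name = ".bem_dl_matrix")]]
NumericMatrix bem_dl_matrix(NumericMatrix coll, NumericMatrix nodes,
                            IntegerMatrix faces) {
  const int nc = coll.nrow(), nv = nodes.nrow(), nf = faces.nrow();
  NumericMatrix out(nc, nv);
  std::vector<V3> vert(nv);
  for (int i = 0; i < nv; ++i) vert[i] = row(nodes, i);

  for (int i = 0; i < nc; ++i) {
    V3 x = row(coll, i);
    for (int f = 0; f < nf; ++f) {
      const int i1 = faces(f, 0) - 1, i2 = faces(f, 1) - 1, i3 = faces(f, 2) - 1;
      V3 y1 = vert[i1] - x, y2 = vert[i2] - x, y3 = vert[i3] - x;
      double l1 = norm(y1), l2 = norm(y2), l3 = norm(y3);
      if (l1 < 1e-10 || l2 < 1e-10 || l3 < 1e-10) continue;  // incident: 0
      double num = dot(y1, cross(y2, y3));
      double den = l1 * l2 * l3 + dot(y1, y2) * l3 + dot(y1, y3) * l2 +
                   dot(y2, y3) * l1;
      double omega = 2.0 * std::atan2(num, den);
      V3 nvec = cross(y2 - y1, y3 - y1);
      double a2 = norm(nvec);
      if (a2 < 1e-14) continue;  // degenerate triangle
      V3 n = (1.0 / a2) * nvec;
      double h = dot(y1, n);
      // J1 = n*Omega - sum_e m_e * L_e
      V3 J1 = omega * n;
      const V3 vs[3] = {y1, y2, y3};
      for (int e = 0; e < 3; ++e) {
        V3 a = vs[e], b = vs[(e + 1) % 3];
        V3 d = b - a;
        double L = norm(d);
        V3 u = (1.0 / L) * d;
        double ua = dot(u, a);
        double la = norm(a), lb = norm(b);
        double dn = ua + la;
        double Le = (dn > 1e-14) ? std::log((L + ua + lb) / dn) : 0.0;
        V3 m = cross(u, n);  // in-plane outward edge normal
        J1 = J1 - Le * m;
      }
      V3 cen = (1.0 / 3.0) * (y1 + y2 + y3);
      const V3 opp[3] = {y3 - y2, y1 - y3, y2 - y1};
      const int ids[3] = {i1, i2, i3};
      for (int j = 0; j < 3; ++j) {
        V3 g = (1.0 / a2) * cross(n, opp[j]);
        double ak = 1.0 / 3.0 - dot(g, cen);
        double Ik = ak * omega + h * dot(g, J1);
        out(i, ids[j]) -= Ik / PI4;  // dG/dn_y dS = -(ytilde.n)/(4 pi r^3) dS
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".bem_sl_matrix")]]
NumericMatrix bem_sl_matrix(NumericMatrix coll, NumericMatrix nodes,
                            IntegerMatrix faces) {
  const int nc = coll.nrow(), nv = nodes.nrow(), nf = faces.nrow();
  NumericMatrix out(nc, nv);
  std::vector<V3> vert(nv);
  for (int i = 0; i < nv; ++i) vert[i] = row(nodes, i);

  for (int i = 0; i < nc; ++i) {
    V3 x = row(coll, i);
    for (int f = 0; f < nf; ++f) {
      const int ids[3] = {faces(f, 0) - 1, faces(f, 1) - 1, faces(f, 2) - 1};
      V3 v[3] = {vert[ids[0]], vert[ids[1]], vert[ids[2]]};
      int sing = -1;
      for (int j = 0; j < 3; ++j)
        if (norm(v[j] - x) < 1e-10) sing = j;
      double acc[3] = {0, 0, 0};
      if (sing >= 0) {
        // Duffy transform about the singular vertex: y = p1 + u[(p2-p1)+v(p3-p2)],
        // Jacobian 2A*u cancels 1/r exactly.
        const int o0 = sing, o1 = (sing + 1) % 3, o2 = (sing + 2) % 3;
        V3 p1 = v[o0], p2 = v[o1], p3 = v[o2];
        double area2 = norm(cross(p2 - p1, p3 - p1));
        double a3[3] = {0, 0, 0};
        for (int iu = 0; iu < 8; ++iu) {
          for (int iv = 0; iv < 8; ++iv) {
            double u = GX[iu], vv = GX[iv], w = GW[iu] * GW[iv];
            V3 dir = (p2 - p1) + vv * (p3 - p2);
            double rd = norm(dir);  // r = u * rd
            double lam[3] = {1.0 - u, u * (1.0 - vv), u * vv};
            for (int k = 0; k < 3; ++k)
              a3[k] += w * area2 * lam[k] / rd;
          }
        }
        acc[o0] = a3[0]; acc[o1] = a3[1]; acc[o2] = a3[2];
      } else {
        double bc0[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
        sl_recurse(x, v, bc0, 0, acc);
      }
      for (int j = 0; j < 3; ++j) out(i, ids[j]) += acc[j] / PI4;
    }
  }
  return out;
}
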