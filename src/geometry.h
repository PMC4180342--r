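#ifndef SWITCHFOLD_GEOMETRY_H
#define SWITCHFOLD_GEOMETRY_H

#include <cmath>

// Minimal 3-vector helpers on raw double[3] storage. Chains are stored as
// flat arrays x[3*i + d]; all moves are rigid rotations of a downstream
// segment, so bond lengths are preserved exactly.

namespace sfgeom {

inline void vsub(const double *a, const double *b, double *out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}

inline double vdot(const double *a, const double *b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

inline void vcross(const double *a, const double *b, double *out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

inline double vnorm(const double *a) { return std::sqrt(vdot(a, a)); }

inline double dist3(const double *a, const double *b) {
  double d0 = a[0] - b[0], d1 = a[1] - b[1], d2 = a[2] - b[2];
  return std::sqrt(d0 * d0 + d1 * d1 + d2 * d2);
}

// Bond angle at vertex b of a-b-c, in (0, pi).
inline double bond_angle(const double *a, const double *b, const double *c) {
  double u[3], v[3];
  vsub(a, b, u); vsub(c, b, v);
  double cs = vdot(u, v) / (vnorm(u) * vnorm(v));
  if (cs > 1.0) cs = 1.0;
  if (cs < -1.0) cs = -1.0;
  return std::acos(cs);
}

// Signed dihedral of a-b-c-d in (-pi, pi].
inline double dihedral(const double *a, const double *b, const double *c,
                       const double *d) {
  double b1[3], b2[3], b3[3], n1[3], n2[3], m[3];
  vsub(b, a, b1); vsub(c, b, b2); vsub(d, c, b3);
  vcross(b1, b2, n1);
  vcross(b2, b3, n2);
  double nb2 = vnorm(b2);
  m[0] = n1[1] * b3[2] - n1[2] * b3[1];
  m[1] = n1[2] * b3[0] - n1[0] * b3[2];
  m[2] = n1[0] * b3[1] - n1[1] * b3[0];
  (void)m;
  double x = vdot(n1, n2);
  double y = nb2 * (b1[0] * n2[0] + b1[1] * n2[1] + b1[2] * n2[2]);
  return std::atan2(y, x);
}

// Rodrigues rotation of point p about the axis through 'origin' with unit
// direction u, by angle a; result written in place.
inline void rotate_about(double *p, const double *origin, const double *u,
                         double ca, double sa) {
  double v[3];
  vsub(p, origin, v);
  double du = vdot(u, v);
  double cr[3];
  vcross(u, v, cr);
  for (int d = 0; d < 3; ++d) {
    p[d] = origin[d] + v[d] * ca + cr[d] * sa + u[d] * du * (1.0 - ca);
  }
}

// h-vector at residue i (0-based): sum of the two bond vectors pointing
// from i to its neighbours. Defined only for interior residues.
inline void hvec(const double *x, int i, double *out) {
  const double *p = x + 3 * i;
  const double *pm = x + 3 * (i - 1);
  const double *pp = x + 3 * (i + 1);
  out[0] = (pm[0] - p[0]) + (pp[0] - p[0]);
  out[1] = (pm[1] - p[1]) + (pp[1] - p[1]);
  out[2] = (pm[2] - p[2]) + (pp[2] - p[2]);
}

}  // namespace sfgeom

#endif
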