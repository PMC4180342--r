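// Orientation-dependent C-alpha Go model: energy function and Metropolis
// folding simulations.
//
// E = sum K_theta (theta - theta0)^2
//   + sum [K_phi1 (1 - cos(phi - phi0)) + K_phi3 (1 - cos 3(phi - phi0))]
//   + sum_native eps * C_ij * B_ij * u(r/r0)        (12-10 well, min -1)
//   + sum_non-native rep_eps * (rep_sigma / r)^12   (|i-j| >= 3 only)
//
// B_ij compares the current angle between the residues' h-vectors with
// its native value: 1 at the native orientation, raised-cosine decay to 0
// at deviation a_theta. Terminal residues have no h-vector; B = 1 there.

#include <Rcpp.h>
#include "geometry.h"

using namespace Rcpp;
using namespace sfgeom;

struct GoPar {
  double K_theta, K_phi1, K_phi3, eps, a_theta, rep_sigma, rep_eps;
  double rep_cut2;  // squared cutoff beyond which repulsion is negligible
};

static double bfactor(const std::vector<double> &x, int N, int i, int j,
                      double Theta0, double a_theta) {
  if (i == 0 || i == N - 1 || j == 0 || j == N - 1) return 1.0;
  double hi[3], hj[3];
  hvec(x.data(), i, hi);
  hvec(x.data(), j, hj);
  double ni = vnorm(hi), nj = vnorm(hj);
  if (ni < 1e-10 || nj < 1e-10) return 1.0;  // degenerate h-vector
  double cs = vdot(hi, hj) / (ni * nj);
  if (cs > 1.0) cs = 1.0;
  if (cs < -1.0) cs = -1.0;
  double dv = std::fabs(std::acos(cs) - Theta0);
  if (dv >= a_theta) return 0.0;
  return 0.5 * (1.0 + std::cos(M_PI * dv / a_theta));
}

static double local_energy(const std::vector<double> &x, int N,
                           const NumericVector &theta0,
                           const NumericVector &phi0, const GoPar &p) {
  double E = 0.0;
  for (int i = 1; i <= N - 2; ++i) {
    double th = bond_angle(&x[3 * (i - 1)], &x[3 * i], &x[3 * (i + 1)]);
    double d = th - theta0[i];
    E += p.K_theta * d * d;
    if (i <= N - 3) {
      double ph = dihedral(&x[3 * (i - 1)], &x[3 * i], &x[3 * (i + 1)],
                           &x[3 * (i + 2)]);
      double dp = ph - phi0[i];
      E += p.K_phi1 * (1.0 - std::cos(dp)) +
           p.K_phi3 * (1.0 - std::cos(3.0 * dp));
    }
  }
  return E;
}

static double contact_energy(const std::vector<double> &x, int N,
                             const IntegerVector &ci, const IntegerVector &cj,
                             const NumericVector &r0, const NumericVector &Cij,
                             const NumericVector &Theta0, const GoPar &p) {
  double E = 0.0;
  for (int c = 0; c < ci.size(); ++c) {
    int i = ci[c], j = cj[c];
    double r = dist3(&x[3 * i], &x[3 * j]);
    double q = r0[c] / r;
    double q2 = q * q;
    double q10 = q2 * q2 * q2 * q2 * q2;
    double u = 5.0 * q10 * q2 - 6.0 * q10;
    E += p.eps * Cij[c] * bfactor(x, N, i, j, Theta0[c], p.a_theta) * u;
  }
  return E;
}

static inline double rep_pair(double r2, const GoPar &p) {
  if (r2 >= p.rep_cut2) return 0.0;
  double s2 = p.rep_sigma * p.rep_sigma / r2;
  double s6 = s2 * s2 * s2;
  return p.rep_eps * s6 * s6;
}

static double rep_energy(const std::vector<double> &x, int N,
                         const std::vector<char> &is_native, const GoPar &p) {
  double E = 0.0;
  for (int i = 0; i < N - 3; ++i) {
    for (int j = i + 3; j < N; ++j) {
      if (is_native[i * N + j]) continue;
      double d0 = x[3 * i] - x[3 * j], d1 = x[3 * i + 1] - x[3 * j + 1],
             d2 = x[3 * i + 2] - x[3 * j + 2];
      E += rep_pair(d0 * d0 + d1 * d1 + d2 * d2, p);
    }
  }
  return E;
}

static GoPar make_par(double K_theta, double K_phi1, double K_phi3,
                      double eps, double a_theta, double rep_sigma,
                      double rep_eps) {
  GoPar p;
  p.K_theta = K_theta; p.K_phi1 = K_phi1; p.K_phi3 = K_phi3;
  p.eps = eps; p.a_theta = a_theta;
  p.rep_sigma = rep_sigma; p.rep_eps = rep_eps;
  p.rep_cut2 = 9.0 * rep_sigma * rep_sigma;
  return p;
}

static std::vector<char> native_mask(int N, const IntegerVector &ci,
                                     const IntegerVector &cj) {
  std::vector<char> m(N * N, 0);
  for (int c = 0; c < ci.size(); ++c) {
    m[ci[c] * N + cj[c]] = 1;
    m[cj[c] * N + ci[c]] = 1;
  }
  return m;
}

static std::vector<double> flatten(const NumericMatrix &xyz) {
  int N = xyz.nrow();
  std::vector<double> x(3 * N);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = xyz(i, d);
  return x;
}

// [[Rcpp::export]]
double go_energy_cpp(NumericMatrix xyz, IntegerVector ci, IntegerVector cj,
                     NumericVector r0, NumericVector Cij, NumericVector Theta0,
                     NumericVector theta0, NumericVector phi0, double K_theta,
                     double K_phi1, double K_phi3, double eps, double a_theta,
                     double rep_sigma, double rep_eps) {
  int N = xyz.nrow();
  std::vector<double> x = flatten(xyz);
  GoPar p = make_par(K_theta, K_phi1, K_phi3, eps, a_theta, rep_sigma, rep_eps);
  std::vector<char> m = native_mask(N, ci, cj);
  return local_energy(x, N, theta0, phi0, p) +
         contact_energy(x, N, ci, cj, r0, Cij, Theta0, p) +
         rep_energy(x, N, m, p);
}

// [[Rcpp::export]]
double bfactor_cpp(NumericMatrix xyz, int i, int j, double Theta0,
                   double a_theta) {
  std::vector<double> x = flatten(xyz);
  return bfactor(x, xyz.nrow(), i - 1, j - 1, Theta0, a_theta);
}

// [[Rcpp::export]]
List go_mc_cpp(NumericMatrix xyz, IntegerVector ci, IntegerVector cj,
               NumericVector r0, NumericVector Cij, NumericVector Theta0,
               NumericVector theta0, NumericVector phi0, double K_theta,
               double K_phi1, double K_phi3, double eps, double a_theta,
               double rep_sigma, double rep_eps, double temperature,
               double gamma, int n_sweeps, int stride, double q_ratio) {
  const int N = xyz.nrow();
  const int nc = ci.size();
  const double PI = M_PI;
  GoPar p = make_par(K_theta, K_phi1, K_phi3, eps, a_theta, rep_sigma, rep_eps);
  std::vector<char> m = native_mask(N, ci, cj);
  std::vector<double> x = flatten(xyz), xnew(3 * N);

  double E = local_energy(x, N, theta0, phi0, p) +
             contact_energy(x, N, ci, cj, r0, Cij, Theta0, p) +
             rep_energy(x, N, m, p);
  double lc_cur = local_energy(x, N, theta0, phi0, p) +
                  contact_energy(x, N, ci, cj, r0, Cij, Theta0, p);

  long n_prop = 0, n_acc = 0;
  int n_samp = n_sweeps / stride;
  NumericVector sm_sweep(n_samp), sm_E(n_samp), sm_Q(n_samp);
  LogicalMatrix flags(n_samp, nc);
  int isamp = 0;

  // Proposal: pivot rotation of the downstream tail; repulsion delta is
  // restricted to pairs spanning the pivot (the move is rigid on the
  // tail), while local and contact terms are recomputed in full.
  auto attempt = [&](int s0, const double *origin, const double *u,
                     double alpha) {
    double ca = std::cos(alpha), sa = std::sin(alpha);
    std::copy(x.begin(), x.end(), xnew.begin());
    for (int j = s0; j < N; ++j) rotate_about(&xnew[3 * j], origin, u, ca, sa);
    double d_rep = 0.0;
    for (int a = 0; a < s0; ++a) {
      for (int b = s0; b < N; ++b) {
        if (b - a < 3 || m[a * N + b]) continue;
        double o0 = x[3 * a] - x[3 * b], o1 = x[3 * a + 1] - x[3 * b + 1],
               o2 = x[3 * a + 2] - x[3 * b + 2];
        double n0 = x[3 * a] - xnew[3 * b], n1 = x[3 * a + 1] - xnew[3 * b + 1],
               n2 = x[3 * a + 2] - xnew[3 * b + 2];
        d_rep += rep_pair(n0 * n0 + n1 * n1 + n2 * n2, p) -
                 rep_pair(o0 * o0 + o1 * o1 + o2 * o2, p);
      }
    }
    double lc_new = local_energy(xnew, N, theta0, phi0, p) +
                    contact_energy(xnew, N, ci, cj, r0, Cij, Theta0, p);
    double dE = (lc_new - lc_cur) + d_rep;
    ++n_prop;
    if (dE <= 0.0 || unif_rand() < std::exp(-dE / temperature)) {
      x.swap(xnew);
      lc_cur = lc_new;
      E += dE;
      ++n_acc;
    }
  };

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int i = 1; i <= N - 2; ++i) {
      double b1[3], b2[3], u[3];
      vsub(&x[3 * (i - 1)], &x[3 * i], b1);
      vsub(&x[3 * (i + 1)], &x[3 * i], b2);
      double th = bond_angle(&x[3 * (i - 1)], &x[3 * i], &x[3 * (i + 1)]);
      double th_new = th + (2.0 * unif_rand() - 1.0) * gamma * PI;
      if (th_new < 0.0) th_new = -th_new;
      if (th_new > PI) th_new = 2.0 * PI - th_new;
      vcross(b1, b2, u);
      double nu = vnorm(u);
      if (nu < 1e-10) {
        double ref[3] = {1.0, 0.0, 0.0};
        if (std::fabs(b2[0]) > 0.9 * vnorm(b2)) { ref[0] = 0.0; ref[1] = 1.0; }
        vcross(b2, ref, u);
        nu = vnorm(u);
      }
      u[0] /= nu; u[1] /= nu; u[2] /= nu;
      double origin[3] = {x[3 * i], x[3 * i + 1], x[3 * i + 2]};
      attempt(i + 1, origin, u, th_new - th);

      if (i <= N - 3) {
        double ax[3];
        vsub(&x[3 * (i + 1)], &x[3 * i], ax);
        double na = vnorm(ax);
        ax[0] /= na; ax[1] /= na; ax[2] /= na;
        double origin2[3] = {x[3 * i], x[3 * i + 1], x[3 * i + 2]};
        attempt(i + 2, origin2, ax, (2.0 * unif_rand() - 1.0) * gamma * PI);
      }
    }

    if ((sweep + 1) % stride == 0 && isamp < n_samp) {
      int formed = 0;
      for (int c = 0; c < nc; ++c) {
        double r = dist3(&x[3 * ci[c]], &x[3 * cj[c]]);
        bool f = r < q_ratio * r0[c];
        flags(isamp, c) = f;
        if (f) ++formed;
      }
      sm_sweep[isamp] = sweep + 1;
      sm_E[isamp] = E;
      sm_Q[isamp] = nc > 0 ? (double)formed / nc : NA_REAL;
      ++isamp;
    }
  }

  NumericMatrix out_xyz(N, 3);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) out_xyz(i, d) = x[3 * i + d];
  double E_full = local_energy(x, N, theta0, phi0, p) +
                  contact_energy(x, N, ci, cj, r0, Cij, Theta0, p) +
                  rep_energy(x, N, m, p);

  return List::create(
      _["xyz"] = out_xyz,
      _["acceptance"] = n_prop > 0 ? (double)n_acc / (double)n_prop : NA_REAL,
      _["sweep"] = sm_sweep, _["E"] = sm_E, _["Q"] = sm_Q,
      _["flags"] = flags, _["energy"] = E, _["energy_full"] = E_full);
}
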