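// Metropolis Monte Carlo sampler of random C-alpha chains under the
// average-distance (Gaussian-well) potential with a hard core.
//
// Moves are internal-coordinate pivots: at each residue the bond angle
// theta and then the dihedral phi are perturbed, each followed by its own
// Metropolis judgment. A pivot rotates the downstream segment rigidly, so
// only pairs spanning the pivot change distance; the energy delta is
// accumulated over exactly those pairs.

#include <Rcpp.h>
#include "geometry.h"

using namespace Rcpp;
using namespace sfgeom;

static inline double pair_e(double r, double rbar, double sigma,
                            double r_cut, double eps_hc, double kT) {
  if (r < r_cut) return eps_hc;
  double d = r - rbar;
  return kT * d * d / (2.0 * sigma * sigma);
}

static double total_energy(const std::vector<double> &x, int N,
                           const NumericMatrix &rbar,
                           const NumericMatrix &sigma,
                           double r_cut, double eps_hc, double kT) {
  double E = 0.0;
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double r = dist3(&x[3 * i], &x[3 * j]);
      E += pair_e(r, rbar(i, j), sigma(i, j), r_cut, eps_hc, kT);
    }
  }
  return E;
}

// [[Rcpp::export]]
double coil_energy_cpp(NumericMatrix xyz, NumericMatrix rbar,
                       NumericMatrix sigma, double r_cut, double eps_hc,
                       double kT) {
  int N = xyz.nrow();
  std::vector<double> x(3 * N);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = xyz(i, d);
  return total_energy(x, N, rbar, sigma, r_cut, eps_hc, kT);
}

// One pivot proposal: rotate residues s0..N-1 about (origin, axis u) by
// angle alpha into xnew (only the moved tail is filled), return dE over
// pairs spanning the pivot.
static double propose_pivot(const std::vector<double> &x,
                            std::vector<double> &xnew, int N, int s0,
                            const double *origin, const double *u,
                            double alpha, const NumericMatrix &rbar,
                            const NumericMatrix &sigma, double r_cut,
                            double eps_hc, double kT) {
  double ca = std::cos(alpha), sa = std::sin(alpha);
  for (int j = s0; j < N; ++j) {
    xnew[3 * j] = x[3 * j];
    xnew[3 * j + 1] = x[3 * j + 1];
    xnew[3 * j + 2] = x[3 * j + 2];
    rotate_about(&xnew[3 * j], origin, u, ca, sa);
  }
  double dE = 0.0;
  for (int a = 0; a < s0; ++a) {
    for (int b = s0; b < N; ++b) {
      double r_old = dist3(&x[3 * a], &x[3 * b]);
      double r_new = dist3(&x[3 * a], &xnew[3 * b]);
      dE += pair_e(r_new, rbar(a, b), sigma(a, b), r_cut, eps_hc, kT) -
            pair_e(r_old, rbar(a, b), sigma(a, b), r_cut, eps_hc, kT);
    }
  }
  return dE;
}

static void unit_normal_axis(const double *b1, const double *b2, double *u) {
  vcross(b1, b2, u);
  double n = vnorm(u);
  if (n < 1e-10) {
    // collinear bonds: any direction perpendicular to b2
    double ref[3] = {1.0, 0.0, 0.0};
    if (std::fabs(b2[0]) > 0.9 * vnorm(b2)) {
      ref[0] = 0.0; ref[1] = 1.0;
    }
    vcross(b2, ref, u);
    n = vnorm(u);
  }
  u[0] /= n; u[1] /= n; u[2] /= n;
}

// [[Rcpp::export]]
List coil_mc_cpp(NumericMatrix xyz, NumericMatrix rbar, NumericMatrix sigma,
                 double r_cut, double eps_hc, double kT, double gamma,
                 int n_sweeps, int burn_in, double contact_cut, int pad,
                 bool record_contacts, bool record_angles) {
  const int N = xyz.nrow();
  const double PI = M_PI;
  std::vector<double> x(3 * N), xnew(3 * N);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = xyz(i, d);

  double E = total_energy(x, N, rbar, sigma, r_cut, eps_hc, kT);
  long n_prop = 0, n_acc = 0;

  const int n_core = N - 2 * pad;
  IntegerMatrix counts(record_contacts ? n_core : 1,
                       record_contacts ? n_core : 1);
  int n_samples = 0;

  NumericMatrix theta_trace(record_angles ? n_sweeps : 1,
                            record_angles ? N : 1);
  NumericMatrix phi_trace(record_angles ? n_sweeps : 1,
                          record_angles ? N : 1);
  if (record_angles) {
    std::fill(theta_trace.begin(), theta_trace.end(), NA_REAL);
    std::fill(phi_trace.begin(), phi_trace.end(), NA_REAL);
  }

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int i = 1; i <= N - 2; ++i) {
      // ---- bond-angle move at residue i, pivots i+1..N-1 ----
      double b1[3], b2[3], u[3];
      vsub(&x[3 * (i - 1)], &x[3 * i], b1);
      vsub(&x[3 * (i + 1)], &x[3 * i], b2);
      double th = bond_angle(&x[3 * (i - 1)], &x[3 * i], &x[3 * (i + 1)]);
      double th_new = th + (2.0 * unif_rand() - 1.0) * gamma * PI;
      if (th_new < 0.0) th_new = -th_new;            // reflect at 0
      if (th_new > PI) th_new = 2.0 * PI - th_new;   // reflect at pi
      unit_normal_axis(b1, b2, u);
      double dE = propose_pivot(x, xnew, N, i + 1, &x[3 * i], u,
                                th_new - th, rbar, sigma, r_cut, eps_hc, kT);
      ++n_prop;
      if (dE <= 0.0 || unif_rand() < std::exp(-dE / kT)) {
        for (int j = i + 1; j < N; ++j)
          for (int d = 0; d < 3; ++d) x[3 * j + d] = xnew[3 * j + d];
        E += dE;
        ++n_acc;
      }
      // ---- dihedral move about bond (i, i+1), pivots i+2..N-1 ----
      if (i <= N - 3) {
        double ax[3];
        vsub(&x[3 * (i + 1)], &x[3 * i], ax);
        double nax = vnorm(ax);
        ax[0] /= nax; ax[1] /= nax; ax[2] /= nax;
        double dphi = (2.0 * unif_rand() - 1.0) * gamma * PI;
        double dE2 = propose_pivot(x, xnew, N, i + 2, &x[3 * i], ax, dphi,
                                   rbar, sigma, r_cut, eps_hc, kT);
        ++n_prop;
        if (dE2 <= 0.0 || unif_rand() < std::exp(-dE2 / kT)) {
          for (int j = i + 2; j < N; ++j)
            for (int d = 0; d < 3; ++d) x[3 * j + d] = xnew[3 * j + d];
          E += dE2;
          ++n_acc;
        }
      }
    }

    if (record_contacts && sweep >= burn_in) {
      double c2 = contact_cut * contact_cut;
      for (int i = pad; i < N - pad - 1; ++i) {
        for (int j = i + 1; j < N - pad; ++j) {
          double d0 = x[3 * i] - x[3 * j];
          double d1 = x[3 * i + 1] - x[3 * j + 1];
          double d2 = x[3 * i + 2] - x[3 * j + 2];
          if (d0 * d0 + d1 * d1 + d2 * d2 <= c2) {
            counts(i - pad, j - pad) += 1;
            counts(j - pad, i - pad) += 1;
          }
        }
      }
      ++n_samples;
    }

    if (record_angles) {
      for (int i = 1; i <= N - 2; ++i) {
        theta_trace(sweep, i) =
            bond_angle(&x[3 * (i - 1)], &x[3 * i], &x[3 * (i + 1)]);
        if (i <= N - 3) {
          phi_trace(sweep, i) = dihedral(&x[3 * (i - 1)], &x[3 * i],
                                         &x[3 * (i + 1)], &x[3 * (i + 2)]);
        }
      }
    }
  }

  NumericMatrix out_xyz(N, 3);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) out_xyz(i, d) = x[3 * i + d];

  return List::create(
      _["xyz"] = out_xyz,
      _["acceptance"] = n_prop > 0 ? (double)n_acc / (double)n_prop : NA_REAL,
      _["counts"] = counts, _["n_samples"] = n_samples,
      _["energy"] = E,
      _["energy_full"] = total_energy(x, N, rbar, sigma, r_cut, eps_hc, kT),
      _["theta_trace"] = theta_trace, _["phi_trace"] = phi_trace);
}
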