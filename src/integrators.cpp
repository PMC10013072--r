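#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>

using namespace Rcpp;
typedef std::complex<double> cplx;

// Fixed-step RK4 integrators for the microscopic rotator system and the
// Ott-Antonsen field, shared by the layer, reduced and full-system runs.
// Both support freezing the resource variable r (layer problem) and the
// resource activity lambda (clamp perturbation protocol).

struct NetDeriv {
  std::vector<double> dphi;
  std::vector<double> cbuf, sbuf;  // scratch: cos/sin of the phases
  double dr1, dr2, dlam, A;
};

static void net_rhs(const std::vector<double>& phi,
                    const std::vector<double>& nu,
                    double r1, double r2, double lam,
                    double sigma, double eps, double eps_prime,
                    double s1, double s2, double omega,
                    double lambda0, double gamma,
                    bool freeze_r, bool freeze_lambda,
                    NetDeriv& out) {
  const int n = (int)phi.size();
  if ((int)out.cbuf.size() != n) { out.cbuf.resize(n); out.sbuf.resize(n); }
  double zre = 0.0, zim = 0.0;
  for (int k = 0; k < n; ++k) {
    out.cbuf[k] = std::cos(phi[k]);
    out.sbuf[k] = std::sin(phi[k]);
    zre += out.cbuf[k];
    zim += out.sbuf[k];
  }
  zre /= n; zim /= n;
  double acc = 0.0;
  for (int k = 0; k < n; ++k) {
    // Im(Z e^{-i phi}) = Im(Z) cos(phi) - Re(Z) sin(phi)
    double d = r1 + r2 * nu[k] - out.sbuf[k] +
        sigma * (zim * out.cbuf[k] - zre * out.sbuf[k]);
    out.dphi[k] = d;
    acc += d;
  }
  out.A = acc / n;
  if (freeze_r) {
    out.dr1 = 0.0; out.dr2 = 0.0;
  } else {
    double u1 = r1 - s1, u2 = r2 - s2;
    double m2 = u1 * u1 + u2 * u2;
    // f(u, lam) = u (lam + i omega - |u|^2)
    out.dr1 = eps * (u1 * (lam - m2) - u2 * omega);
    out.dr2 = eps * (u2 * (lam - m2) + u1 * omega);
  }
  out.dlam = freeze_lambda ? 0.0 : -eps_prime * (lam - lambda0 - gamma * out.A);
}

// [[Rcpp::export]]
List rk4_network_cpp(NumericVector phases, NumericVector nu,
                     double r1, double r2, double lam,
                     double sigma, double eps, double eps_prime,
                     double s1, double s2, double omega,
                     double lambda0, double gamma,
                     double dt, int nsteps, int record_every,
                     bool freeze_r, bool freeze_lambda, double t0) {
  const int n = phases.size();
  std::vector<double> phi(phases.begin(), phases.end());
  std::vector<double> nuv(nu.begin(), nu.end());
  NetDeriv k1, k2, k3, k4;
  k1.dphi.resize(n); k2.dphi.resize(n); k3.dphi.resize(n); k4.dphi.resize(n);
  std::vector<double> tmp(n);

  int nrec = nsteps / record_every + 1;
  NumericVector t_out(nrec), A_out(nrec), R_out(nrec), Th_out(nrec),
      r1_out(nrec), r2_out(nrec), lam_out(nrec);
  int j = 0;

  for (int step = 0; step <= nsteps; ++step) {
    if (step % record_every == 0) {
      net_rhs(phi, nuv, r1, r2, lam, sigma, eps, eps_prime, s1, s2, omega,
              lambda0, gamma, freeze_r, freeze_lambda, k1);
      double zre = 0.0, zim = 0.0;
      for (int k = 0; k < n; ++k) { zre += std::cos(phi[k]); zim += std::sin(phi[k]); }
      zre /= n; zim /= n;
      t_out[j] = t0 + step * dt;
      A_out[j] = k1.A;
      R_out[j] = std::sqrt(zre * zre + zim * zim);
      Th_out[j] = std::atan2(zim, zre);
      r1_out[j] = r1; r2_out[j] = r2; lam_out[j] = lam;
      ++j;
    }
    if (step == nsteps) break;

    net_rhs(phi, nuv, r1, r2, lam, sigma, eps, eps_prime, s1, s2, omega,
            lambda0, gamma, freeze_r, freeze_lambda, k1);
    for (int k = 0; k < n; ++k) tmp[k] = phi[k] + 0.5 * dt * k1.dphi[k];
    net_rhs(tmp, nuv, r1 + 0.5 * dt * k1.dr1, r2 + 0.5 * dt * k1.dr2,
            lam + 0.5 * dt * k1.dlam, sigma, eps, eps_prime, s1, s2, omega,
            lambda0, gamma, freeze_r, freeze_lambda, k2);
    for (int k = 0; k < n; ++k) tmp[k] = phi[k] + 0.5 * dt * k2.dphi[k];
    net_rhs(tmp, nuv, r1 + 0.5 * dt * k2.dr1, r2 + 0.5 * dt * k2.dr2,
            lam + 0.5 * dt * k2.dlam, sigma, eps, eps_prime, s1, s2, omega,
            lambda0, gamma, freeze_r, freeze_lambda, k3);
    for (int k = 0; k < n; ++k) tmp[k] = phi[k] + dt * k3.dphi[k];
    net_rhs(tmp, nuv, r1 + dt * k3.dr1, r2 + dt * k3.dr2,
            lam + dt * k3.dlam, sigma, eps, eps_prime, s1, s2, omega,
            lambda0, gamma, freeze_r, freeze_lambda, k4);

    for (int k = 0; k < n; ++k)
      phi[k] += dt / 6.0 * (k1.dphi[k] + 2.0 * k2.dphi[k] + 2.0 * k3.dphi[k] + k4.dphi[k]);
    r1 += dt / 6.0 * (k1.dr1 + 2.0 * k2.dr1 + 2.0 * k3.dr1 + k4.dr1);
    r2 += dt / 6.0 * (k1.dr2 + 2.0 * k2.dr2 + 2.0 * k3.dr2 + k4.dr2);
    lam += dt / 6.0 * (k1.dlam + 2.0 * k2.dlam + 2.0 * k3.dlam + k4.dlam);
  }

  return List::create(
      _["t"] = t_out, _["A"] = A_out, _["R"] = R_out, _["Theta"] = Th_out,
      _["r1"] = r1_out, _["r2"] = r2_out, _["lambda"] = lam_out,
      _["phases_final"] = NumericVector(phi.begin(), phi.end()),
      _["r1_final"] = r1, _["r2_final"] = r2, _["lambda_final"] = lam);
}

struct OADeriv {
  std::vector<cplx> dz;
  double dr1, dr2, dlam;
};

static void oa_rhs_cpp(const std::vector<cplx>& z,
                       const std::vector<double>& nodes,
                       const std::vector<double>& w,
                       double r1, double r2, double lam,
                       double sigma, double eps, double eps_prime,
                       double s1, double s2, double omega,
                       double lambda0, double gamma,
                       bool freeze_r, bool freeze_lambda,
                       OADeriv& out) {
  const int m = (int)z.size();
  cplx Z(0.0, 0.0);
  for (int k = 0; k < m; ++k) Z += w[k] * z[k];
  const cplx Zc = std::conj(Z);
  for (int k = 0; k < m; ++k) {
    double I = r1 + r2 * nodes[k];
    cplx zz = z[k] * z[k];
    out.dz[k] = 0.5 * (1.0 - zz) + cplx(0.0, I) * z[k]
        + 0.5 * sigma * Z - 0.5 * sigma * Zc * zz;
  }
  double A = r1 - Z.imag();  // population activity in the mean-field limit
  if (freeze_r) {
    out.dr1 = 0.0; out.dr2 = 0.0;
  } else {
    double u1 = r1 - s1, u2 = r2 - s2;
    double m2 = u1 * u1 + u2 * u2;
    out.dr1 = eps * (u1 * (lam - m2) - u2 * omega);
    out.dr2 = eps * (u2 * (lam - m2) + u1 * omega);
  }
  out.dlam = freeze_lambda ? 0.0 : -eps_prime * (lam - lambda0 - gamma * A);
}

// [[Rcpp::export]]
List rk4_oa_cpp(ComplexVector z0, NumericVector nodes, NumericVector weights,
                double r1, double r2, double lam,
                double sigma, double eps, double eps_prime,
                double s1, double s2, double omega,
                double lambda0, double gamma,
                double dt, int nsteps, int record_every,
                bool freeze_r, bool freeze_lambda, double t0) {
  const int m = z0.size();
  std::vector<cplx> z(m);
  for (int k = 0; k < m; ++k) z[k] = cplx(z0[k].r, z0[k].i);
  std::vector<double> nod(nodes.begin(), nodes.end());
  std::vector<double> w(weights.begin(), weights.end());

  OADeriv k1, k2, k3, k4;
  k1.dz.resize(m); k2.dz.resize(m); k3.dz.resize(m); k4.dz.resize(m);
  std::vector<cplx> tmp(m);

  int nrec = nsteps / record_every + 1;
  NumericVector t_out(nrec), zre_out(nrec), zim_out(nrec),
      r1_out(nrec), r2_out(nrec), lam_out(nrec);
  double max_abs_z = 0.0;
  int j = 0;

  for (int step = 0; step <= nsteps; ++step) {
    double ma = 0.0;
    for (int k = 0; k < m; ++k) ma = std::max(ma, std::abs(z[k]));
    if (ma > max_abs_z) max_abs_z = ma;
    if (step % record_every == 0) {
      cplx Z(0.0, 0.0);
      for (int k = 0; k < m; ++k) Z += w[k] * z[k];
      t_out[j] = t0 + step * dt;
      zre_out[j] = Z.real(); zim_out[j] = Z.imag();
      r1_out[j] = r1; r2_out[j] = r2; lam_out[j] = lam;
      ++j;
    }
    if (step == nsteps) break;

    oa_rhs_cpp(z, nod, w, r1, r2, lam, sigma, eps, eps_prime, s1, s2, omega,
               lambda0, gamma, freeze_r, freeze_lambda, k1);
    for (int k = 0; k < m; ++k) tmp[k] = z[k] + 0.5 * dt * k1.dz[k];
    oa_rhs_cpp(tmp, nod, w, r1 + 0.5 * dt * k1.dr1, r2 + 0.5 * dt * k1.dr2,
               lam + 0.5 * dt * k1.dlam, sigma, eps, eps_prime, s1, s2, omega,
               lambda0, gamma, freeze_r, freeze_lambda, k2);
    for (int k = 0; k < m; ++k) tmp[k] = z[k] + 0.5 * dt * k2.dz[k];
    oa_rhs_cpp(tmp, nod, w, r1 + 0.5 * dt * k2.dr1, r2 + 0.5 * dt * k2.dr2,
               lam + 0.5 * dt * k2.dlam, sigma, eps, eps_prime, s1, s2, omega,
               lambda0, gamma, freeze_r, freeze_lambda, k3);
    for (int k = 0; k < m; ++k) tmp[k] = z[k] + dt * k3.dz[k];
    oa_rhs_cpp(tmp, nod, w, r1 + dt * k3.dr1, r2 + dt * k3.dr2,
               lam + dt * k3.dlam, sigma, eps, eps_prime, s1, s2, omega,
               lambda0, gamma, freeze_r, freeze_lambda, k4);

    for (int k = 0; k < m; ++k)
      z[k] += dt / 6.0 * (k1.dz[k] + 2.0 * k2.dz[k] + 2.0 * k3.dz[k] + k4.dz[k]);
    r1 += dt / 6.0 * (k1.dr1 + 2.0 * k2.dr1 + 2.0 * k3.dr1 + k4.dr1);
    r2 += dt / 6.0 * (k1.dr2 + 2.0 * k2.dr2 + 2.0 * k3.dr2 + k4.dr2);
    lam += dt / 6.0 * (k1.dlam + 2.0 * k2.dlam + 2.0 * k3.dlam + k4.dlam);
  }

  ComplexVector z_final(m);
  for (int k = 0; k < m; ++k) {
    z_final[k].r = z[k].real();
    z_final[k].i = z[k].imag();
  }
  return List::create(
      _["t"] = t_out, _["ReZ"] = zre_out, _["ImZ"] = zim_out,
      _["r1"] = r1_out, _["r2"] = r2_out, _["lambda"] = lam_out,
      _["z_final"] = z_final, _["r1_final"] = r1, _["r2_final"] = r2,
      _["lambda_final"] = lam, _["max_abs_z"] = max_abs_z);
}
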