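// Semi-implicit Fourier-spectral integrator for the conserved multi-phase
// field model: d_t phi_i + v_i . grad phi_i = Lap( dF/dphi_i ).
// The stiff linear Cahn-Hilliard part (eps/Ca) Lap^2 phi and a stabilising
// split term sigma Lap phi are treated implicitly in Fourier space; the
// cubic well, the cell-cell interaction term and advection are explicit.
// Spatial transforms use FFTW3 real-to-complex plans (FFTW_ESTIMATE, so the
// chosen algorithm -- and hence the floating-point result -- is identical
// across runs).
//
// Grid convention: phi(r, c) lives at x1 = r * dx, x2 = c * dx on a periodic
// [0, L)^2 domain with n points per side.

#include <RcppArmadillo.h>
#include <fftw3.h>

using namespace arma;

namespace {

struct FFTPlan {
  int n, nc;
  mat rbuf;
  cx_mat cbuf;
  fftw_plan pf, pb;
  explicit FFTPlan(int n_)
      : n(n_), nc(n_ / 2 + 1), rbuf(n_, n_), cbuf(n_ / 2 + 1, n_) {
    pf = fftw_plan_dft_r2c_2d(
        n, n, rbuf.memptr(), reinterpret_cast<fftw_complex *>(cbuf.memptr()),
        FFTW_ESTIMATE);
    pb = fftw_plan_dft_c2r_2d(
        n, n, reinterpret_cast<fftw_complex *>(cbuf.memptr()), rbuf.memptr(),
        FFTW_ESTIMATE);
  }
  ~FFTPlan() {
    fftw_destroy_plan(pf);
    fftw_destroy_plan(pb);
  }
  void fwd(const mat &A, cx_mat &out) {
    rbuf = A;
    fftw_execute(pf);
    out = cbuf;
  }
  void bwd(const cx_mat &F, mat &out) {
    cbuf = F;  // c2r destroys its input, so work on the member copy
    fftw_execute(pb);
    out = rbuf / (double(n) * double(n));
  }
};

inline double wrap_pi(double x) {
  // wrap to (-pi, pi]
  return x - 2.0 * M_PI * std::ceil((x - M_PI) / (2.0 * M_PI));
}

}  // namespace

// One or more Euler steps of the full model for all N cells.
// phi: n x n x N cube, theta: length N, dW: N x nsteps Gaussian increments
// with sd sqrt(tau). mode: 0 = active self-propulsion, 1 = passive shear
// v = 0.5 |x1 - L/2| e_2 (v0 ignored). beta_literal: 0 = nearest nematic
// representative of the elongation axis, 1 = the signed-arg rule.
// [[Rcpp::export]]
Rcpp::List cpp_run_chunk(const arma::cube &phi_in, const arma::vec &theta_in,
                         const arma::mat &dW, int nsteps, double tau,
                         double L, double eps, double v0, double a, double Ca,
                         double In, double Dr, double alpha, double sigma,
                         int mode, int beta_literal) {
  // deep copies: the cube conversion aliases R's memory, and the caller's
  // state must not be mutated in place
  arma::cube phi(phi_in.memptr(), phi_in.n_rows, phi_in.n_cols,
                 phi_in.n_slices);
  arma::vec theta(theta_in.memptr(), theta_in.n_elem);
  const int n = phi.n_rows;
  const int N = phi.n_slices;
  const int nc = n / 2 + 1;
  const double dx = L / n;

  FFTPlan fft(n);

  // Wavenumbers. FFTW interprets the column-major arma matrix as row-major,
  // so the halved ("fast") output dimension corresponds to the arma row
  // index. The grid is square so the labelling of axes is symmetric.
  vec kf(nc), ks(n);
  for (int i = 0; i < nc; i++) kf(i) = 2.0 * M_PI * i / L;
  for (int j = 0; j < n; j++)
    ks(j) = 2.0 * M_PI * (j <= n / 2 ? j : j - n) / L;
  mat k2(nc, n), denom(nc, n);
  for (int j = 0; j < n; j++)
    for (int i = 0; i < nc; i++) {
      double kk = kf(i) * kf(i) + ks(j) * ks(j);
      k2(i, j) = kk;
      denom(i, j) = 1.0 + tau * (eps / Ca) * kk * kk + tau * sigma * kk;
    }

  // periodic neighbour index tables
  ivec ip(n), im(n);
  for (int i = 0; i < n; i++) {
    ip(i) = (i + 1) % n;
    im(i) = (i + n - 1) % n;
  }

  // cached transforms of the current fields
  cx_cube PH(nc, n, N);
  cx_mat tmp(nc, n);
  for (int s = 0; s < N; s++) {
    fft.fwd(phi.slice(s), tmp);
    PH.slice(s) = tmp;
  }

  mat sumB(n, n), sumW(n, n), mu(n, n), adv(n, n), newphi(n, n);
  cx_mat Fmu(nc, n), Fadv(nc, n), NH(nc, n);
  cube phinew(n, n, N);
  cx_cube PHnew(nc, n, N);
  vec vmag(n);
  for (int r = 0; r < n; r++) vmag(r) = 0.5 * std::fabs(r * dx - L / 2.0);

  const double inv2dx = 1.0 / (2.0 * dx);
  bool ok = true;
  int steps_done = 0;

  for (int step = 0; step < nsteps && ok; step++) {
    // fields entering the explicit terms are all at the current time level
    sumB.zeros();
    sumW.zeros();
    for (int s = 0; s < N; s++) {
      const mat &P = phi.slice(s);
      for (int c = 0; c < n; c++)
        for (int r = 0; r < n; r++) {
          double p = P(r, c);
          double u = (p - 1.0) / 2.0;
          sumB(r, c) += (p + 1.0) / 2.0;
          sumW(r, c) += 1.0 - (a + 1.0) * u * u + a * u * u * u * u;
        }
    }

    for (int s = 0; s < N; s++) {
      const mat &P = phi.slice(s);
      const double ci = std::cos(theta(s)), si = std::sin(theta(s));
      for (int c = 0; c < n; c++) {
        int cp = ip(c), cm = im(c);
        for (int r = 0; r < n; r++) {
          int rp = ip(r), rm = im(r);
          double p = P(r, c);
          double u = (p - 1.0) / 2.0;
          double B = (p + 1.0) / 2.0;
          double w = 1.0 - (a + 1.0) * u * u + a * u * u * u * u;
          double wp = -(a + 1.0) * u + 2.0 * a * u * u * u;  // dw/dphi
          double gx = (P(rp, c) - P(rm, c)) * inv2dx;
          double gy = (P(r, cp) - P(r, cm)) * inv2dx;
          mu(r, c) = (p * p * p - p) / (eps * Ca) +
                     (0.5 * (sumW(r, c) - w) + wp * (sumB(r, c) - B)) / In -
                     sigma * p;
          adv(r, c) = (mode == 0) ? v0 * B * (ci * gx + si * gy)
                                  : vmag(r) * gy;
        }
      }
      fft.fwd(mu, Fmu);
      fft.fwd(adv, Fadv);
      NH = (PH.slice(s) - tau * (k2 % Fmu) - tau * Fadv) / denom;
      PHnew.slice(s) = NH;
      fft.bwd(NH, newphi);
      phinew.slice(s) = newphi;
    }
    phi = phinew;
    PH = PHnew;

    if (!phi.is_finite()) {
      ok = false;
      break;
    }

    // orientation update from the freshly advanced fields
    for (int s = 0; s < N; s++) {
      const mat &P = phi.slice(s);
      double S0 = 0.0, S1 = 0.0, area = 0.0;
      for (int c = 0; c < n; c++) {
        int cp = ip(c), cm = im(c);
        for (int r = 0; r < n; r++) {
          int rp = ip(r), rm = im(r);
          double gx = (P(rp, c) - P(rm, c)) * inv2dx;
          double gy = (P(r, cp) - P(r, cm)) * inv2dx;
          S0 += gy * gy - gx * gx;
          S1 += gx * gy;
          area += (P(r, c) + 1.0) / 2.0;
        }
      }
      S0 *= dx * dx / 8.0;
      S1 *= -dx * dx / 4.0;
      area *= dx * dx;
      double lam = std::sqrt(S0 * S0 + S1 * S1);
      double th = theta(s);
      double beta;
      if (lam < 1e-12 * area) {
        beta = th;  // isotropic cell: no alignment torque
      } else {
        double psi = 0.5 * std::atan2(S1, S0);  // elongation axis angle
        if (beta_literal) {
          double edot = std::cos(th) * std::cos(psi) +
                        std::sin(th) * std::sin(psi);
          beta = (edot >= 0.0) ? psi : -psi;
        } else {
          double d = wrap_pi(psi - th);
          if (std::fabs(d) > M_PI / 2.0) psi = wrap_pi(psi + M_PI);
          beta = psi;
        }
      }
      th = th + alpha * wrap_pi(beta - th) * tau +
           std::sqrt(2.0 * Dr) * dW(s, step);
      theta(s) = wrap_pi(th);
    }
    steps_done = step + 1;
  }

  return Rcpp::List::create(Rcpp::Named("phi") = phi,
                            Rcpp::Named("theta") = theta,
                            Rcpp::Named("ok") = ok,
                            Rcpp::Named("steps_done") = steps_done);
}

// Shape deformation tensor of one field by midpoint quadrature of the
// gradient integrals (central differences, periodic).
// [[Rcpp::export]]
Rcpp::List cpp_shape_tensor(const arma::mat &P, double L) {
  const int n = P.n_rows;
  const double dx = L / n;
  const double inv2dx = 1.0 / (2.0 * dx);
  double S0 = 0.0, S1 = 0.0, area = 0.0;
  for (int c = 0; c < n; c++) {
    int cp = (c + 1) % n, cm = (c + n - 1) % n;
    for (int r = 0; r < n; r++) {
      int rp = (r + 1) % n, rm = (r + n - 1) % n;
      double gx = (P(rp, c) - P(rm, c)) * inv2dx;
      double gy = (P(r, cp) - P(r, cm)) * inv2dx;
      S0 += gy * gy - gx * gx;
      S1 += gx * gy;
      area += (P(r, c) + 1.0) / 2.0;
    }
  }
  return Rcpp::List::create(Rcpp::Named("S0") = S0 * dx * dx / 8.0,
                            Rcpp::Named("S1") = -S1 * dx * dx / 4.0,
                            Rcpp::Named("area") = area * dx * dx);
}
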