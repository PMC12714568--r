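// Bloch-McConnell evolution core for R1rho and CEST forward models.
//
// The magnetization basis is the 3N-vector (Mx, My, Mz per state). Offsets are
// referenced to the population-average resonance; conversion ppm -> rad/s uses
// 2*pi*ppm*larmor_mhz. The generator for state i with rotating-frame offset
// delta_i (rad/s) and spin-lock amplitude w1 (rad/s, along x) is
//
//   d/dt [Mx,My,Mz]_i = [ -R2   -d_i   0  ] [Mx]
//                       [  d_i  -R2   -w1 ] [My]  + exchange couplings
//                       [  0     w1   -R1 ] [Mz]
//
// so that the stationary direction of the relaxation-free one-state problem is
// (sin t, 0, cos t) with tan t = w1/delta. Exchange adds k(j->i)*I3 blocks and
// -sum_j k(i->j)*I3 on the diagonal (columns of the exchange matrix sum to 0,
// conserving total magnetization). The homogeneous form (no M0 recovery term)
// is used: R1rho and CEST observables are decays toward zero, matching the
// normalization conventions of both experiments.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double TWO_PI = 6.283185307179586476925;

// Build the 3N x 3N evolution matrix.
// kmat(i,j) = first-order rate constant for i -> j (s^-1).
static arma::mat bm_matrix(const arma::vec& delta, double w1,
                           double r1, double r2, const arma::mat& kmat) {
  const arma::uword n = delta.n_elem;
  arma::mat L(3 * n, 3 * n, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i) {
    const arma::uword o = 3 * i;
    L(o, o) = -r2;        L(o, o + 1) = -delta(i);
    L(o + 1, o) = delta(i); L(o + 1, o + 1) = -r2;  L(o + 1, o + 2) = -w1;
    L(o + 2, o + 1) = w1;   L(o + 2, o + 2) = -r1;
    double kout = 0.0;
    for (arma::uword j = 0; j < n; ++j) {
      if (j == i) continue;
      kout += kmat(i, j);
      const arma::uword oj = 3 * j;
      // influx j -> i
      L(o, oj)         += kmat(j, i);
      L(o + 1, oj + 1) += kmat(j, i);
      L(o + 2, oj + 2) += kmat(j, i);
    }
    L(o, o)         -= kout;
    L(o + 1, o + 1) -= kout;
    L(o + 2, o + 2) -= kout;
  }
  return L;
}

// Propagate M0 under L to the requested times via complex eigendecomposition,
// falling back to scaling-and-squaring (arma::expmat) when the eigenvector
// matrix is ill-conditioned.
static arma::mat propagate(const arma::mat& L, const arma::vec& m0,
                           const arma::vec& times) {
  const arma::uword n = L.n_rows, nt = times.n_elem;
  arma::mat out(n, nt);
  arma::cx_vec eval;
  arma::cx_mat evec;
  bool ok = arma::eig_gen(eval, evec, L);
  if (ok) {
    arma::cx_vec c;
    ok = arma::solve(c, evec, arma::cx_vec(m0, arma::vec(n, arma::fill::zeros)),
                     arma::solve_opts::no_approx);
    if (ok && arma::rcond(evec) > 1e-13) {
      for (arma::uword t = 0; t < nt; ++t) {
        arma::cx_vec mt = evec * (c % arma::exp(eval * times(t)));
        out.col(t) = arma::real(mt);
      }
      return out;
    }
  }
  // fallback: direct matrix exponential per unique time
  for (arma::uword t = 0; t < nt; ++t) {
    out.col(t) = arma::expmat(L * times(t)) * m0;
  }
  return out;
}

// Nonlinear least-squares fit of y = a*exp(-r*t) by Gauss-Newton with a
// log-linear start. Returns the decay rate r.
static double fit_monoexp(const arma::vec& t, const arma::vec& y) {
  const arma::uword n = t.n_elem;
  double a = y(0), r = 0.0;
  bool pos = arma::all(y > 0.0);
  if (pos) {
    // log-linear start (exact for a perfect exponential)
    arma::vec ly = arma::log(y);
    double tm = arma::mean(t), lm = arma::mean(ly);
    double sxx = arma::accu(arma::square(t - tm));
    if (sxx > 0) {
      r = -arma::accu((t - tm) % (ly - lm)) / sxx;
      a = std::exp(lm + r * tm);
    }
  } else {
    a = y.max();
    r = 1.0;
  }
  for (int it = 0; it < 50; ++it) {
    arma::vec e = a * arma::exp(-r * t);
    arma::vec res = y - e;
    arma::mat J(n, 2);
    J.col(0) = e / a;          // d/da
    J.col(1) = -t % e;         // d/dr
    arma::vec step;
    arma::mat JtJ = J.t() * J;
    JtJ.diag() += 1e-12 * arma::trace(JtJ);
    if (!arma::solve(step, JtJ, J.t() * res, arma::solve_opts::no_approx)) break;
    a += step(0);
    r += step(1);
    if (std::abs(step(1)) < 1e-12 * std::max(1.0, std::abs(r))) break;
  }
  return r;
}

struct R1rhoResult { double rate; };

// Single-point R1rho: build matrix, choose alignment, propagate 5 delays,
// project onto the initial effective-field axis, fit a mono-exponential.
static double r1rho_point(const arma::vec& pops, const arma::mat& kmat,
                          const arma::vec& dw_rad, double r1, double r2,
                          double w1, double omega, int n_delays,
                          double max_delay, double align_threshold) {
  const arma::uword n = pops.n_elem;
  // rotating-frame offsets referenced to the population-average shift;
  // omega = omega_RF - omega_obs, so delta_i = (omega_i - omega_obs) - omega
  // and the exchange peak appears at a carrier offset of +dw (minor state)
  double dw_avg = arma::dot(pops, dw_rad);
  arma::vec delta = dw_rad - dw_avg - omega;
  arma::mat L = bm_matrix(delta, w1, r1, r2, kmat);

  // alignment rule: exchange regime from kex/|dw| for exchanging minor states
  double ratio = arma::datum::inf;
  for (arma::uword j = 0; j < n; ++j) {
    double adw = std::abs(dw_rad(j) - dw_rad(0));
    if (j == 0 || adw < 1e-9 || pops(j) <= 0) continue;
    double kex = arma::accu(kmat.row(j)) + arma::accu(kmat.col(j));
    ratio = std::min(ratio, kex / adw);
  }
  double theta;
  if (ratio >= align_threshold) {
    theta = std::atan2(w1, -omega);         // average-state effective field
  } else {
    theta = std::atan2(w1, delta(0));       // ground-state effective field
  }
  arma::vec m0(3 * n, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i) {
    m0(3 * i)     = pops(i) * std::sin(theta);
    m0(3 * i + 2) = pops(i) * std::cos(theta);
  }

  // one eigendecomposition serves every delay; the projection of M(t) onto
  // the initial effective-field axis reduces to a scalar sum over modes
  arma::cx_vec axis(3 * n, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i) {
    axis(3 * i)     = std::sin(theta);
    axis(3 * i + 2) = std::cos(theta);
  }
  arma::cx_vec eval;
  arma::cx_mat evec;
  bool eig_ok = arma::eig_gen(eval, evec, L);
  arma::cx_vec amp;  // per-mode amplitude of the projected signal
  if (eig_ok && arma::rcond(evec) > 1e-13) {
    arma::cx_vec c0v;
    eig_ok = arma::solve(c0v, evec,
                         arma::cx_vec(m0, arma::vec(3 * n, arma::fill::zeros)),
                         arma::solve_opts::no_approx);
    if (eig_ok) amp = (evec.st() * axis) % c0v;
  }
  auto project_at = [&](double t) {
    if (eig_ok) {
      std::complex<double> s(0.0, 0.0);
      for (arma::uword k = 0; k < amp.n_elem; ++k)
        s += amp(k) * std::exp(eval(k) * t);
      return s.real();
    }
    arma::vec mt = arma::expmat(L * t) * m0;  // conditioning fallback
    double s = 0.0;
    for (arma::uword i = 0; i < n; ++i)
      s += mt(3 * i) * std::sin(theta) + mt(3 * i + 2) * std::cos(theta);
    return s;
  };

  // delays: 5 points evenly spaced to ~70% decay (capped at max_delay)
  double tprobe = std::min(0.005, max_delay / 4.0);
  double c0 = project_at(0.0), c1 = project_at(tprobe);
  double rguess = (c0 > 0 && c1 > 0) ? std::log(c0 / c1) / tprobe : 1.0;
  rguess = std::max(rguess, 1e-3);
  double tmax = std::min(max_delay, 1.2 / rguess);
  arma::vec delays = arma::linspace(0.0, tmax, n_delays);
  arma::vec proj(n_delays);
  for (int t = 0; t < n_delays; ++t) proj(t) = project_at(delays(t));
  return fit_monoexp(delays, proj);
}

//' @noRd
// [[Rcpp::export(name = ".bm_r1rho_grid")]]
NumericVector bm_r1rho_grid(NumericVector pops, NumericMatrix kmat,
                            NumericVector dw_ppm, double larmor_mhz,
                            double r1, double r2,
                            NumericVector power_hz, NumericVector offset_hz,
                            int n_delays = 5, double max_delay = 0.12,
                            double align_threshold = 5.0) {
  arma::vec p = as<arma::vec>(pops);
  arma::mat K = as<arma::mat>(kmat);
  arma::vec dw = as<arma::vec>(dw_ppm) * TWO_PI * larmor_mhz;
  int m = power_hz.size();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    if (power_hz[i] <= 0) stop("spin-lock power must be positive");
    out[i] = r1rho_point(p, K, dw, r1, r2,
                         TWO_PI * power_hz[i], TWO_PI * offset_hz[i],
                         n_delays, max_delay, align_threshold);
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".bm_cest_grid")]]
NumericVector bm_cest_grid(NumericVector pops, NumericMatrix kmat,
                           NumericVector dw_ppm, double larmor_mhz,
                           double r1, double r2,
                           NumericVector b1_hz, NumericVector offset_ppm,
                           double t_relax,
                           NumericVector b1_scale, NumericVector b1_weight) {
  arma::vec p = as<arma::vec>(pops);
  arma::mat K = as<arma::mat>(kmat);
  arma::vec dwp = as<arma::vec>(dw_ppm);
  const arma::uword n = p.n_elem;
  int m = b1_hz.size();
  int nq = b1_scale.size();
  NumericVector out(m);
  arma::vec times = {t_relax};
  for (int i = 0; i < m; ++i) {
    // saturation carrier at offset_ppm from the dominant-state resonance
    arma::vec delta = (dwp - offset_ppm[i]) * TWO_PI * larmor_mhz;
    arma::vec m0(3 * n, arma::fill::zeros);
    for (arma::uword s = 0; s < n; ++s) m0(3 * s + 2) = p(s);
    double acc = 0.0;
    for (int q = 0; q < nq; ++q) {
      double w1 = TWO_PI * b1_hz[i] * b1_scale[q];
      arma::mat L = bm_matrix(delta, w1, r1, r2, K);
      arma::mat mt = propagate(L, m0, times);
      acc += b1_weight[q] * mt(2, 0);  // Mz of the dominant (first) state
    }
    out[i] = acc / p(0);               // normalize by zero-delay reference
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".bm_evolution_matrix")]]
NumericMatrix bm_evolution_matrix(NumericVector pops, NumericMatrix kmat,
                                  NumericVector dw_ppm, double larmor_mhz,
                                  double r1, double r2,
                                  double power_hz, double offset_hz) {
  arma::vec p = as<arma::vec>(pops);
  arma::mat K = as<arma::mat>(kmat);
  arma::vec dw = as<arma::vec>(dw_ppm) * TWO_PI * larmor_mhz;
  double dw_avg = arma::dot(p, dw);
  arma::vec delta = dw - dw_avg - TWO_PI * offset_hz;
  arma::mat L = bm_matrix(delta, TWO_PI * power_hz, r1, r2, K);
  return wrap(L);
}
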