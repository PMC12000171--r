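#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Crank-Nicolson solution of the Kolmogorov forward (Fokker-Planck) equation
//   df/dt = -mu(t) df/dx + (sigma^2/2) d2f/dx2
// on x in [-b, b] with absorbing boundaries f(+-b, t) = 0 and a Dirac initial
// condition at x = 0 (centre node). The drift is uniform in space, so the
// operator is tridiagonal with constant off-diagonal structure per step.
//
// drift_half holds mu evaluated at the half steps t_n + dt/2, n = 0..nt-1.
// The Dirac initial condition is replaced by its analytic short-time
// solution after n_startup steps (a drifted Gaussian with the leading
// image-pair correction for the absorbing barriers); pure Crank-Nicolson
// takes over from there. This avoids both the ringing a grid Dirac excites
// under Crank-Nicolson and the first-order error of damped startup steps.
//
// Returns the outward probability flux (defective density) at each boundary
// on the full time grid t_0 = 0 .. t_nt, the final interior mass, and the
// largest per-step mass-balance violation observed after the startup steps.

// [[Rcpp::export]]
List cn_forward(NumericVector drift_half, double b, double sigma,
                int nx, double dt, int n_startup) {
  const int nt = drift_half.size();
  if (nx < 5 || nx % 2 == 0) stop("nx must be odd and >= 5");
  if (n_startup < 1 || n_startup > nt) stop("invalid n_startup");
  const int m = nx - 2;               // interior nodes
  const double dx = 2.0 * b / (nx - 1);
  const double D = 0.5 * sigma * sigma;
  const double rd = D * dt / (dx * dx);     // diffusion number

  std::vector<double> f(m, 0.0), rhs(m), cp(m), dpr(m);

  // analytic warm start at t_w = n_startup * dt: N(mean, s2) plus the
  // first image in each barrier (exact for constant drift, adequate for
  // the smooth drifts used here over a few milliseconds)
  {
    double mean = 0.0;
    for (int n = 0; n < n_startup; ++n) mean += drift_half[n] * dt;
    const double mu_eff = mean / (n_startup * dt);
    const double s2 = sigma * sigma * (n_startup * dt);
    const double norm = 1.0 / std::sqrt(2.0 * M_PI * s2);
    const double wu = std::exp(2.0 * mu_eff * b / (sigma * sigma));
    for (int i = 0; i < m; ++i) {
      const double x = -b + (i + 1) * dx;
      double v = std::exp(-(x - mean) * (x - mean) / (2.0 * s2));
      v -= wu * std::exp(-(x - 2.0 * b - mean) * (x - 2.0 * b - mean) /
                         (2.0 * s2));
      v -= (1.0 / wu) * std::exp(-(x + 2.0 * b - mean) * (x + 2.0 * b - mean) /
                                 (2.0 * s2));
      f[i] = (v > 0.0) ? norm * v : 0.0;
    }
  }

  NumericVector g_up(nt + 1, 0.0), g_low(nt + 1, 0.0);
  const double fluxc = D / (6.0 * dx);

  double max_imbal = 0.0;
  double mass_prev = 0.0;
  for (int i = 0; i < m; ++i) mass_prev += f[i];
  mass_prev *= dx;

  // flux at the warm-start time itself (essentially zero for sane grids)
  g_up[n_startup]  = fluxc * (18.0 * f[m - 1] - 9.0 * f[m - 2] + 2.0 * f[m - 3]);
  g_low[n_startup] = fluxc * (18.0 * f[0] - 9.0 * f[1] + 2.0 * f[2]);

  for (int n = n_startup; n < nt; ++n) {
    const double mu = drift_half[n];
    const double ra = mu * dt / (2.0 * dx); // advection number
    const double th = 0.5;                  // Crank-Nicolson

    // operator coefficients: (L f)_i = lo*f_{i-1} + di*f_i + up*f_{i+1}
    const double lo = rd + ra;   // times dt already folded in
    const double di = -2.0 * rd;
    const double up = rd - ra;

    // fused pass 1: rhs = (I + (1-th) L) f and the Thomas forward sweep
    const double a_sub = -th * lo, a_dia = 1.0 - th * di, a_sup = -th * up;
    const double e_lo = (1.0 - th) * lo, e_di = 1.0 + (1.0 - th) * di,
                 e_up = (1.0 - th) * up;
    {
      double r0 = e_di * f[0] + e_up * f[1];
      cp[0] = a_sup / a_dia;
      dpr[0] = r0 / a_dia;
      for (int i = 1; i < m; ++i) {
        double ri = e_di * f[i] + e_lo * f[i - 1];
        if (i < m - 1) ri += e_up * f[i + 1];
        const double w = a_dia - a_sub * cp[i - 1];
        cp[i] = a_sup / w;
        dpr[i] = (ri - a_sub * dpr[i - 1]) / w;
      }
    }
    // pass 2: linear back-substitution (clamping inside this sweep would
    // let one clamped node perturb all later nodes and break the
    // drift-sign mirror symmetry at undershoot scale)
    f[m - 1] = dpr[m - 1];
    for (int i = m - 2; i >= 0; --i) f[i] = dpr[i] - cp[i] * f[i + 1];
    // pass 3: undershoot clamp and interior mass
    double mass = 0.0;
    for (int i = 0; i < m; ++i) {
      if (f[i] < 0.0) f[i] = 0.0;
      mass += f[i];
    }
    mass *= dx;
    if (!std::isfinite(mass))
      stop("numerical failure (non-finite density) at time step %d", n + 1);

    // third-order one-sided boundary flux; boundary value is exactly 0
    g_up[n + 1]  = fluxc * (18.0 * f[m - 1] - 9.0 * f[m - 2] + 2.0 * f[m - 3]);
    g_low[n + 1] = fluxc * (18.0 * f[0] - 9.0 * f[1] + 2.0 * f[2]);
    if (g_up[n + 1] < 0.0) g_up[n + 1] = 0.0;
    if (g_low[n + 1] < 0.0) g_low[n + 1] = 0.0;
    if (n > n_startup) {
      // trapezoidal absorbed mass over this step vs interior mass change
      const double absorbed = 0.5 * dt *
        (g_up[n] + g_up[n + 1] + g_low[n] + g_low[n + 1]);
      const double imbal = std::fabs(mass_prev - mass - absorbed);
      if (imbal > max_imbal) max_imbal = imbal;
    }
    mass_prev = mass;
  }

  return List::create(_["g_upper"] = g_up, _["g_lower"] = g_low,
                      _["mass_interior"] = mass_prev,
                      _["max_step_imbalance"] = max_imbal,
                      _["dx"] = dx);
}

// Euler-Maruyama first-passage simulator with Brownian-bridge crossing
// correction; serves as an independent stochastic oracle for the PDE route.
// drift holds mu(t_n) for n = 0..nsteps-1. Paths start at 0 between
// absorbing boundaries at +-b. Returns decision times and boundaries
// (+1 upper, -1 lower, 0 censored at the horizon). Uses R's RNG.

// [[Rcpp::export]]
List em_simulate(NumericVector drift, double b, double sigma,
                 double dt, int n_paths, bool bridge) {
  const int nsteps = drift.size();
  NumericVector rt(n_paths);
  IntegerVector boundary(n_paths);
  const double sdt = sigma * std::sqrt(dt);
  const double inv = 1.0 / (sigma * sigma * dt);
  RNGScope scope;

  for (int p = 0; p < n_paths; ++p) {
    double x = 0.0;
    int hit = 0;
    double t_hit = nsteps * dt;
    for (int n = 0; n < nsteps; ++n) {
      const double xn = x + drift[n] * dt + sdt * norm_rand();
      if (xn >= b)       { hit = 1;  t_hit = (n + 1) * dt; break; }
      else if (xn <= -b) { hit = -1; t_hit = (n + 1) * dt; break; }
      if (bridge) {
        const double pu = std::exp(-2.0 * (b - x) * (b - xn) * inv);
        const double pl = std::exp(-2.0 * (b + x) * (b + xn) * inv);
        const double u = unif_rand();
        if (u < pu)           { hit = 1;  t_hit = (n + 0.5) * dt; break; }
        else if (u < pu + pl) { hit = -1; t_hit = (n + 0.5) * dt; break; }
      }
      x = xn;
    }
    rt[p] = t_hit;
    boundary[p] = hit;
  }
  return List::create(_["rt"] = rt, _["boundary"] = boundary);
}

// sparse shift-convolution: out[t] = sum_i w[i] * g[t - j[i]]
// (the discrete uniform non-decision kernel applied to one branch)

// [[Rcpp::export]]
NumericVector shift_convolve_cpp(NumericVector g, IntegerVector j,
                                 NumericVector w) {
  const int n = g.size(), m = j.size();
  NumericVector out(n);
  for (int i = 0; i < m; ++i) {
    const int s = j[i];
    const double wi = w[i];
    for (int t = s; t < n; ++t) out[t] += wi * g[t - s];
  }
  return out;
}
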