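#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Crank-Nicolson forward solver for the Fokker-Planck equation
//
//   dp/dt = -v dp/dx + (1/2) d2p/dx2          (diffusion coefficient = 1)
//
// on a fixed spatial grid over [-a, a], with absorbing boundaries that
// collapse exponentially, b(t) = a * exp(-tau * t).  Collapse is handled by
// masking grid nodes outside the current bound and harvesting their mass as
// boundary flux; absorption through an active boundary is accounted as the
// per-step mass deficit of the conservative interior update, split between
// the two ends in proportion to the one-sided boundary fluxes.  This keeps
// total probability (upper + lower + undecided) conserved to machine
// precision before the final non-negativity clamp.
//
// The first few steps use a fully implicit update (Rannacher start-up) to
// damp the oscillations Crank-Nicolson produces from the delta initial
// condition.  The implicit tridiagonal system is Toeplitz and constant in
// time, so its forward-elimination coefficients are prefactored once per
// theta value; the per-step solve then needs no divisions.
//
// Returns flux densities at time-cell midpoints t_n = (n - 1/2) dt.

struct ThomasFactor {
  // prefactored forward elimination for the Toeplitz tridiagonal
  // [Al, Ad, Au]; cp[i] and inv_m[i] depend only on the offset from the
  // start of the active window, not on the window's length
  std::vector<double> cp, inv_m;
  double Al, Au;
  void factor(int n, double Al_, double Ad_, double Au_) {
    Al = Al_; Au = Au_;
    cp.resize(n); inv_m.resize(n);
    inv_m[0] = 1.0 / Ad_;
    cp[0] = Au_ * inv_m[0];
    for (int i = 1; i < n; ++i) {
      inv_m[i] = 1.0 / (Ad_ - Al_ * cp[i - 1]);
      cp[i] = Au_ * inv_m[i];
    }
  }
};

// [[Rcpp::export]]
List fptd_solve_cpp(double v, double a, double tau, double z,
                    double dt, double dx, double t_max) {
  if (dt <= 0 || dx <= 0 || t_max <= 0)
    stop("dt, dx and t_max must all be positive");
  if (a <= 0) stop("threshold 'a' must be positive");
  if (tau < 0) stop("collapse rate 'tau' must be non-negative");
  if (std::fabs(z) >= 1) stop("|z| must be < 1");

  const int N = std::max(4, (int)std::lround(2.0 * a / dx)); // nodes 0..N
  const double h = 2.0 * a / N;                              // actual spacing
  const int M = std::max(1, (int)std::lround(t_max / dt));

  const double x0 = z * a;
  if (x0 <= -a + h || x0 >= a - h)
    stop("starting point lies within one grid cell of a bound; refine dx");

  // density on interior nodes x_j = -a + j*h, j = 1..N-1
  std::vector<double> p(N + 1, 0.0), dp(N + 1, 0.0), rhs(N + 1, 0.0);
  {
    int j = (int)std::floor((x0 + a) / h);
    double w = (x0 + a) / h - j;        // linear split of the unit delta
    p[j]     += (1.0 - w) / h;
    p[j + 1] += w / h;
  }

  const double D = 0.5;                  // sigma^2 / 2 with sigma = 1
  const double alpha = D / (h * h);
  const double beta  = v / (2.0 * h);
  // L p_j = (alpha + beta) p_{j-1} - 2 alpha p_j + (alpha - beta) p_{j+1}
  const double cl = alpha + beta, cd = -2.0 * alpha, cu = alpha - beta;

  const int n_rannacher = 4;
  ThomasFactor fac_be, fac_cn;           // backward Euler and CN factors
  fac_be.factor(N, -1.0 * dt * cl, 1.0 - 1.0 * dt * cd, -1.0 * dt * cu);
  fac_cn.factor(N, -0.5 * dt * cl, 1.0 - 0.5 * dt * cd, -0.5 * dt * cu);

  NumericVector t_mid(M), up_dens(M), lo_dens(M);
  double up_mass = 0.0, lo_mass = 0.0;
  int lo_i = 1, hi_i = N - 1;            // active interior range

  for (int n = 0; n < M; ++n) {
    const double t1 = (n + 1) * dt;
    const bool be = n < n_rannacher;
    const double theta = be ? 1.0 : 0.5;
    const ThomasFactor& F = be ? fac_be : fac_cn;
    double step_up = 0.0, step_lo = 0.0;

    // shrink the active window to the bound at the end of the step,
    // harvesting the mass of newly excluded nodes
    const double b = a * std::exp(-tau * t1);
    while (lo_i <= hi_i && (-a + lo_i * h) <= -b) {
      step_lo += p[lo_i] * h; p[lo_i] = 0.0; ++lo_i;
    }
    while (hi_i >= lo_i && (-a + hi_i * h) >= b) {
      step_up += p[hi_i] * h; p[hi_i] = 0.0; --hi_i;
    }

    if (hi_i >= lo_i) {
      const int m = hi_i - lo_i + 1;
      double mass0 = 0.0;
      const double g = (1.0 - theta) * dt;
      // rhs = (I + (1-theta) dt L) p with Dirichlet 0 outside the window,
      // fused with the division-free Thomas forward sweep
      {
        const double pj = p[lo_i];
        const double pu = (m > 1) ? p[lo_i + 1] : 0.0;
        mass0 += pj;
        rhs[0] = pj + g * (cd * pj + cu * pu);
        dp[0] = rhs[0] * F.inv_m[0];
      }
      for (int k = 1; k < m; ++k) {
        const double pj = p[lo_i + k];
        const double pl = p[lo_i + k - 1];
        const double pu = (k < m - 1) ? p[lo_i + k + 1] : 0.0;
        mass0 += pj;
        const double r = pj + g * (cl * pl + cd * pj + cu * pu);
        dp[k] = (r - F.Al * dp[k - 1]) * F.inv_m[k];
      }
      mass0 *= h;
      const double p_lo_edge = p[lo_i], p_hi_edge = p[hi_i];
      // back substitution
      p[lo_i + m - 1] = dp[m - 1];
      double mass1 = dp[m - 1];
      for (int k = m - 2; k >= 0; --k) {
        const double x = dp[k] - F.cp[k] * p[lo_i + k + 1];
        p[lo_i + k] = x;
        mass1 += x;
      }
      mass1 *= h;

      double deficit = mass0 - mass1;
      if (deficit > 0) {
        // one-sided boundary fluxes (diffusive + upwind advective), used
        // only to split the absorbed mass between the two ends
        double f_up = D * (p_hi_edge + p[hi_i]) * 0.5 / h +
                      std::max(v, 0.0) * (p_hi_edge + p[hi_i]) * 0.5;
        double f_lo = D * (p_lo_edge + p[lo_i]) * 0.5 / h +
                      std::max(-v, 0.0) * (p_lo_edge + p[lo_i]) * 0.5;
        double fsum = f_up + f_lo;
        double w_up = (fsum > 0) ? f_up / fsum : 0.5;
        step_up += deficit * w_up;
        step_lo += deficit * (1.0 - w_up);
      }
    }

    t_mid[n] = (n + 0.5) * dt;
    up_dens[n] = step_up / dt;
    lo_dens[n] = step_lo / dt;
    up_mass += step_up;
    lo_mass += step_lo;

    // once essentially all mass is absorbed the remaining densities are
    // zero; stop stepping (the residual goes to the undecided account)
    if (1.0 - up_mass - lo_mass < 1e-12) {
      for (int nn = n + 1; nn < M; ++nn) t_mid[nn] = (nn + 0.5) * dt;
      break;
    }
  }

  // clamp stray negative densities (tiny CN oscillations)
  double undecided = 0.0;
  for (int j = lo_i; j <= hi_i && hi_i >= lo_i; ++j) {
    if (p[j] < 0) p[j] = 0;
    undecided += p[j] * h;
  }
  for (int n = 0; n < M; ++n) {
    if (up_dens[n] < 0) up_dens[n] = 0;
    if (lo_dens[n] < 0) lo_dens[n] = 0;
  }

  return List::create(_["time"] = t_mid,
                      _["upper"] = up_dens,
                      _["lower"] = lo_dens,
                      _["p_upper"] = up_mass,
                      _["p_lower"] = lo_mass,
                      _["undecided"] = undecided,
                      _["dt"] = dt, _["dx"] = h, _["t_max"] = t_max);
}

// Summed log-likelihood of (choice, decision-time) trials over the 12
// mask-by-emotion cells, evaluated in one pass: for each cell the FPTD is
// solved and the appropriate density is linearly interpolated at each
// trial's rt - Ter.  Equivalent to summing trial_loglik() over cells; kept
// in C++ because it sits in the optimizer's inner loop.
//
// cell_v, cell_z, cell_ter: per-cell engine parameters (length n_cells);
// trial_cell: 0-based cell index per trial; trial_upper: 1 if the trial
// ended at the upper ('unfriendly') bound; trial_rt: response times (s).
// [[Rcpp::export]]
double cells_negloglik_cpp(NumericVector cell_v, NumericVector cell_z,
                           NumericVector cell_ter,
                           double a, double tau,
                           IntegerVector trial_cell,
                           IntegerVector trial_upper,
                           NumericVector trial_rt,
                           double dt, double dx, double t_max,
                           double floor_dens) {
  const int n_cells = cell_v.size();
  const int n_tr = trial_rt.size();
  double nll = 0.0;
  for (int c = 0; c < n_cells; ++c) {
    List f = fptd_solve_cpp(cell_v[c], a, tau, cell_z[c], dt, dx, t_max);
    NumericVector tg = f["time"], up = f["upper"], lo = f["lower"];
    const int M = tg.size();
    const double t0 = tg[0];
    for (int i = 0; i < n_tr; ++i) {
      if (trial_cell[i] != c) continue;
      const double td = trial_rt[i] - cell_ter[c];
      double dens = 0.0;
      if (td > 0) {
        const NumericVector& d = trial_upper[i] ? up : lo;
        const double u = (td - t0) / dt;
        if (u >= 0 && u < M - 1) {
          const int j = (int)u;
          const double w = u - j;
          dens = (1 - w) * d[j] + w * d[j + 1];
        }
      }
      nll -= std::log(std::max(dens, floor_dens));
    }
  }
  return nll;
}

// Euler-Maruyama paths with exponentially collapsing absorbing bounds.
// choice: +1 upper ('unfriendly'), -1 lower ('friendly'), 0 miss.
//
// Besides the endpoint test, each step applies the Brownian-bridge
// crossing probability exp(-2 (b0 - x0)(b1 - x1) / dt) against the
// (linearly interpolated) bound, which removes the O(sqrt(dt)) barrier
// under-detection bias of the plain Euler scheme.  Crossings detected by
// the bridge are stamped at the step midpoint.
//
// Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
List sim_paths_cpp(int n, double v, double a, double tau, double z,
                   double dt, double t_dec_max) {
  if (dt <= 0) stop("step size must be positive");
  if (a <= 0 || std::fabs(z) >= 1) stop("invalid parameters");
  const long long max_steps = (long long)std::ceil(t_dec_max / dt);
  IntegerVector choice(n);
  NumericVector dtime(n);
  const double sq = std::sqrt(dt);
  for (int i = 0; i < n; ++i) {
    double x = z * a, t = 0.0;
    double b_prev = a;
    int ch = 0; double td = NA_REAL;
    for (long long s = 1; s <= max_steps; ++s) {
      const double x_prev = x;
      x += v * dt + sq * norm_rand();
      t = s * dt;
      const double b = a * std::exp(-tau * t);
      if (x >= b)       { ch = 1;  td = t; break; }
      else if (x <= -b) { ch = -1; td = t; break; }
      // interior endpoints: bridge test against both (moving) barriers
      const double pu = std::exp(-2.0 * (b_prev - x_prev) * (b - x) / dt);
      if (unif_rand() < pu) { ch = 1; td = t - 0.5 * dt; break; }
      const double pl = std::exp(-2.0 * (x_prev + b_prev) * (x + b) / dt);
      if (unif_rand() < pl) { ch = -1; td = t - 0.5 * dt; break; }
      b_prev = b;
    }
    choice[i] = ch;
    dtime[i] = td;
  }
  return List::create(_["choice"] = choice, _["dtime"] = dtime);
}
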