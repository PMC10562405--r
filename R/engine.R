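#' Engine configuration
#'
#' Numerical settings of the first-passage-time solver.  Defaults: 5 ms time
#' step, 5e-3 evidence-unit spatial step, 2.3 s horizon (the response
#' deadline), Crank-Nicolson stepping with an implicit start-up.
#'
#' @param dt time step, seconds (> 0).
#' @param dx spatial step, evidence units (> 0).
#' @param t_max solution horizon, seconds (> 0).
#' @return An object of class `engine_config`.
#' @export
engine_config <- function(dt = 0.005, dx = 0.005, t_max = 2.3) {
  if (!is.numeric(dt) || dt <= 0) stop("configuration error: dt must be > 0")
  if (!is.numeric(dx) || dx <= 0) stop("configuration error: dx must be > 0")
  if (!is.numeric(t_max) || t_max <= 0)
    stop("configuration error: t_max must be > 0")
  structure(list(dt = dt, dx = dx, t_max = t_max), class = "engine_config")
}

#' Exponentially collapsing decision bound
#'
#' The (upper) decision threshold at time `t`: `a * exp(-tau * t)`.  The
#' lower threshold is its mirror image.
#'
#' @param a initial threshold (> 0).
#' @param tau collapse rate, 1/s (>= 0); `tau = 0` gives a constant bound.
#' @param t time(s) since stimulus onset minus non-decision time, seconds.
#' @return Threshold value(s) at `t`.
#' @export
bound_at <- function(a, tau, t) {
  stopifnot(a > 0, tau >= 0, all(t >= 0))
  a * exp(-tau * t)
}

#' First-passage-time densities for the collapsing-bound diffusion
#'
#' Forward-evolves the evidence density under drift `v` and unit diffusion
#' between absorbing bounds at `+/- a * exp(-tau t)`, starting from a point
#' mass at `z * a`, and returns the probability flux through each bound.
#' Densities are reported at time-cell midpoints; their integrals plus the
#' undecided mass at `t_max` sum to 1 up to solver tolerance.
#'
#' @param v drift rate.
#' @param a initial threshold (> 0).
#' @param tau bound collapse rate (>= 0).
#' @param z starting point as signed fraction of `a`, |z| < 1.
#' @param config an [engine_config()].
#' @return An object of class `fptd`: list with `time`, `upper`, `lower`
#'   (densities per second), `p_upper`, `p_lower`, `undecided`, and the grid
#'   settings.
#' @export
solve_fptd <- function(v, a, tau, z, config = engine_config()) {
  stopifnot(inherits(config, "engine_config"))
  out <- fptd_solve_cpp(v, a, tau, z, config$dt, config$dx, config$t_max)
  structure(out, class = "fptd")
}

#' Analytic first-passage densities for constant bounds (testing oracle)
#'
#' Classical eigenfunction (large-time) series for the first-passage-time
#' density of a drifted Wiener process between two constant absorbing
#' barriers at `+/- a`, starting at `z * a`.  Used as an independent check
#' of [solve_fptd()] in the `tau = 0` case; the series is truncated when the
#' envelope of the remainder falls below `tol`.
#'
#' @param v drift rate.
#' @param a threshold (> 0), constant in time.
#' @param z starting fraction, |z| < 1.
#' @param t_grid times (s) at which to evaluate the densities (> 0).
#' @param tol truncation tolerance for the series remainder.
#' @param max_terms error out if more than this many terms are needed.
#' @return An `fptd`-like list with `time`, `upper`, `lower`, `p_upper`,
#'   `p_lower`.
#' @export
fptd_analytic <- function(v, a, z, t_grid, tol = 1e-10, max_terms = 1e5) {
  stopifnot(a > 0, abs(z) < 1, all(t_grid > 0))
  A <- 2 * a                       # barrier separation
  w <- (z + 1) * a                 # distance of start from the lower barrier
  mu <- v
  dens_one_side <- function(w, mu, t) {
    # density of absorption at the barrier a distance w below the start
    # (lower barrier); t vectorized
    lam <- pi^2 / (2 * A^2)
    tmin <- min(t)
    K <- ceiling(sqrt(max(1, -log(tol) / (lam * tmin))))
    if (K > max_terms)
      stop("analytic series does not converge at requested tolerance")
    k <- seq_len(K)
    S <- outer(t, k, function(tt, kk)
      kk * sin(pi * kk * w / A) * exp(-kk^2 * lam * tt))
    (pi / A^2) * exp(-mu * w - mu^2 * t / 2) * rowSums(S)
  }
  lower <- dens_one_side(w, mu, t_grid)
  upper <- dens_one_side(A - w, -mu, t_grid)
  p_up <- absorption_prob_upper(v, a, z)
  list(time = t_grid, upper = pmax(upper, 0), lower = pmax(lower, 0),
       p_upper = p_up, p_lower = 1 - p_up)
}

#' Closed-form absorption probability at the upper barrier (constant bounds)
#'
#' For a Wiener process with drift `v` and unit diffusion between constant
#' barriers `+/- a` started at `z * a`:
#' `P(upper) = (1 - exp(-2 v w)) / (1 - exp(-2 v A))` with `w = (z + 1) a`,
#' `A = 2 a`; the zero-drift limit is `w / A`.
#'
#' @inheritParams fptd_analytic
#' @return Probability of absorption at the upper barrier.
#' @export
absorption_prob_upper <- function(v, a, z) {
  stopifnot(a > 0, abs(z) < 1)
  w <- (z + 1) * a
  A <- 2 * a
  if (abs(v) < 1e-12) return(w / A)
  expm1(-2 * v * w) / expm1(-2 * v * A)
}

#' Log-likelihood of observed (choice, RT) trials under a solved FPTD
#'
#' Interpolates the appropriate first-passage density at the decision time
#' `rt - Ter` for each trial.  Densities below the floor (including RTs at
#' or before `Ter`, or beyond the solution horizon) are scored at the floor
#' value rather than -Inf; undecided mass is never scored (missed trials are
#' excluded upstream).
#'
#' @param fptd an object from [solve_fptd()].
#' @param Ter non-decision time, seconds.
#' @param choice character vector, `"unfriendly"` (upper) or `"friendly"`
#'   (lower); misses are not allowed here.
#' @param rt response times, seconds, measured from stimulus onset.
#' @param floor minimum density per second used in place of smaller or
#'   out-of-support values.
#' @return Vector of per-trial log-densities.
#' @export
trial_loglik <- function(fptd, Ter, choice, rt, floor = 1e-10) {
  stopifnot(length(choice) == length(rt))
  if (any(choice == "miss")) stop("missed trials cannot be scored")
  td <- rt - Ter
  dens <- numeric(length(rt))
  up <- choice == "unfriendly"
  if (any(up))
    dens[up] <- approx(fptd$time, fptd$upper, xout = td[up],
                       yleft = 0, yright = 0)$y
  if (any(!up))
    dens[!up] <- approx(fptd$time, fptd$lower, xout = td[!up],
                        yleft = 0, yright = 0)$y
  dens[td <= 0] <- 0
  log(pmax(dens, floor))
}
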