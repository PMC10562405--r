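test_that("the collapsing bound evaluates exactly", {
  expect_equal(bound_at(1.08, 1.29, 0), 1.08)
  expect_equal(bound_at(1.08, 1.29, 1.0), 1.08 * exp(-1.29),
               tolerance = 1e-12)
  expect_equal(bound_at(1.08, 1.29, 1.0), 0.297, tolerance = 1e-3)
  expect_equal(bound_at(2, 0, c(0, 5, 50)), c(2, 2, 2))
  expect_error(bound_at(-1, 0, 0))
})

test_that("unbiased symmetric diffusion splits evenly between bounds", {
  f <- solve_fptd(0, 1, 0, 0)
  expect_equal(f$p_upper, f$p_lower, tolerance = 1e-10)
  expect_equal(f$upper, f$lower, tolerance = 1e-10)
  expect_true(all(f$upper >= 0) && all(f$lower >= 0))
})

test_that("absorption probabilities match the closed form", {
  # v=1, constant bounds +/-0.5: P(upper) = 1/(1+exp(-2*1*0.5))
  f <- solve_fptd(1, 0.5, 0, 0)
  expect_lt(f$undecided, 1e-5)
  expect_lt(abs(f$p_upper - 1 / (1 + exp(-1))), 2e-3)
  # drifted, off-center start
  f2 <- solve_fptd(2, 0.8, 0, 0.2)
  expect_lt(abs(f2$p_upper - absorption_prob_upper(2, 0.8, 0.2)), 2e-3)
})

test_that("zero-drift mean first-passage time equals a squared", {
  cfg <- engine_config(t_max = 12)
  f <- solve_fptd(0, 1, 0, 0, cfg)
  m <- sum(f$time * (f$upper + f$lower)) * cfg$dt
  expect_lt(abs(m - 1.0), 5e-3)
})

test_that("probability is conserved across the parameter range", {
  grid <- expand.grid(v = c(-2, 0, 3.5), a = c(0.6, 1.08, 2),
                      tau = c(0, 1.29, 5), z = c(-0.4, 0, 0.3))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    f <- solve_fptd(g$v, g$a, g$tau, g$z)
    total <- f$p_upper + f$p_lower + f$undecided
    expect_lt(abs(total - 1), 1e-3)
    expect_true(all(f$upper >= 0) && all(f$lower >= 0))
  }
})

test_that("upper-bound mass is monotone in drift and start point", {
  cfg <- engine_config()
  p_by_v <- vapply(c(-2, -1, 0, 1, 2), function(v)
    solve_fptd(v, 1.08, 1.29, 0, cfg)$p_upper, numeric(1))
  expect_true(all(diff(p_by_v) > 0))
  p_by_z <- vapply(c(-0.6, -0.2, 0, 0.2, 0.6), function(z)
    solve_fptd(0.5, 1.08, 1.29, z, cfg)$p_upper, numeric(1))
  expect_true(all(diff(p_by_z) > 0))
})

test_that("solver converges under grid refinement", {
  base <- solve_fptd(1.5, 1.08, 1.29, 0.1, engine_config())
  half <- solve_fptd(1.5, 1.08, 1.29, 0.1,
                     engine_config(dt = 0.0025, dx = 0.0025))
  expect_lt(abs(base$p_upper - half$p_upper), 5e-3)
})

test_that("solver matches the analytic constant-bound series", {
  cfg <- engine_config(dt = 0.001, dx = 0.001)
  cases <- list(c(0, 1, 0), c(1, 0.5, 0), c(2, 0.8, 0.2),
                c(-1.5, 1.2, -0.3))
  for (cs in cases) {
    f <- solve_fptd(cs[1], cs[2], 0, cs[3], cfg)
    an <- fptd_analytic(cs[1], cs[2], cs[3], f$time)
    expect_lt(max(abs(f$upper - an$upper)), 0.02)
    expect_lt(max(abs(f$lower - an$lower)), 0.02)
  }
  # starting near the upper threshold: nearly all mass leaves upward, fast
  fz <- solve_fptd(0, 1, 0, 0.95, engine_config(t_max = 12))
  expect_gt(fz$p_upper, 0.95)
  mean_up <- sum(fz$time * fz$upper) * 0.005 / fz$p_upper
  expect_lt(mean_up, 0.25)
})

test_that("analytic series errors out when it cannot converge", {
  expect_error(fptd_analytic(0, 1, 0, t_grid = 1e-9, max_terms = 100L),
               "converge")
})

test_that("degenerate grids and starts are rejected", {
  expect_error(engine_config(dt = 0), "configuration")
  expect_error(engine_config(dx = -1), "configuration")
  expect_error(solve_fptd(0, 1, 0, 0.9999, engine_config()), "grid cell")
})

test_that("trial log-likelihood interpolates densities with a floor", {
  f <- solve_fptd(0, 1, 0, 0)
  # symmetric null case scores both choices identically
  ll_up <- trial_loglik(f, 0.3, "unfriendly", 0.8)
  ll_lo <- trial_loglik(f, 0.3, "friendly", 0.8)
  expect_equal(ll_up, ll_lo, tolerance = 1e-10)
  # out-of-support RTs hit the floor, not -Inf
  expect_equal(trial_loglik(f, 0.3, "unfriendly", 0.29), log(1e-10))
  expect_equal(trial_loglik(f, 0.3, "friendly", 99), log(1e-10))
  expect_error(trial_loglik(f, 0.3, "miss", 1.0), "missed")
})

test_that("the C++ cell scorer agrees with trial_loglik summation", {
  p <- group_mean_params()
  tr <- small_dataset(40L, seed = 5L)
  prep <- maskddm:::prepare_cells(tr)
  eng <- engine_config()
  nll_cpp <- maskddm:::negloglik_theta(unclass(p), prep, eng)
  nll_r <- 0
  for (C in c(0L, 1L)) {
    for (k in main_emotion_levels()) {
      sel <- tr$mask == C & tr$emotion == k
      f <- solve_fptd(drift_rate(p, k / 100, C), p[["a"]], p[["tau"]],
                      start_point(p, C), eng)
      nll_r <- nll_r - sum(trial_loglik(f, nondecision(p, C),
                                        tr$choice[sel], tr$rt_s[sel]))
    }
  }
  expect_equal(nll_cpp, nll_r, tolerance = 1e-8)
})

test_that("the generating parameters outscore a perturbed drift at scale", {
  p <- group_mean_params()
  tr <- small_dataset(300L, seed = 8L)
  prep <- maskddm:::prepare_cells(tr)
  eng <- engine_config()
  nll_truth <- maskddm:::negloglik_theta(unclass(p), prep, eng)
  perturbed <- unclass(p)
  perturbed["vslope0"] <- perturbed["vslope0"] * 1.3
  expect_lt(nll_truth, maskddm:::negloglik_theta(perturbed, prep, eng))
})
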