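test_that("RT preprocessing removes only extreme log-RTs per cell", {
  # a cell of identical RTs: SD = 0, nothing removed
  tr <- data.frame(participant = "p1", block = 1L, mask = 0L, emotion = 10L,
                   filler = FALSE, choice = "unfriendly", rt_s = 0.5)
  tr <- tr[rep(1, 20), ]
  out <- preprocess_rt(tr)
  expect_true(all(out$valid))
  expect_equal(attr(out, "removal_fraction"), 0)

  # log-normal RTs at large n: ~0.27% beyond 3 SD
  set.seed(31)
  n <- 40000
  tr2 <- data.frame(participant = "p1", block = 1L, mask = 0L,
                    emotion = 10L, filler = FALSE, choice = "unfriendly",
                    rt_s = exp(rnorm(n, -0.6, 0.25)))
  out2 <- preprocess_rt(tr2)
  expect_lt(abs(attr(out2, "removal_fraction") - 2 * pnorm(-3)), 1.5e-3)

  # misses never get a valid flag
  tr3 <- rbind(tr, data.frame(participant = "p1", block = 1L, mask = 0L,
                              emotion = 10L, filler = FALSE,
                              choice = "miss", rt_s = NA_real_))
  expect_false(preprocess_rt(tr3)$valid[21])
})

test_that("psychometric fits recover generating parameters", {
  # unbiased, insensitive observer: flat at 0.5
  d0 <- simulate_psychometric(6000, b0 = 0, b1 = 0, seed = 32)
  f0 <- fit_psychometric(d0, "unmasked")
  expect_lt(abs(f0$b0), 0.1)
  expect_lt(abs(f0$b1), 0.3)

  # the reported masked-condition medians, recovered from generated data
  d1 <- simulate_psychometric(10000, b0 = -0.22, b1 = 6.47, seed = 33)
  f1 <- fit_psychometric(d1, "unmasked")
  expect_lt(abs(f1$b1 - 6.47), 6.47 * 0.05)
  expect_lt(abs(f1$b0 - -0.22), 0.08)
  expect_equal(f1$df, 4L)

  # the logistic at S = 0 under the reported masked bias
  expect_lt(abs(psychometric_p(-0.22, 6.47, 0) - 0.4452), 1e-4)
  expect_equal(psychometric_p(-0.22, 6.47, 0), plogis(-0.22),
               tolerance = 1e-12)
})

test_that("separation is flagged and the slope bounded", {
  d <- simulate_psychometric(200, b0 = 0, b1 = 60, seed = 34)
  d$choice <- ifelse(d$emotion > 0, "unfriendly", "friendly")
  f <- fit_psychometric(d, "unmasked")
  expect_true(f$separation)
  expect_lte(abs(f$b1), 50)
})

test_that("deviance exclusion operates near the nominal 5% rate", {
  set.seed(35)
  excluded <- vapply(1:300, function(i) {
    d <- simulate_psychometric(600, b0 = 0.2, b1 = 8,
                               seed = 35000 + i)
    fit_psychometric(d, "unmasked")$excluded
  }, logical(1))
  expect_lt(abs(mean(excluded) - 0.05), 0.045)
})

test_that("cohort bias/sensitivity summaries behave", {
  # symmetric bias values around zero: no significant bias, median ~ 0
  set.seed(36)
  mk <- function(b0m, b1m, b0u, b1u) list(
    masked = structure(list(b0 = b0m, b1 = b1m, excluded = FALSE),
                       class = "psychometric_fit"),
    unmasked = structure(list(b0 = b0u, b1 = b1u, excluded = FALSE),
                         class = "psychometric_fit"))
  eps <- c(-0.3, -0.2, -0.1, 0.1, 0.2, 0.3)
  fits <- lapply(eps, function(e) mk(e, 6 + e, -e, 10 - e))
  out <- bias_and_sensitivity_tests(fits)
  expect_equal(out$medians$b0_median, c(0, 0))
  expect_gt(out$tests$p[out$tests$test == "b0_masked_vs_0"], 0.05)
  # masked sensitivity clearly below unmasked
  expect_lt(out$medians$b1_median[1], out$medians$b1_median[2])
  expect_lt(out$tests$p[out$tests$test == "b1_masked_vs_unmasked"], 0.05)
  # invariance to participant ordering
  out2 <- bias_and_sensitivity_tests(rev(fits))
  expect_equal(out$medians, out2$medians)
})

test_that("a synthetic cohort shows the mask signatures in descriptives", {
  co <- simulate_cohort(cohort_spec(4L, sds = setNames(rep(0, 10),
                                                       ddm_param_names()),
                                    seed = 37L))
  pre <- lapply(co$trials, preprocess_rt)
  fits <- lapply(pre, function(tr) list(
    masked = fit_psychometric(tr, "masked"),
    unmasked = fit_psychometric(tr, "unmasked")))
  out <- bias_and_sensitivity_tests(fits)
  # vslopemask < 0 implies a shallower masked psychometric slope
  expect_lt(out$medians$b1_median[out$medians$condition == "masked"],
            out$medians$b1_median[out$medians$condition == "unmasked"])

  med <- condition_medians(do.call(rbind, pre))
  coh <- med$cohort
  # masked responses are slower at matched |k| (Termask > 0, flatter
  # slope); at the most ambiguous levels the model-implied gap (~24 ms)
  # is within cohort noise, so assert cell-wise only where it is large
  for (k in c(-60L, -40L, 40L, 60L)) {
    expect_gt(coh$mean_of_medians[coh$mask == 1 & coh$emotion == k],
              coh$mean_of_medians[coh$mask == 0 & coh$emotion == k])
  }
  expect_gt(mean(coh$mean_of_medians[coh$mask == 1]),
            mean(coh$mean_of_medians[coh$mask == 0]))
})

test_that("cell medians are within the range of their trials", {
  tr <- small_dataset(25L, seed = 38L)
  tr$valid <- TRUE
  med <- condition_medians(tr)
  for (i in seq_len(nrow(med$per_participant))) {
    row <- med$per_participant[i, ]
    cell <- tr$rt_s[tr$mask == row$mask & tr$emotion == row$emotion]
    expect_gte(row$median_rt, min(cell))
    expect_lte(row$median_rt, max(cell))
  }
  # single-trial cell: the median is that trial
  one <- data.frame(participant = "x", mask = 0L, emotion = 10L,
                    filler = FALSE, choice = "friendly", rt_s = 0.77)
  expect_equal(condition_medians(one)$per_participant$median_rt, 0.77)
})
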