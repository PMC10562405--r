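#' Response-time preprocessing
#'
#' Flags analyzable trials.  Misses are excluded outright; within each
#' mask-by-emotion cell, response times are log-transformed and trials more
#' than three standard deviations from the cell's mean log-RT are flagged
#' invalid.  Cells with fewer than two finite RTs (SD undefined or zero)
#' are left untouched; empty cells raise a warning.
#'
#' @param trials raw trial record data.frame (`mask`, `emotion`, `choice`,
#'   `rt_s`; one participant or several, processed per participant when a
#'   `participant` column is present).
#' @param n_sd cut in SD units on the log scale (default 3).
#' @return The input with a logical `valid` column and attribute
#'   `removal_fraction` (fraction of non-miss trials flagged invalid).
#' @export
preprocess_rt <- function(trials, n_sd = 3) {
  split_by <- if ("participant" %in% names(trials))
    trials$participant else rep("all", nrow(trials))
  valid <- rep(FALSE, nrow(trials))
  for (pid in unique(split_by)) {
    rows <- which(split_by == pid)
    sub <- trials[rows, , drop = FALSE]
    ok <- sub$choice != "miss" & is.finite(sub$rt_s)
    cell <- interaction(sub$mask, sub$emotion, drop = TRUE)
    for (cl in levels(cell)) {
      in_cell <- cell == cl & ok
      if (!any(in_cell)) {
        warning("empty cell ", cl, " for participant ", pid)
        next
      }
      lrt <- log(sub$rt_s[in_cell])
      if (sum(in_cell) < 2 || sd(lrt) == 0) {
        valid[rows[in_cell]] <- TRUE
        next
      }
      keep <- abs(lrt - mean(lrt)) <= n_sd * sd(lrt)
      valid[rows[in_cell]] <- keep
    }
  }
  out <- trials
  out$valid <- valid
  n_scored <- sum(trials$choice != "miss")
  attr(out, "removal_fraction") <-
    if (n_scored) 1 - sum(valid) / n_scored else NA_real_
  out
}

#' Psychometric (logistic) fit of choice data
#'
#' Fits the two-parameter logistic
#' `p(unfriendly) = 1 / (1 + exp(-(b0 + b1 S)))` to one condition's choices
#' by binomial maximum likelihood on per-level counts, where `S` is the
#' stimulus emotion as a fraction (-0.60..0.60).  `b0` is the
#' emotion-independent choice bias and `b1` the sensitivity.  The residual
#' deviance against the per-level saturated model, on
#' `(number of S levels - 2)` degrees of freedom, flags participants whose
#' choices the logistic cannot describe: `excluded` is TRUE when the
#' deviance exceeds the chi-square 0.95 quantile for its df.
#'
#' @param trials trial records for one participant.
#' @param condition `"masked"` or `"unmasked"`.
#' @param include_fillers include the +/-20 filler levels (default FALSE).
#' @return A list of class `psychometric_fit`: `b0`, `b1`, `deviance`,
#'   `df`, `excluded`, `separation` (TRUE when the fit is degenerate and
#'   the slope was bounded), `condition`, `n_trials`.
#' @export
fit_psychometric <- function(trials, condition = c("unmasked", "masked"),
                             include_fillers = FALSE) {
  condition <- match.arg(condition)
  C <- if (condition == "masked") 1L else 0L
  keep <- trials$mask == C & trials$choice != "miss"
  if (!include_fillers) keep <- keep & !trials$filler
  if ("valid" %in% names(trials)) keep <- keep & trials$valid
  tr <- trials[keep, , drop = FALSE]
  if (!nrow(tr)) stop("no analyzable trials in the ", condition, " condition")
  y <- as.integer(tr$choice == "unfriendly")
  S <- tr$emotion / 100
  counts <- aggregate(cbind(unfriendly = y, friendly = 1 - y),
                      by = list(S = S), FUN = sum)
  fit <- suppressWarnings(
    glm(cbind(unfriendly, friendly) ~ S, family = binomial(), data = counts))
  b <- coef(fit)
  separation <- !fit$converged || abs(b[2]) > 50
  if (separation) b[2] <- sign(b[2]) * min(abs(b[2]), 50)
  df <- nrow(counts) - 2L
  dev <- fit$deviance
  structure(list(b0 = unname(b[1]), b1 = unname(b[2]), deviance = dev,
                 df = df,
                 excluded = df > 0 && dev > qchisq(0.95, df),
                 separation = separation, condition = condition,
                 n_trials = nrow(tr)),
            class = "psychometric_fit")
}

#' Evaluate the logistic psychometric function
#'
#' @param b0 bias (logit units).
#' @param b1 sensitivity (logit units per unit emotion fraction).
#' @param S stimulus emotion fraction(s).
#' @return Probability of an 'unfriendly' choice.
#' @export
psychometric_p <- function(b0, b1, S) 1 / (1 + exp(-(b0 + b1 * S)))

#' Generate Bernoulli choices from the psychometric function
#'
#' @inheritParams psychometric_p
#' @param n number of trials.
#' @param S_levels emotion fractions sampled uniformly per trial.
#' @param seed integer seed.
#' @return A trial record data.frame usable with [fit_psychometric()]
#'   (all trials unmasked, `rt_s` set to NA).
#' @export
simulate_psychometric <- function(n, b0, b1,
                                  S_levels = main_emotion_levels() / 100,
                                  seed = 1L) {
  withr_seed(seed, {
    S <- sample(S_levels, n, replace = TRUE)
    p <- psychometric_p(b0, b1, S)
    y <- runif(n) < p
    data.frame(participant = "sim", block = 1L, mask = 0L,
               emotion = as.integer(round(S * 100)), filler = FALSE,
               choice = ifelse(y, "unfriendly", "friendly"), rt_s = NA_real_)
  })
}

#' Cohort-level bias and sensitivity tests
#'
#' Summarizes per-participant psychometric fits: condition medians of bias
#' `b0` and sensitivity `b1`, one-sample Wilcoxon signed-rank tests of
#' `b0 = 0` per condition, and a paired signed-rank test of masked vs
#' unmasked sensitivity.  Participants flagged `excluded` are dropped.
#'
#' @param fits a list, one element per participant, each a list with
#'   components `masked` and `unmasked` (both `psychometric_fit`).
#' @return A list with `medians` (data.frame) and `tests` (data.frame of
#'   statistic and p-value per test).
#' @export
bias_and_sensitivity_tests <- function(fits) {
  stopifnot(length(fits) >= 2)
  keep <- !vapply(fits, function(f)
    isTRUE(f$masked$excluded) || isTRUE(f$unmasked$excluded), logical(1))
  fits <- fits[keep]
  grab <- function(cond, what) vapply(fits, function(f)
    f[[cond]][[what]], numeric(1))
  b0m <- grab("masked", "b0"); b0u <- grab("unmasked", "b0")
  b1m <- grab("masked", "b1"); b1u <- grab("unmasked", "b1")
  wtest <- function(x, y = NULL, paired = FALSE) {
    t <- suppressWarnings(
      if (is.null(y)) wilcox.test(x, mu = 0) else
        wilcox.test(x, y, paired = paired))
    c(statistic = unname(t$statistic), p = t$p.value)
  }
  tests <- rbind(
    b0_masked_vs_0 = wtest(b0m),
    b0_unmasked_vs_0 = wtest(b0u),
    b1_masked_vs_unmasked = wtest(b1m, b1u, paired = TRUE))
  medians <- data.frame(
    condition = c("masked", "unmasked"),
    b0_median = c(median(b0m), median(b0u)),
    b1_median = c(median(b1m), median(b1u)),
    n = length(fits))
  list(medians = medians,
       tests = data.frame(test = rownames(tests), tests, row.names = NULL))
}

#' Per-cell median response times
#'
#' Median RT per participant and mask-by-emotion cell (valid, non-miss
#' trials), plus the cohort mean of those medians per cell.
#'
#' @param trials preprocessed trial records (may span participants).
#' @return A list with `per_participant` and `cohort` data.frames; empty
#'   cells carry NA.
#' @export
condition_medians <- function(trials) {
  keep <- trials$choice != "miss" & is.finite(trials$rt_s)
  if ("valid" %in% names(trials)) keep <- keep & trials$valid
  tr <- trials[keep, , drop = FALSE]
  pid <- if ("participant" %in% names(tr)) tr$participant else
    rep("all", nrow(tr))
  dat <- data.frame(participant = pid, mask = tr$mask, emotion = tr$emotion,
                    rt_s = tr$rt_s)
  per <- aggregate(rt_s ~ participant + mask + emotion, data = dat,
                   FUN = median, na.action = stats::na.omit)
  names(per)[names(per) == "rt_s"] <- "median_rt"
  coh <- aggregate(median_rt ~ mask + emotion, data = per, FUN = mean)
  names(coh)[names(coh) == "median_rt"] <- "mean_of_medians"
  list(per_participant = per, cohort = coh)
}
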