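#' Goodness of fit: predicted vs empirical choice proportions and RT quantiles
#'
#' Compares a fitted model's predictions with the participant's data in the
#' four cells used for model appraisal: happy (k < 0) vs angry (k > 0)
#' faces, collapsed over intensity, crossed with masked/unmasked.  For each
#' cell and each response ('unfriendly', 'friendly') the empirical choice
#' proportion and RT quantiles (5, 10, 30, 50, 70, 90 percent) are set
#' against the model-implied values computed from the fitted parameters'
#' first-passage densities (mixing emotion levels by their trial counts).
#' Cells with no observed responses of a given type report missing
#' quantiles.
#'
#' @param fit a converged [fit_mle()] result.
#' @param trials the trial records the fit was computed from.
#' @param engine an [engine_config()] for the model predictions.
#' @return A data.frame with columns `mask`, `valence`, `response`,
#'   `n_emp`, `p_emp`, `p_pred`, `q_level`, `rt_emp`, `rt_pred` (long
#'   format over quantile levels).
#' @export
goodness_of_fit <- function(fit, trials, engine = engine_config()) {
  stopifnot(inherits(fit, "ddm_fit"))
  if (!fit$converged) stop("goodness of fit requires a converged fit")
  qs <- c(.05, .10, .30, .50, .70, .90)
  keep <- !trials$filler & trials$choice != "miss"
  if ("valid" %in% names(trials)) keep <- keep & trials$valid
  tr <- trials[keep, , drop = FALSE]
  p <- fit$params
  out <- list()
  for (C in c(0L, 1L)) {
    for (val in c("happy", "angry")) {
      lev <- main_emotion_levels()
      lev <- if (val == "happy") lev[lev < 0] else lev[lev > 0]
      sel <- tr$mask == C & tr$emotion %in% lev
      sub <- tr[sel, , drop = FALSE]
      # model mixture over emotion levels, weighted by trial counts
      wts <- vapply(lev, function(e) sum(sub$emotion == e), numeric(1))
      if (sum(wts) == 0) wts <- rep(1, length(lev))
      fptds <- lapply(lev, function(e)
        solve_fptd(drift_rate(p, e / 100, C), p[["a"]], p[["tau"]],
                   start_point(p, C), engine))
      w <- wts / sum(wts)
      tmix <- fptds[[1]]$time
      up_mix <- Reduce(`+`, Map(function(f, wi) wi * f$upper, fptds, w))
      lo_mix <- Reduce(`+`, Map(function(f, wi) wi * f$lower, fptds, w))
      Ter <- nondecision(p, C)
      for (resp in c("unfriendly", "friendly")) {
        dens <- if (resp == "unfriendly") up_mix else lo_mix
        mass <- sum(dens) * engine$dt
        # model RT quantiles conditional on this response
        cdf <- cumsum(dens) * engine$dt / max(mass, 1e-12)
        rt_pred <- vapply(qs, function(q) {
          i <- which(cdf >= q)[1]
          if (is.na(i)) NA_real_ else tmix[i] + Ter
        }, numeric(1))
        obs <- sub$rt_s[sub$choice == resp]
        n_cell <- nrow(sub)
        rt_emp <- if (length(obs)) unname(quantile(obs, qs))
                  else rep(NA_real_, length(qs))
        out[[length(out) + 1L]] <- data.frame(
          mask = C, valence = val, response = resp,
          n_emp = length(obs),
          p_emp = if (n_cell) length(obs) / n_cell else NA_real_,
          p_pred = mass,
          q_level = qs, rt_emp = rt_emp, rt_pred = rt_pred)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
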