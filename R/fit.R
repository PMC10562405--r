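#' Fitting bounds
#'
#' Box constraints used by the optimizer, bracketing plausible values by a
#' wide margin.  Starting-point draws additionally require
#' |z0 + zmask| < 0.9 (enforced by penalty).
#'
#' @return A list with vectors `lower` and `upper` named by parameter.
#' @export
fit_bounds <- function() {
  lower <- c(a = 0.3, tau = 0, Ter0 = 0.1, Termask = -0.2, vc0 = -5,
             vcmask = -5, vslope0 = -20, vslopemask = -20, z0 = -0.9,
             zmask = -0.9)
  upper <- c(a = 5, tau = 10, Ter0 = 1.0, Termask = 0.2, vc0 = 5,
             vcmask = 5, vslope0 = 20, vslopemask = 20, z0 = 0.9,
             zmask = 0.9)
  list(lower = lower, upper = upper)
}

#' Fitting settings
#'
#' Settings for the seeded global search (differential evolution, run on a
#' coarsened grid for speed) and the local Nelder-Mead polish chain on the
#' full-resolution grid.
#'
#' @param seed integer seed; the whole fit is deterministic given it.
#' @param de_pop population size of the differential-evolution stage.
#' @param de_iter number of DE generations.
#' @param de_f DE differential weight.
#' @param de_cr DE crossover probability.
#' @param de_coarsen factor by which dt and dx are multiplied during the
#'   DE stage (1 disables coarsening).
#' @param polish_maxit maximum Nelder-Mead iterations per polish restart.
#' @param polish_restarts maximum number of Nelder-Mead restarts; the
#'   chain stops early once a restart improves the negative log-likelihood
#'   by less than `polish_tol`.
#' @param polish_tol early-stopping tolerance (log-likelihood units).
#' @param refine_factor factor applied to dt and dx for the final
#'   refinement polish (reduces discretization bias in the estimates);
#'   1 disables the stage.
#' @param refine_maxit maximum Nelder-Mead iterations for the refinement.
#' @param engine an [engine_config()] used for likelihood evaluation.
#' @param floor likelihood floor density (per second).
#' @return A list of class `fit_settings`.
#' @export
fit_settings <- function(seed = 1L, de_pop = 40L, de_iter = 150L,
                         de_f = 0.7, de_cr = 0.9, de_coarsen = 2,
                         polish_maxit = 2000L, polish_restarts = 5L,
                         polish_tol = 1.0, refine_factor = 0.5,
                         refine_maxit = 800L, engine = engine_config(),
                         floor = 1e-10) {
  structure(list(seed = as.integer(seed), de_pop = as.integer(de_pop),
                 de_iter = as.integer(de_iter), de_f = de_f, de_cr = de_cr,
                 de_coarsen = de_coarsen,
                 polish_maxit = as.integer(polish_maxit),
                 polish_restarts = as.integer(polish_restarts),
                 polish_tol = polish_tol, refine_factor = refine_factor,
                 refine_maxit = as.integer(refine_maxit),
                 engine = engine, floor = floor),
            class = "fit_settings")
}

# data-driven starting point: drift terms from a logistic choice fit
# (logit P(upper) ~ 2 v a_eff for constant bounds), Ter from the fastest
# responses, neutral start point and mid-range bound/collapse
heuristic_start <- function(prep, a_init = 1.2, tau_init = 1.5) {
  C <- prep$cells$mask[prep$trial_cell + 1L]
  k <- prep$cells$emotion[prep$trial_cell + 1L] / 100
  co <- lapply(c(0L, 1L), function(cc) {
    sel <- C == cc
    f <- suppressWarnings(glm(prep$trial_upper[sel] ~ k[sel],
                              family = binomial()))
    coef(f)
  })
  a_eff <- 0.7 * a_init
  Ter0 <- max(0.12, 0.9 * quantile(prep$trial_rt[C == 0], 0.01))
  out <- c(a = a_init, tau = tau_init, Ter0 = unname(Ter0), Termask = 0,
           vc0 = unname(co[[1]][1] / (2 * a_eff)),
           vcmask = unname((co[[2]][1] - co[[1]][1]) / (2 * a_eff)),
           vslope0 = unname(co[[1]][2] / (2 * a_eff)),
           vslopemask = unname((co[[2]][2] - co[[1]][2]) / (2 * a_eff)),
           z0 = 0, zmask = 0)
  out[!is.finite(out)] <- 0
  out
}

# prepare flattened cell-indexed trial arrays: analyzable trials only
prepare_cells <- function(trials) {
  keep <- !trials$filler & trials$choice != "miss"
  if ("valid" %in% names(trials)) keep <- keep & trials$valid
  tr <- trials[keep, , drop = FALSE]
  cells <- expand.grid(mask = c(0L, 1L), emotion = main_emotion_levels(),
                       KEEP.OUT.ATTRS = FALSE)
  key <- paste(tr$mask, tr$emotion)
  cell_key <- paste(cells$mask, cells$emotion)
  cell_idx <- match(key, cell_key)
  if (anyNA(cell_idx))
    stop("trials with emotion levels outside the main design")
  n_per_cell <- tabulate(cell_idx, nbins = nrow(cells))
  if (any(n_per_cell < 1))
    stop("fewer than one analyzable trial in some mask-by-emotion cell")
  list(cells = cells,
       trial_cell = cell_idx - 1L,                  # 0-based for C++
       trial_upper = as.integer(tr$choice == "unfriendly"),
       trial_rt = tr$rt_s,
       n_trials = nrow(tr))
}

# negative log-likelihood of a full 10-vector theta on prepared cells;
# evaluates one FPTD per (mask, emotion) cell (a, tau shared; z and Ter
# vary with mask only) and scores trials in C++
negloglik_theta <- function(theta, prep, engine, floor = 1e-10) {
  names(theta) <- ddm_param_names()
  if (theta[["a"]] <= 0 || theta[["tau"]] < 0 || theta[["Ter0"]] <= 0 ||
      theta[["Ter0"]] + theta[["Termask"]] <= 0 ||
      abs(theta[["z0"]]) >= 0.95 ||
      abs(theta[["z0"]] + theta[["zmask"]]) >= 0.95)
    return(1e10)
  C <- prep$cells$mask
  k <- prep$cells$emotion / 100
  v <- theta[["vc0"]] + C * theta[["vcmask"]] +
    k * (theta[["vslope0"]] + C * theta[["vslopemask"]])
  z <- theta[["z0"]] + C * theta[["zmask"]]
  Ter <- theta[["Ter0"]] + C * theta[["Termask"]]
  # reject starts the grid cannot represent (within one cell of a bound)
  if (any(abs(z) * theta[["a"]] >= theta[["a"]] - 1.5 * engine$dx))
    return(1e10)
  nll <- tryCatch(
    cells_negloglik_cpp(v, z, Ter, theta[["a"]], theta[["tau"]],
                        prep$trial_cell, prep$trial_upper, prep$trial_rt,
                        engine$dt, engine$dx, engine$t_max, floor),
    error = function(e) 1e10)
  if (!is.finite(nll)) 1e10 else nll
}

# compact seeded differential evolution (rand/1/bin) over free coordinates
de_optim <- function(fn, lower, upper, pop_size, n_iter, f, cr, init = NULL) {
  d <- length(lower)
  pop <- matrix(runif(pop_size * d, rep(lower, each = pop_size),
                      rep(upper, each = pop_size)), nrow = pop_size)
  if (!is.null(init)) pop[1, ] <- pmin(pmax(init, lower), upper)
  cost <- apply(pop, 1, fn)
  for (it in seq_len(n_iter)) {
    for (i in seq_len(pop_size)) {
      idx <- sample.int(pop_size, 3)
      while (any(idx == i)) idx <- sample.int(pop_size, 3)
      trial <- pop[idx[1], ] + f * (pop[idx[2], ] - pop[idx[3], ])
      cross <- runif(d) < cr
      cross[sample.int(d, 1)] <- TRUE
      trial <- ifelse(cross, trial, pop[i, ])
      trial <- pmin(pmax(trial, lower), upper)
      ct <- fn(trial)
      if (ct <= cost[i]) {
        pop[i, ] <- trial
        cost[i] <- ct
      }
    }
  }
  best <- which.min(cost)
  list(par = pop[best, ], value = cost[best],
       evals = pop_size * (n_iter + 1))
}

#' Fit a drift-diffusion model to one participant by maximum likelihood
#'
#' Maximizes the summed log first-passage density over the participant's
#' analyzable trials (main emotion levels only; fillers, misses and trials
#' flagged invalid by preprocessing are excluded).  The search runs seeded
#' stages within [fit_bounds()]: (1) a data-driven start from a logistic
#' choice fit and the fastest responses, (2) a differential-evolution
#' population (including that start) evolved on a coarsened grid followed
#' by a bounded quasi-Newton descent on the same grid, (3) a Nelder-Mead
#' restart chain on the full-resolution grid, stopped when a restart no
#' longer improves the fit, and (4) a short refinement polish on a finer
#' grid that trims discretization bias from the estimates.  The result is
#' deterministic given `settings$seed`.
#'
#' @param trials a trial record data.frame (one participant).
#' @param spec a [model_spec()]; pinned bias terms are fixed at zero.
#' @param settings a [fit_settings()].
#' @return An object of class `ddm_fit`: list with `participant`, `model`,
#'   `params` (full 10-vector, pinned entries zero), `logLik`, `n_free`,
#'   `n_trials`, `AIC`, `BIC`, `converged`, and optimizer metadata.
#' @export
fit_mle <- function(trials, spec = model_spec("full_vc_z"),
                    settings = fit_settings()) {
  stopifnot(inherits(spec, "model_spec"))
  prep <- prepare_cells(trials)
  bounds <- fit_bounds()
  free <- spec$free
  fixed <- setNames(numeric(10), ddm_param_names())
  eng <- settings$engine
  coarse <- engine_config(dt = eng$dt * settings$de_coarsen,
                          dx = eng$dx * settings$de_coarsen,
                          t_max = eng$t_max)
  obj_fine <- function(x) {
    th <- fixed
    th[free] <- x
    negloglik_theta(th, prep, eng, settings$floor)
  }
  obj_coarse <- function(x) {
    th <- fixed
    th[free] <- x
    negloglik_theta(th, prep, coarse, settings$floor)
  }
  res <- withr_seed(settings$seed, {
    hs <- heuristic_start(prep)[free]
    de <- de_optim(obj_coarse, bounds$lower[free], bounds$upper[free],
                   settings$de_pop, settings$de_iter, settings$de_f,
                   settings$de_cr, init = hs)
    # gradient-based ridge descent, still on the cheap coarse grid
    lb <- optim(de$par, obj_coarse, method = "L-BFGS-B",
                lower = bounds$lower[free], upper = bounds$upper[free],
                control = list(maxit = 80))
    par <- if (lb$value <= de$value) lb$par else de$par
    val <- obj_fine(par)
    evals <- de$evals + lb$counts[["function"]] + 1L
    converged <- FALSE
    for (r in seq_len(settings$polish_restarts)) {
      pol <- optim(par, obj_fine, method = "Nelder-Mead",
                   control = list(maxit = settings$polish_maxit,
                                  reltol = 1e-10))
      evals <- evals + pol$counts[["function"]]
      improved <- val - pol$value
      if (pol$value <= val) {
        par <- pol$par
        val <- pol$value
      }
      if (r > 1 && improved < settings$polish_tol) {
        converged <- TRUE
        break
      }
    }
    if (settings$refine_factor < 1) {
      refined <- engine_config(dt = eng$dt * settings$refine_factor,
                               dx = eng$dx * settings$refine_factor,
                               t_max = eng$t_max)
      obj_ref <- function(x) {
        th <- fixed
        th[free] <- x
        negloglik_theta(th, prep, refined, settings$floor)
      }
      pol <- optim(par, obj_ref, method = "Nelder-Mead",
                   control = list(maxit = settings$refine_maxit,
                                  reltol = 1e-10))
      evals <- evals + pol$counts[["function"]]
      if (pol$value <= obj_ref(par)) {
        par <- pol$par
        val <- pol$value
      } else {
        val <- obj_ref(par)
      }
    }
    list(par = par, val = val, evals = evals, converged = converged)
  })
  params <- fixed
  params[free] <- res$par
  class(params) <- "ddm_params"
  logL <- -res$val
  n_free <- length(free)
  n_tr <- prep$n_trials
  structure(list(
    participant = if ("participant" %in% names(trials))
      trials$participant[1] else NA_character_,
    model = spec$name,
    params = params,
    logLik = logL,
    n_free = n_free,
    n_trials = n_tr,
    AIC = 2 * n_free - 2 * logL,
    BIC = n_free * log(n_tr) - 2 * logL,
    converged = res$converged && res$val < 1e9,
    seed = settings$seed,
    evals = res$evals
  ), class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf("ddm_fit: model %s, participant %s\n", x$model,
              x$participant))
  cat(sprintf("  logLik %.2f  AIC %.2f  BIC %.2f  (%d free, %d trials)\n",
              x$logLik, x$AIC, x$BIC, x$n_free, x$n_trials))
  print(round(unclass(x$params), 4))
  invisible(x)
}

#' Model selection over a cohort of fits
#'
#' For each participant with a converged fit of every model, picks the
#' AIC- and BIC-minimizing model (ties broken toward the model with fewer
#' free parameters) and averages criteria per model.
#'
#' @param fits list of `ddm_fit` objects (all models x all participants).
#' @return A data.frame of class `selection_table` with one row per model:
#'   `model`, `mean_AIC`, `mean_BIC`, `pct_best_AIC`, `pct_best_BIC`.
#' @export
select_models <- function(fits) {
  df <- do.call(rbind, lapply(fits, function(f)
    data.frame(participant = f$participant, model = f$model, AIC = f$AIC,
               BIC = f$BIC, n_free = f$n_free, converged = f$converged)))
  df <- df[df$converged, , drop = FALSE]
  keep <- table(df$participant)
  complete <- names(keep)[keep == length(model_names())]
  dropped <- setdiff(unique(df$participant), complete)
  if (length(dropped))
    warning("participants excluded for missing model fits: ",
            paste(dropped, collapse = ", "))
  df <- df[df$participant %in% complete, , drop = FALSE]
  if (!nrow(df)) stop("no participant has all four converged fits")
  pick <- function(sub, crit) {
    o <- order(sub[[crit]], sub$n_free)
    sub$model[o[1]]
  }
  best <- do.call(rbind, lapply(split(df, df$participant), function(sub)
    data.frame(best_AIC = pick(sub, "AIC"), best_BIC = pick(sub, "BIC"))))
  out <- data.frame(model = model_names())
  out$mean_AIC <- vapply(out$model, function(m)
    mean(df$AIC[df$model == m]), numeric(1))
  out$mean_BIC <- vapply(out$model, function(m)
    mean(df$BIC[df$model == m]), numeric(1))
  out$pct_best_AIC <- vapply(out$model, function(m)
    100 * mean(best$best_AIC == m), numeric(1))
  out$pct_best_BIC <- vapply(out$model, function(m)
    100 * mean(best$best_BIC == m), numeric(1))
  class(out) <- c("selection_table", "data.frame")
  out
}
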