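# Cheap fitting settings for unit tests: coarse engine, small DE stage, no
# refinement.  Accuracy is not the point of tests that use these; speed is.
cheap_settings <- function(seed = 1L) {
  fit_settings(seed = seed, de_pop = 12L, de_iter = 25L,
               polish_maxit = 300L, polish_restarts = 2L, polish_tol = 5,
               refine_factor = 1,
               engine = engine_config(dt = 0.01, dx = 0.01))
}

# A small balanced dataset from the group-mean parameters
small_dataset <- function(n_per_cell = 60L, seed = 1L) {
  simulate_cells(group_mean_params(), n_per_cell, seed = seed)
}

# Construct a ddm_fit-like stub (for selection-table logic tests)
fit_stub <- function(participant, model, logL, n_free, n_trials = 500L,
                     converged = TRUE) {
  structure(list(participant = participant, model = model,
                 params = group_mean_params(), logLik = logL,
                 n_free = n_free, n_trials = n_trials,
                 AIC = 2 * n_free - 2 * logL,
                 BIC = n_free * log(n_trials) - 2 * logL,
                 converged = converged, seed = 1L, evals = 0L),
            class = "ddm_fit")
}
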