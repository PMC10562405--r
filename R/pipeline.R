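#' Pipeline run configuration
#'
#' Reads (or builds) the configuration for an end-to-end run: simulate a
#' synthetic cohort, preprocess and describe it, fit the four-model family
#' per participant, select models, and optionally run a parameter-recovery
#' experiment.  All stochastic stages derive their seeds from the single
#' top-level seed.
#'
#' @param seed top-level integer seed.
#' @param n_participants cohort size.
#' @param out_dir output directory for the run.
#' @param models character vector of models to fit.
#' @param engine list overriding [engine_config()] fields (`dt`, `dx`,
#'   `t_max`).
#' @param optimizer list overriding [fit_settings()] fields.
#' @param recovery NULL, or a list with `trials_per_cell` and `n_reps` to
#'   run the recovery stage.
#' @param verbose print stage progress to stderr.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed, n_participants = 2L, out_dir = tempfile("run"),
                       models = model_names(), engine = list(),
                       optimizer = list(), recovery = NULL, verbose = TRUE) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  eng <- do.call(engine_config, engine)
  opt <- do.call(fit_settings, c(list(engine = eng), optimizer))
  structure(list(seed = as.integer(seed),
                 n_participants = as.integer(n_participants),
                 out_dir = out_dir, models = match.arg(models,
                   model_names(), several.ok = TRUE),
                 engine = eng, optimizer = opt, recovery = recovery,
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with top-level keys matching the arguments above
#'   (`engine`, `optimizer` and `recovery` as nested maps).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> describe -> fit -> select (-> recover) and writes
#' every stage's outputs under `config$out_dir`: participant trial CSVs and
#' true parameters, per-participant psychometric fits and cell medians,
#' per-fit results, the model-selection table, the optional recovery
#' report, and a `manifest.json` recording seeds and MD5 hashes of all
#' written files.  Any stage failure aborts with a stage-tagged error;
#' outputs of completed stages are preserved.
#'
#' @param config a [run_config()].
#' @return The manifest (invisibly); side effect: files under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (config$verbose) message("[maskddm] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  data_dir <- file.path(config$out_dir, "data")

  say("stage simulate")
  cohort <- stage("simulate", {
    cs <- cohort_spec(config$n_participants, seed = config$seed)
    co <- simulate_cohort(cs)
    write_cohort(co, data_dir)
    co
  })

  say("stage describe")
  desc <- stage("describe", {
    pre <- lapply(cohort$trials, preprocess_rt)
    psy <- lapply(pre, function(tr) list(
      masked = fit_psychometric(tr, "masked"),
      unmasked = fit_psychometric(tr, "unmasked")))
    psy_df <- do.call(rbind, lapply(names(psy), function(id) {
      f <- psy[[id]]
      data.frame(participant = id,
                 condition = c("masked", "unmasked"),
                 b0 = c(f$masked$b0, f$unmasked$b0),
                 b1 = c(f$masked$b1, f$unmasked$b1),
                 deviance = c(f$masked$deviance, f$unmasked$deviance),
                 df = c(f$masked$df, f$unmasked$df),
                 excluded = c(f$masked$excluded, f$unmasked$excluded))
    }))
    write.csv(psy_df, file.path(config$out_dir, "psychometric.csv"),
              row.names = FALSE)
    med <- condition_medians(do.call(rbind, pre))
    write.csv(med$per_participant,
              file.path(config$out_dir, "cell_medians.csv"),
              row.names = FALSE)
    list(pre = pre, psy = psy)
  })

  say("stage fit (", length(config$models), " models x ",
      config$n_participants, " participants)")
  fits <- stage("fit", {
    all_fits <- list()
    for (id in names(desc$pre)) {
      for (m in config$models) {
        st <- config$optimizer
        st$seed <- (config$seed + match(m, model_names()) * 131L +
                      match(id, names(desc$pre)) * 17L) %%
          .Machine$integer.max
        f <- fit_mle(desc$pre[[id]], model_spec(m), st)
        all_fits[[paste(id, m, sep = "_")]] <- f
      }
    }
    fit_df <- do.call(rbind, lapply(all_fits, function(f)
      data.frame(participant = f$participant, model = f$model,
                 as.data.frame(t(unclass(f$params))), logLik = f$logLik,
                 n_free = f$n_free, n_trials = f$n_trials, AIC = f$AIC,
                 BIC = f$BIC, converged = f$converged, seed = f$seed)))
    write.csv(fit_df, file.path(config$out_dir, "fits.csv"),
              row.names = FALSE)
    all_fits
  })

  say("stage select")
  stage("select", {
    sel <- select_models(fits)
    write.csv(sel, file.path(config$out_dir, "selection.csv"),
              row.names = FALSE)
  })

  if (!is.null(config$recovery)) {
    say("stage recover")
    stage("recover", {
      rec <- parameter_recovery(
        group_mean_params(),
        trials_per_cell = config$recovery$trials_per_cell,
        n_reps = config$recovery$n_reps,
        seed = config$seed, settings = config$optimizer)
      write.csv(rec$summary, file.path(config$out_dir, "recovery.csv"),
                row.names = FALSE)
    })
  }

  say("stage manifest")
  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package = "maskddm",
    version = as.character(utils::packageVersion("maskddm")),
    seed = config$seed,
    n_participants = config$n_participants,
    models = config$models,
    engine = unclass(config$engine),
    files = data.frame(
      file = sub(paste0("^", config$out_dir, "/?"), "", files),
      md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
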