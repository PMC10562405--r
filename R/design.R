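#' Build the experiment's trial design
#'
#' Generates the 608-trial two-alternative forced-choice design: 96 trials
#' (48 masked) for each of the six main stimulus emotions (-60, -40, -10,
#' 10, 40, 60 percent) plus 32 filler trials (16 masked) at -20 and 20
#' percent, arranged in 8 blocks of 76 trials.  Each block holds a random
#' alternation of all mask-by-emotion conditions (12 trials per main cell
#' and 2 per filler cell per block, shuffled within block).  A per-trial
#' fixation duration is drawn uniformly between 600 and 1200 ms; it jitters
#' the stimulus onset but does not enter the response-time clock.
#'
#' @param seed integer seed; the design is deterministic given the seed.
#' @return A data.frame of class `trial_design` with columns `trial`,
#'   `block` (1..8), `mask` (0/1), `emotion` (signed integer percent),
#'   `filler` (logical), `fixation_ms`.
#' @export
build_design <- function(seed = 1L) {
  withr_seed(seed, {
    main <- expand.grid(mask = c(0L, 1L), emotion = main_emotion_levels(),
                        rep = seq_len(6L), KEEP.OUT.ATTRS = FALSE)
    fill <- expand.grid(mask = c(0L, 1L), emotion = filler_emotion_levels(),
                        rep = 1L, KEEP.OUT.ATTRS = FALSE)
    main$filler <- FALSE
    fill$filler <- TRUE
    block_pool <- rbind(main[c("mask", "emotion", "filler")],
                        fill[c("mask", "emotion", "filler")])  # 76 trials
    blocks <- lapply(seq_len(8L), function(b) {
      bl <- block_pool[sample.int(nrow(block_pool)), , drop = FALSE]
      bl$block <- b
      bl
    })
    d <- do.call(rbind, blocks)
    d$trial <- seq_len(nrow(d))
    d$fixation_ms <- sample(600:1200, nrow(d), replace = TRUE)
    rownames(d) <- NULL
    d <- d[c("trial", "block", "mask", "emotion", "filler", "fixation_ms")]
    class(d) <- c("trial_design", "data.frame")
    d
  })
}

# evaluate expr under a local, restored RNG state
withr_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv())) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a single decision trial
#'
#' Runs one (or `n`) Euler-Maruyama realization(s) of the diffusion for a
#' given condition: the path starts at `z * a` (with `z = z0 + C zmask`),
#' drifts at the condition's rate, and is absorbed at the exponentially
#' collapsing bounds.  The response time is the crossing time plus the
#' non-decision time; a miss is returned when no bound is crossed before
#' the 2.3 s response deadline (i.e. within `deadline - Ter` of decision
#' time).  Uses R's RNG: seed with `set.seed()`.
#'
#' @param params a [ddm_params()] vector.
#' @param mask mask indicator C, 0 or 1.
#' @param emotion signed stimulus emotion in percent (e.g. -60..60).
#' @param n number of independent trials to draw.
#' @param dt Euler step, seconds (default 1 ms).
#' @param deadline response deadline, seconds.
#' @return A data.frame with columns `choice` ("unfriendly", "friendly" or
#'   "miss") and `rt_s` (seconds; NA for misses).
#' @export
simulate_trial <- function(params, mask, emotion, n = 1L, dt = 0.001,
                           deadline = 2.3) {
  validate_ddm_params(params)
  if (dt <= 0) stop("configuration error: step size must be > 0")
  v <- drift_rate(params, emotion / 100, mask)
  z <- start_point(params, mask)
  Ter <- nondecision(params, mask)
  t_dec_max <- deadline - Ter
  if (t_dec_max <= 0) stop("non-decision time exceeds the deadline")
  out <- sim_paths_cpp(as.integer(n), v, params[["a"]], params[["tau"]], z,
                       dt, t_dec_max)
  choice <- c("friendly", "miss", "unfriendly")[out$choice + 2L]
  rt <- out$dtime + Ter
  rt[choice == "miss"] <- NA_real_
  data.frame(choice = choice, rt_s = rt)
}

#' Simulate one participant over a full design
#'
#' @param params true [ddm_params()] for this participant.
#' @param design a [build_design()] table.
#' @param seed integer seed; records are reproducible given the seed.
#' @param participant_id identifier stored in the output.
#' @param dt Euler step, seconds.
#' @return A data.frame of trial records: `participant`, `block`, `mask`,
#'   `emotion`, `filler`, `choice`, `rt_s`.
#' @export
simulate_participant <- function(params, design = build_design(seed),
                                 seed = 1L, participant_id = "p01",
                                 dt = 0.001) {
  validate_ddm_params(params)
  withr_seed(seed, {
    cells <- unique(design[c("mask", "emotion")])
    res <- vector("list", nrow(cells))
    idx <- vector("list", nrow(cells))
    for (i in seq_len(nrow(cells))) {
      sel <- design$mask == cells$mask[i] & design$emotion == cells$emotion[i]
      idx[[i]] <- which(sel)
      res[[i]] <- simulate_trial(params, cells$mask[i], cells$emotion[i],
                                 n = sum(sel), dt = dt)
    }
    out <- design
    out$choice <- NA_character_
    out$rt_s <- NA_real_
    for (i in seq_len(nrow(cells))) {
      out$choice[idx[[i]]] <- res[[i]]$choice
      out$rt_s[idx[[i]]] <- res[[i]]$rt_s
    }
    out$participant <- participant_id
    out <- out[c("participant", "block", "mask", "emotion", "filler",
                 "choice", "rt_s")]
    class(out) <- "data.frame"
    rownames(out) <- NULL
    out
  })
}

#' Simulate a synthetic cohort
#'
#' Draws per-participant true parameters from the cohort specification's
#' (truncated) normal population distributions and simulates each
#' participant over a freshly randomized design.  Rejection sampling
#' enforces parameter validity; an error is raised if a draw cannot be
#' achieved (infeasible truncation region).
#'
#' @param spec a [cohort_spec()].
#' @param dt Euler step, seconds.
#' @return A list with `trials` (one trial data.frame per participant),
#'   `true_params` (data.frame of the generating parameters) and `spec`.
#' @export
simulate_cohort <- function(spec, dt = 0.001) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_participants
  ids <- sprintf("p%03d", seq_len(n))
  draws <- withr_seed(spec$seed, {
    lapply(seq_len(n), function(i) draw_valid_params(spec$means, spec$sds))
  })
  trials <- vector("list", n)
  for (i in seq_len(n)) {
    sub_seed <- (spec$seed * 1009L + i * 7919L) %% .Machine$integer.max
    des <- build_design(seed = sub_seed)
    trials[[i]] <- simulate_participant(draws[[i]], des, seed = sub_seed + 1L,
                                        participant_id = ids[i], dt = dt)
  }
  tp <- do.call(rbind, lapply(draws, function(p) as.data.frame(t(unclass(p)))))
  tp <- cbind(participant = ids, tp)
  list(trials = setNames(trials, ids), true_params = tp, spec = spec)
}

draw_valid_params <- function(means, sds, max_tries = 1000L) {
  nm <- ddm_param_names()
  for (i in seq_len(max_tries)) {
    x <- rnorm(length(nm), unclass(means)[nm], sds[nm])
    names(x) <- nm
    ok <- x[["a"]] > 0 && x[["tau"]] >= 0 && x[["Ter0"]] > 0 &&
      x[["Ter0"]] + x[["Termask"]] >= 0 &&
      abs(x[["z0"]]) < 1 && abs(x[["z0"]] + x[["zmask"]]) < 1
    if (ok) {
      class(x) <- "ddm_params"
      return(x)
    }
  }
  stop("could not draw valid parameters; truncation region may be infeasible")
}

#' Write / read cohort trial tables
#'
#' Trial tables are stored one CSV per participant with header
#' `participant,block,mask,emotion,filler,choice,rt_s` (empty `rt_s` for
#' misses); the generating parameters go to a sidecar JSON.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output/input directory.
#' @return `write_cohort` returns the directory invisibly; `read_cohort`
#'   returns a named list of trial data.frames.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$trials)) {
    write.csv(cohort$trials[[id]], file.path(dir, paste0(id, ".csv")),
              row.names = FALSE, quote = FALSE, na = "")
  }
  jsonlite::write_json(cohort$true_params,
                       file.path(dir, "true_params.json"), digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  files <- sort(list.files(dir, pattern = "^p[0-9]+\\.csv$",
                           full.names = TRUE))
  if (!length(files)) stop("no participant CSV files found in ", dir)
  out <- lapply(files, function(f) {
    d <- read.csv(f, colClasses = c(participant = "character",
                                    choice = "character"))
    d$rt_s <- as.numeric(d$rt_s)
    d$filler <- as.logical(d$filler)
    d
  })
  setNames(out, sub("\\.csv$", "", basename(files)))
}
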