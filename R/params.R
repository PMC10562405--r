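#' Drift-diffusion model parameters
#'
#' Container for the ten free parameters of the full collapsing-bound
#' drift-diffusion model of masked/unmasked friendly-unfriendly judgments.
#' The drift rate on a trial with stimulus emotion fraction `k` (in
#' \[-1, 1\], e.g. 0.60 for a 60% angry morph) and mask indicator `C` is
#'
#'   v = vc0 + C * vcmask + k * (vslope0 + C * vslopemask)
#'
#' the non-decision time is `Ter0 + C * Termask` (seconds), and the starting
#' point, expressed as a signed fraction of the initial bound (positive
#' toward the upper, 'unfriendly' threshold), is `z0 + C * zmask`.  The
#' decision thresholds collapse exponentially, `b(t) = a * exp(-tau * t)`,
#' and are shared between masked and unmasked conditions, as is the starting
#' point baseline.  The diffusion (noise) coefficient is fixed at 1.
#'
#' @param a initial decision threshold (> 0); bounds sit at +/- a at t = 0.
#' @param tau exponential collapse rate of the bounds, 1/s (>= 0).
#' @param Ter0 non-decision time for unmasked faces, seconds (> 0).
#' @param Termask additive mask effect on non-decision time, seconds.
#' @param vc0 drift-rate criterion (drift intercept) for unmasked faces.
#' @param vcmask additive mask effect on the drift-rate criterion
#'   (perceptual bias; positive values favor 'unfriendly').
#' @param vslope0 drift-rate slope per unit emotion fraction, unmasked.
#' @param vslopemask additive mask effect on the drift slope.
#' @param z0 starting point as a signed fraction of the initial bound,
#'   |z0| < 1; positive values start closer to the 'unfriendly' threshold.
#' @param zmask additive mask effect on the starting point fraction
#'   (preconceptual bias); |z0 + zmask| < 1 is required.
#'
#' @return An object of class `ddm_params` (a named numeric vector).
#' @seealso [group_mean_params()], [drift_rate()], [condition_table()]
#' @export
ddm_params <- function(a, tau, Ter0, Termask = 0, vc0 = 0, vcmask = 0,
                       vslope0 = 0, vslopemask = 0, z0 = 0, zmask = 0) {
  p <- c(a = a, tau = tau, Ter0 = Ter0, Termask = Termask, vc0 = vc0,
         vcmask = vcmask, vslope0 = vslope0, vslopemask = vslopemask,
         z0 = z0, zmask = zmask)
  storage.mode(p) <- "double"
  class(p) <- "ddm_params"
  validate_ddm_params(p)
  p
}

#' @rdname ddm_params
#' @param p object to validate.
#' @export
validate_ddm_params <- function(p) {
  stopifnot(is.numeric(p), length(p) == 10,
            identical(names(p), ddm_param_names()))
  if (any(!is.finite(p))) stop("all DDM parameters must be finite")
  if (p[["a"]] <= 0) stop("threshold 'a' must be positive")
  if (p[["tau"]] < 0) stop("collapse rate 'tau' must be non-negative")
  if (p[["Ter0"]] <= 0) stop("'Ter0' must be positive")
  if (p[["Ter0"]] + p[["Termask"]] < 0)
    stop("masked non-decision time Ter0 + Termask must be non-negative")
  if (abs(p[["z0"]]) >= 1 || abs(p[["z0"]] + p[["zmask"]]) >= 1)
    stop("starting point fractions must satisfy |z0| < 1 and |z0 + zmask| < 1")
  invisible(p)
}

#' @rdname ddm_params
#' @export
ddm_param_names <- function() {
  c("a", "tau", "Ter0", "Termask", "vc0", "vcmask",
    "vslope0", "vslopemask", "z0", "zmask")
}

#' Group-mean drift-diffusion parameters
#'
#' The group-mean (and between-participant SD) parameter values of the full
#' model used as the package's reference generating truth for synthetic
#' cohorts and recovery experiments.  Non-decision times are stored in
#' seconds (the group means are 380 ms baseline, +14 ms mask effect).
#'
#' @return For `group_mean_params()`, a `ddm_params` vector of means; for
#'   `group_param_sds()`, a named numeric vector of between-participant SDs
#'   on the same scale.
#' @export
group_mean_params <- function() {
  ddm_params(a = 1.08, tau = 1.29, Ter0 = 0.380, Termask = 0.014,
             vc0 = 0.17, vcmask = -0.28, vslope0 = 5.68,
             vslopemask = -1.78, z0 = -0.06, zmask = 0.10)
}

#' @rdname group_mean_params
#' @export
group_param_sds <- function() {
  c(a = 0.23, tau = 0.5, Ter0 = 0.061, Termask = 0.026, vc0 = 0.36,
    vcmask = 0.53, vslope0 = 0.11, vslopemask = 1.10, z0 = 0.08,
    zmask = 0.11)
}

#' Model specification: the four-model family
#'
#' The family nests by pinning the two mask-bias terms to zero: the null
#' model pins both `vcmask` (drift-criterion bias) and `zmask`
#' (starting-point bias); `reduced_vc` frees `vcmask` only; `reduced_z`
#' frees `zmask` only; `full_vc_z` frees both.  All models share the eight
#' remaining parameters.
#'
#' @param name one of `"null"`, `"reduced_vc"`, `"reduced_z"`, `"full_vc_z"`.
#' @return An object of class `model_spec` with elements `name`, `free`
#'   (character vector of free parameter names) and `n_free`.
#' @export
model_spec <- function(name = c("null", "reduced_vc", "reduced_z",
                                "full_vc_z")) {
  name <- match.arg(name)
  base <- setdiff(ddm_param_names(), c("vcmask", "zmask"))
  free <- switch(name,
    null       = base,
    reduced_vc = c(base, "vcmask"),
    reduced_z  = c(base, "zmask"),
    full_vc_z  = c(base, "vcmask", "zmask"))
  free <- ddm_param_names()[ddm_param_names() %in% free]
  structure(list(name = name, free = free, n_free = length(free)),
            class = "model_spec")
}

#' @rdname model_spec
#' @export
model_names <- function() c("null", "reduced_vc", "reduced_z", "full_vc_z")

#' Pin a parameter vector to a model specification
#'
#' Sets the parameters a specification excludes to zero.
#'
#' @param p a `ddm_params` vector.
#' @param spec a `model_spec`.
#' @return The pinned `ddm_params` vector.
#' @export
pin_params <- function(p, spec) {
  pinned <- setdiff(ddm_param_names(), spec$free)
  p[pinned] <- 0
  validate_ddm_params(p)
  p
}

#' Cohort specification for synthetic participants
#'
#' Per-participant true parameters are drawn independently from normal
#' distributions with the given means and SDs, truncated so that every draw
#' is a valid parameter set (a > 0, tau >= 0, Ter0 > 0, Ter0 + Termask >= 0,
#' |z0| < 1 and |z0 + zmask| < 1).  Defaults are the group means/SDs of
#' [group_mean_params()].
#'
#' @param n_participants number of synthetic participants (>= 1).
#' @param means `ddm_params` of population means.
#' @param sds named numeric vector of population SDs (>= 0), same names.
#' @param seed integer seed controlling both the parameter draws and the
#'   per-participant trial simulation.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants, means = group_mean_params(),
                        sds = group_param_sds(), seed = 1L) {
  stopifnot(n_participants >= 1)
  validate_ddm_params(means)
  sds <- sds[ddm_param_names()]
  if (any(is.na(sds)) || any(sds < 0))
    stop("population SDs must be named, complete and non-negative")
  structure(list(n_participants = as.integer(n_participants),
                 means = means, sds = sds, seed = as.integer(seed)),
            class = "cohort_spec")
}
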