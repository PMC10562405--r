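#' Condition-level model quantities
#'
#' Map a parameter vector and an experimental condition (mask indicator `C`,
#' stimulus emotion fraction `k`) to the engine-level drift rate,
#' non-decision time and starting point.  `k` is the signed morph level as a
#' fraction (the data files carry integer percent labels -60..60; divide by
#' 100).  Positive drift and positive starting point push toward the upper,
#' 'unfriendly' threshold.
#'
#' @param p a [ddm_params()] vector.
#' @param k stimulus emotion fraction(s) in \[-1, 1\].
#' @param C mask indicator, 0 (unmasked) or 1 (masked); vectorized.
#' @return `drift_rate`: drift in evidence units per second;
#'   `nondecision`: seconds; `start_point`: signed fraction of the initial
#'   bound.
#' @export
drift_rate <- function(p, k, C) {
  stopifnot(all(C %in% c(0, 1)), all(abs(k) <= 1))
  p[["vc0"]] + C * p[["vcmask"]] +
    k * (p[["vslope0"]] + C * p[["vslopemask"]])
}

#' @rdname drift_rate
#' @export
nondecision <- function(p, C) {
  stopifnot(all(C %in% c(0, 1)))
  ter <- p[["Ter0"]] + C * p[["Termask"]]
  if (any(ter < 0)) stop("non-decision time is negative")
  ter
}

#' @rdname drift_rate
#' @export
start_point <- function(p, C) {
  stopifnot(all(C %in% c(0, 1)))
  z <- p[["z0"]] + C * p[["zmask"]]
  if (any(abs(z) >= 1)) stop("|starting point fraction| must be < 1")
  z
}

#' Emotion levels of the design
#'
#' The six main signed morph levels (percent) and the two filler levels.
#' @return Integer vector of levels.
#' @export
main_emotion_levels <- function() c(-60L, -40L, -10L, 10L, 40L, 60L)

#' @rdname main_emotion_levels
#' @export
filler_emotion_levels <- function() c(-20L, 20L)

#' Engine parameterization for every analyzable cell
#'
#' Expands a parameter vector under a model specification into the 12
#' mask-by-emotion cells (2 mask levels x 6 main emotion levels), each with
#' its engine tuple (v, a, tau, z, Ter).  The threshold `a`, collapse rate
#' `tau` and baseline start point are shared across cells; only the drift,
#' non-decision time and (for models with a starting-point bias) the start
#' fraction vary with the mask.
#'
#' @param p a [ddm_params()] vector; parameters pinned by `spec` must be 0.
#' @param spec a [model_spec()].
#' @return A data.frame with columns `mask`, `emotion` (integer percent),
#'   `k` (fraction), `v`, `a`, `tau`, `z`, `Ter`.
#' @export
condition_table <- function(p, spec = model_spec("full_vc_z")) {
  pinned <- setdiff(ddm_param_names(), spec$free)
  if (any(p[pinned] != 0))
    stop("parameters pinned by the model spec must be zero: ",
         paste(pinned[p[pinned] != 0], collapse = ", "))
  cells <- expand.grid(mask = c(0L, 1L), emotion = main_emotion_levels(),
                       KEEP.OUT.ATTRS = FALSE)
  cells <- cells[order(cells$mask, cells$emotion), , drop = FALSE]
  rownames(cells) <- NULL
  cells$k <- cells$emotion / 100
  cells$v <- drift_rate(p, cells$k, cells$mask)
  cells$a <- p[["a"]]
  cells$tau <- p[["tau"]]
  cells$z <- start_point(p, cells$mask)
  cells$Ter <- nondecision(p, cells$mask)
  cells
}
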