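#' Canonical study-condition mixture models
#'
#' Mixture models parameterized by the fitted amplitudes and lifetimes of
#' the Hfq/amiE single-molecule study conditions, used as the default
#' ground truths for the synthetic-data generator:
#' \describe{
#'   \item{`amiE102`}{full-length substrate, Hfq alone: weights
#'     (0.56, 0.44) on lifetimes (2 s, 60 s) — unstable complexes slightly
#'     more common than stable ones.}
#'   \item{`amiE102_Crc`}{with 100 nM Crc: weights (0.30, 0.70), same
#'     lifetimes — Crc shifts the equilibrium towards stable complexes
#'     without changing the lifetimes.}
#'   \item{`amiE_3ARNmut`}{downstream ARN-motif mutant, Hfq alone: weights
#'     (0.81, 0.05, 0.14) on lifetimes (0.4 s, 2 s, 60 s) — mostly
#'     transient, non-specific binding with a 0.14 long-lived fraction.}
#' }
#'
#' @return A named list of [mixture_model()] objects.
#' @examples
#' study_models()$amiE102
#' @export
study_models <- function() {
  list(
    amiE102 = mixture_model(c(0.56, 0.44), c(2, 60)),
    amiE102_Crc = mixture_model(c(0.30, 0.70), c(2, 60)),
    amiE_3ARNmut = mixture_model(c(0.81, 0.05, 0.14), c(0.4, 2, 60))
  )
}

#' Canonical acquisition constants
#'
#' The standard acquisition settings of the single-molecule assay: 0.1 s
#' camera frames, 3-minute (180 s) recordings, minimum resolvable interval
#' of one frame, and a Cy5 photobleaching lifetime of 173 s.
#'
#' @return A list with `frame_interval`, `t_min`, `t_max` and
#'   `bleach_lifetime`, all in seconds.
#' @export
acquisition_defaults <- function() {
  list(frame_interval = 0.1, t_min = 0.1, t_max = 180, bleach_lifetime = 173)
}
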