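#' Construct a connection growth model
#'
#' A growth model describes how the generating absolute partial correlation
#' of one connection rises with postmenstrual age (PMA): a logistic curve
#' from `floor` toward `adult_target`, centred at `onset_pma` with slope
#' `rate`. These curves are the synthetic generator's ground truth; they
#' emulate the rise in functional connectivity over the equivalent of the
#' third gestational trimester.
#'
#' @param connection_id Connection identifier (see [connection_index()]).
#' @param adult_target Asymptotic absolute partial correlation, in `[0, 0.9]`.
#' @param onset_pma Curve midpoint, weeks PMA.
#' @param rate Logistic slope, 1/weeks (`>= 0`).
#' @param floor Early-age absolute partial correlation, in `[0, adult_target]`.
#' @return A list of class `growth_model`.
#' @export
growth_model <- function(connection_id, adult_target, onset_pma, rate, floor = 0) {
  stopifnot(is.numeric(adult_target), length(adult_target) == 1L,
            is.numeric(onset_pma), length(onset_pma) == 1L,
            is.numeric(rate), length(rate) == 1L,
            is.numeric(floor), length(floor) == 1L)
  if (adult_target < 0 || adult_target > 0.9) {
    stop("adult_target must lie in [0, 0.9], got ", adult_target)
  }
  if (floor < 0 || floor > adult_target) {
    stop("floor must lie in [0, adult_target]")
  }
  if (rate < 0) stop("rate must be >= 0")
  structure(
    list(connection_id = connection_id, adult_target = adult_target,
         onset_pma = onset_pma, rate = rate, floor = floor),
    class = "growth_model"
  )
}

#' Evaluate a growth model at a given PMA
#'
#' Returns `floor + (adult_target - floor) * logistic(rate * (pma -
#' onset_pma))`. The value is nondecreasing in PMA, equals the midpoint
#' between floor and adult target at `pma = onset_pma`, and approaches
#' `adult_target` asymptotically.
#'
#' @param model A [growth_model()].
#' @param pma Weeks PMA (vectorised; must be `> 0`).
#' @return Numeric vector of generating absolute partial correlations.
#' @export
growth_target <- function(model, pma) {
  stopifnot(inherits(model, "growth_model"))
  if (any(pma <= 0)) stop("pma must be positive")
  model$floor + (model$adult_target - model$floor) *
    plogis(model$rate * (pma - model$onset_pma))
}

# Per-subnetwork growth parameters used by the default models. The scale of
# the adult targets keeps the implied precision matrix positive definite by
# construction (see build_precision_matrix) and is in the range typical of
# absolute partial correlations between cortical ROI signals. Onsets are
# staggered sensory < affective < cognitive so the generated cohort matures
# sensory-first, the pattern the statistics modules are designed to detect;
# connections outside all three subnetworks get a weak, intermediate-onset
# "background" curve.
.default_growth_pars <- list(
  thalamus_si = list(adult_target = 0.30, onset_pma = 28.0, rate = 0.4, floor = 0.05),
  sensory     = list(adult_target = 0.22, onset_pma = 31.0, rate = 0.6, floor = 0.02),
  affective   = list(adult_target = 0.18, onset_pma = 34.5, rate = 0.6, floor = 0.02),
  cognitive   = list(adult_target = 0.15, onset_pma = 38.0, rate = 0.6, floor = 0.02),
  background  = list(adult_target = 0.10, onset_pma = 36.0, rate = 0.5, floor = 0.02)
)

#' Default growth models for all 66 connections
#'
#' Assigns each connection the growth curve of the earliest-maturing
#' subnetwork it belongs to (priority sensory, then affective, then
#' cognitive); connections outside every subnetwork get a weak background
#' curve, and the thalamus-SI connection gets an early-onset curve of its
#' own since it is already functional in the youngest preterm infants and
#' serves as the presence reference downstream.
#'
#' @return Named list of [growth_model()] objects, one per connection id.
#' @export
default_growth_models <- function() {
  idx <- connection_index()
  models <- lapply(seq_len(nrow(idx)), function(i) {
    a <- idx$roi_a[i]; b <- idx$roi_b[i]
    pars <-
      if (all(c(a, b) %in% c("thalamus", "SI"))) {
        .default_growth_pars$thalamus_si
      } else if (all(c(a, b) %in% .subnetwork_rois$sensory)) {
        .default_growth_pars$sensory
      } else if (all(c(a, b) %in% .subnetwork_rois$affective)) {
        .default_growth_pars$affective
      } else if (all(c(a, b) %in% .subnetwork_rois$cognitive)) {
        .default_growth_pars$cognitive
      } else {
        .default_growth_pars$background
      }
    growth_model(idx$connection_id[i], pars$adult_target, pars$onset_pma,
                 pars$rate, pars$floor)
  })
  setNames(models, idx$connection_id)
}
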