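#' Default latent-trait calibration constants
#'
#' The synthetic cohort is driven by a single latent schizotypy trait
#' \eqn{z \sim N(0, 1)} that loads on tPAS item ratings, PAS endorsements,
#' reaction-time slowing and time-map duration. The constants below were
#' fixed once, by large-n simulation, so that with default specs the scale
#' score means/SDs, the scale inter-correlation, the score-RT correlation
#' and the score-duration correlation of a large generated cohort match the
#' published group statistics the generator is meant to emulate. They are
#' the single source of truth: every `*_spec()` default reads from here.
#'
#' Fields:
#' \describe{
#'   \item{tpas_baseline}{Latent mean of a tPAS item rating before
#'     rounding/clipping to the 1-10 response scale.}
#'   \item{tpas_loading}{Item-rating change (rating units) per trait SD.}
#'   \item{tpas_item_sd}{Item-specific noise SD (rating units).}
#'   \item{pas_intercept}{Logit of the endorsement probability of a PAS
#'     item at trait z = 0.}
#'   \item{pas_loading}{Logit change per trait SD.}
#'   \item{rt_trait_slope}{Reaction-time slowing, ms per trait SD.}
#'   \item{duration_trait_slope}{Time-map duration increase, ms per trait
#'     SD, common to all conditions.}
#' }
#'
#' @return Named list of calibration constants.
#' @export
trait_calibration <- function() {
  list(
    tpas_baseline        = 3.368,
    tpas_loading         = 2.002,
    tpas_item_sd         = 6.389,
    pas_intercept        = -1.674,
    pas_loading          = 0.494,
    rt_trait_slope       = 133,
    duration_trait_slope = 6.8
  )
}
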