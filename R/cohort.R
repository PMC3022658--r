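#' Specification of a synthetic questionnaire cohort
#'
#' A single latent schizotypy trait per subject drives tPAS item ratings
#' (discretised Gaussians clipped to the 1-10 response scale) and PAS
#' endorsements (Bernoulli with a logistic link). Defaults come from
#' [trait_calibration()] and emulate a 170-subject behavioural cohort with
#' equal numbers of women and men.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param sex_ratio Fraction of women.
#' @param trait_mean,trait_sd Latent trait distribution parameters.
#' @param tpas_baseline,tpas_loading,tpas_item_sd tPAS item model: latent
#'   item value is `baseline + loading * z + N(0, item_sd)`, rounded and
#'   clipped to 1..10.
#' @param pas_intercept,pas_loading PAS item model: endorsement probability
#'   is `plogis(intercept + loading * z)`.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 170,
                        sex_ratio = 0.5,
                        trait_mean = 0,
                        trait_sd = 1,
                        tpas_baseline = trait_calibration()$tpas_baseline,
                        tpas_loading = trait_calibration()$tpas_loading,
                        tpas_item_sd = trait_calibration()$tpas_item_sd,
                        pas_intercept = trait_calibration()$pas_intercept,
                        pas_loading = trait_calibration()$pas_loading) {
  n_subjects <- stop_if_not_count(n_subjects, "n_subjects", lower = 2L)
  stop_if_not_scalar_number(sex_ratio, "sex_ratio", 0, 1)
  stop_if_not_scalar_number(trait_mean, "trait_mean")
  stop_if_not_scalar_number(trait_sd, "trait_sd", lower = 0)
  stop_if_not_scalar_number(tpas_baseline, "tpas_baseline")
  stop_if_not_scalar_number(tpas_loading, "tpas_loading")
  stop_if_not_scalar_number(tpas_item_sd, "tpas_item_sd", lower = 0)
  stop_if_not_scalar_number(pas_intercept, "pas_intercept")
  stop_if_not_scalar_number(pas_loading, "pas_loading")
  structure(list(
    n_subjects = n_subjects, sex_ratio = sex_ratio,
    trait_mean = trait_mean, trait_sd = trait_sd,
    tpas_baseline = tpas_baseline, tpas_loading = tpas_loading,
    tpas_item_sd = tpas_item_sd,
    pas_intercept = pas_intercept, pas_loading = pas_loading
  ), class = "cohort_spec")
}

#' Generate a synthetic questionnaire cohort
#'
#' Draws one latent trait per subject and simulates the 20 tPAS ratings and
#' 35 PAS true/false endorsements from it (see [cohort_spec()] for the item
#' models). Women are listed first up to `round(sex_ratio * n)`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed for reproducibility.
#' @return A tibble with one row per subject: `subject`, `sex`
#'   (`"F"`/`"M"`), `trait`, item columns `tpas_01`..`tpas_20` (integers
#'   1-10) and `pas_01`..`pas_35` (logical).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_subjects = 20), seed = 1)
#' dplyr::count(cohort, sex)
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  n_f <- round(spec$sex_ratio * n)
  with_seed_or_not(seed, {
    z <- rnorm(n, spec$trait_mean, spec$trait_sd)
    latent <- spec$tpas_baseline + spec$tpas_loading * z
    tpas <- matrix(
      pmin(10L, pmax(1L, as.integer(round(
        rep(latent, each = 20L) + rnorm(20L * n, 0, spec$tpas_item_sd)
      )))),
      nrow = n, ncol = 20L, byrow = TRUE
    )
    p_endorse <- plogis(spec$pas_intercept + spec$pas_loading * z)
    pas <- matrix(
      rbinom(35L * n, 1L, rep(p_endorse, each = 35L)) == 1L,
      nrow = n, ncol = 35L, byrow = TRUE
    )
    colnames(tpas) <- sprintf("tpas_%02d", 1:20)
    colnames(pas) <- sprintf("pas_%02d", 1:35)
    dplyr::bind_cols(
      tibble::tibble(
        subject = sprintf("S%04d", seq_len(n)),
        sex = factor(rep(c("F", "M"), c(n_f, n - n_f)), levels = c("F", "M")),
        trait = z
      ),
      tibble::as_tibble(tpas),
      tibble::as_tibble(pas)
    )
  })
}
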