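#' Specification of synthetic task behaviour
#'
#' Trial-level reaction times and accuracy for the self-projection-in-time
#' task (conditions Past / Now / Future). Per trial,
#' `RT = base * lognormal(mean 1)`, where
#' `base = condition mean + subject offset + rt_trait_slope * z` and the
#' mean-one lognormal has arithmetic SD `rt_sd_within` around `base`; so
#' with all noise and slope at zero every trial equals its condition mean.
#' Default condition means and error rates are the published group values
#' for this task; the trait slope is calibrated so the score-RT
#' correlation of a large cohort matches the published one.
#'
#' @param condition_rt_means Named vector of RT means (ms) for Past, Now,
#'   Future.
#' @param rt_sd_between Between-subject SD of the subject RT offset (ms).
#' @param rt_sd_within Within-subject trial-to-trial RT SD (ms).
#' @param error_rates Named vector of error probabilities per condition.
#' @param trait_rt_slope RT slowing in ms per latent-trait SD.
#' @param n_trials_per_condition Trials per subject and condition (two
#'   120-stimulus blocks per condition by default).
#' @return A list of class `behavior_spec`.
#' @export
behavior_spec <- function(condition_rt_means = c(Past = 475.3, Now = 401.1,
                                                 Future = 480.1),
                          rt_sd_between = 70,
                          rt_sd_within = 120,
                          error_rates = c(Past = 0.092, Now = 0.061,
                                          Future = 0.098),
                          trait_rt_slope = trait_calibration()$rt_trait_slope,
                          n_trials_per_condition = 240) {
  conds <- task_conditions()
  if (!setequal(names(condition_rt_means), conds)) {
    abort("`condition_rt_means` needs exactly the names Past, Now, Future.")
  }
  if (!setequal(names(error_rates), conds)) {
    abort("`error_rates` needs exactly the names Past, Now, Future.")
  }
  if (any(condition_rt_means <= 0)) abort("All RT means must be positive.")
  if (any(error_rates < 0 | error_rates > 1)) {
    abort("Error rates must be probabilities in [0, 1].")
  }
  stop_if_not_scalar_number(rt_sd_between, "rt_sd_between", lower = 0)
  stop_if_not_scalar_number(rt_sd_within, "rt_sd_within", lower = 0)
  stop_if_not_scalar_number(trait_rt_slope, "trait_rt_slope")
  n_trials_per_condition <- stop_if_not_count(n_trials_per_condition,
                                              "n_trials_per_condition")
  structure(list(
    condition_rt_means = condition_rt_means[conds],
    rt_sd_between = rt_sd_between, rt_sd_within = rt_sd_within,
    error_rates = error_rates[conds], trait_rt_slope = trait_rt_slope,
    n_trials_per_condition = n_trials_per_condition
  ), class = "behavior_spec")
}

#' Generate synthetic trial data for a cohort
#'
#' One row per trial per subject and condition. Event category (self vs
#' non-self world events) and relative direction (backward vs forward in
#' time from the imagined time-point) are balanced as in the task design;
#' they carry no simulated effects but are retained for downstream
#' grouping.
#'
#' @param subjects Cohort tibble from [generate_cohort()] (needs `subject`
#'   and `trait` columns).
#' @param spec A [behavior_spec()].
#' @param seed Integer seed.
#' @return Trial tibble: `subject`, `condition`, `event_category`,
#'   `direction`, `rt` (ms, > 0), `correct` (logical).
#' @export
generate_behavior <- function(subjects, spec = behavior_spec(), seed = NULL) {
  stopifnot(inherits(spec, "behavior_spec"))
  stopifnot(all(c("subject", "trait") %in% names(subjects)))
  n_sub <- nrow(subjects)
  n_tr <- spec$n_trials_per_condition
  conds <- task_conditions()
  with_seed_or_not(seed, {
    offsets <- rnorm(n_sub, 0, spec$rt_sd_between)
    rows <- purrr::map(seq_len(n_sub), function(i) {
      purrr::map(conds, function(cond) {
        base <- spec$condition_rt_means[[cond]] + offsets[i] +
          spec$trait_rt_slope * subjects$trait[i]
        if (base <= 0) base <- 1   # RTs must stay positive
        if (spec$rt_sd_within > 0) {
          sigma <- sqrt(log1p((spec$rt_sd_within / base)^2))
          rt <- base * rlnorm(n_tr, -sigma^2 / 2, sigma)
        } else {
          rt <- rep(base, n_tr)
        }
        tibble::tibble(
          subject = subjects$subject[i],
          condition = cond,
          event_category = rep(c("self", "nonself"), length.out = n_tr),
          direction = rep(c("backward", "backward", "forward", "forward"),
                          length.out = n_tr),
          rt = rt,
          correct = runif(n_tr) >= spec$error_rates[[cond]]
        )
      })
    })
    out <- dplyr::bind_rows(purrr::flatten(rows))
    out$condition <- as_condition(out$condition)
    out
  })
}
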