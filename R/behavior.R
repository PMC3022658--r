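#' Summarise trials per subject and condition
#'
#' Mean reaction time over correct trials and error rate over all trials,
#' for every subject x condition cell. A cell without a single correct
#' trial has no defined RT mean and is reported as an error.
#'
#' @param trials Trial tibble ([generate_behavior()] or any table with
#'   `subject`, `condition`, `rt`, `correct`).
#' @return Tibble: `subject`, `condition`, `mean_rt` (ms, correct trials
#'   only), `error_rate`, `n_trials`, `n_correct`.
#' @export
summarize_trials <- function(trials) {
  stopifnot(all(c("subject", "condition", "rt", "correct") %in% names(trials)))
  if (any(trials$rt <= 0)) abort("Reaction times must be positive.")
  out <- trials |>
    dplyr::group_by(.data$subject, .data$condition) |>
    dplyr::summarise(
      mean_rt = mean(.data$rt[.data$correct]),
      error_rate = mean(!.data$correct),
      n_trials = dplyr::n(),
      n_correct = sum(.data$correct),
      .groups = "drop"
    )
  if (any(out$n_correct == 0L)) {
    bad <- out[out$n_correct == 0L, ]
    abort(sprintf(
      "No correct trials for subject %s, condition %s: RT mean undefined.",
      bad$subject[1], as.character(bad$condition[1])))
  }
  out
}

#' Within-subject ANOVA on a behavioural measure
#'
#' Runs the repeated-measures ANOVA with condition (Past/Now/Future) as
#' the within factor on a per-subject summary measure. RT and accuracy go
#' through the identical code path; only the measure column differs.
#'
#' @param summaries Output of [summarize_trials()] (or a per-map fit
#'   table).
#' @param measure `"mean_rt"` or `"error_rate"` (any numeric column).
#' @param ... Passed to [rm_anova()].
#' @return An [rm_anova()] object.
#' @export
behavior_anova <- function(summaries, measure = "mean_rt", ...) {
  rm_anova(summaries, measure, subject = "subject",
           condition = "condition", ...)
}

#' Correlate questionnaire scores with behaviour
#'
#' For each subject the three condition summaries are first averaged
#' (unweighted mean of the condition means — conditions have equal trial
#' counts by design), then the subject-level aggregate is correlated with
#' each scale score by Pearson product-moment correlation, two-tailed.
#'
#' @param summaries Output of [summarize_trials()].
#' @param scores Scored cohort ([score_scales()]): `subject`,
#'   `tpas_score`, `pas_score`.
#' @param measure `"mean_rt"` (default) or `"error_rate"`.
#' @return Tibble with one row per scale: `scale`, `measure`, `estimate`,
#'   `statistic`, `df`, `p.value`, `n`.
#' @export
correlate_scores_with_behavior <- function(summaries, scores,
                                           measure = "mean_rt") {
  stopifnot(measure %in% names(summaries))
  agg <- summaries |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(value = mean(.data[[measure]]), .groups = "drop")
  joined <- dplyr::inner_join(agg, scores, by = "subject")
  if (nrow(joined) < nrow(agg)) {
    abort("Some subjects in the summaries have no questionnaire scores.")
  }
  purrr::map_dfr(c(tpas = "tpas_score", pas = "pas_score"), function(col) {
    pearson_test(joined[[col]], joined$value)
  }, .id = "scale") |>
    dplyr::mutate(measure = measure, .after = "scale")
}
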