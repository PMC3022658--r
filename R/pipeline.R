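#' Configuration for a full simulated analysis run
#'
#' Bundles every stage's parameters with a master seed. Stage seeds are
#' derived deterministically from the master seed, so a config fully
#' determines every artifact of [run_all()].
#'
#' @param seed Master integer seed.
#' @param n_questionnaire Size of the questionnaire-only cohort.
#' @param n_eeg Size of the EEG cohort.
#' @param cohort Questionnaire generator spec ([cohort_spec()]); its
#'   `n_subjects` is overridden per sub-cohort.
#' @param behavior Behaviour generator spec ([behavior_spec()]).
#' @param ep EP generator spec ([ep_spec()]).
#' @param q_range Candidate template counts for model-order selection.
#' @param n_restarts Segmentation restarts.
#' @param polarity Polarity-sensitive microstate assignment.
#' @param do_source Run source localisation of the time-map.
#' @param grid_spacing_mm Source lattice spacing.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       n_questionnaire = 170,
                       n_eeg = 14,
                       cohort = cohort_spec(),
                       behavior = behavior_spec(),
                       ep = ep_spec(),
                       q_range = 2:12,
                       n_restarts = 20,
                       polarity = TRUE,
                       do_source = TRUE,
                       grid_spacing_mm = 12) {
  seed <- stop_if_not_count(seed, "seed", lower = 0L)
  structure(list(
    seed = seed, n_questionnaire = n_questionnaire, n_eeg = n_eeg,
    cohort = cohort, behavior = behavior, ep = ep,
    q_range = q_range, n_restarts = n_restarts, polarity = polarity,
    do_source = do_source, grid_spacing_mm = grid_spacing_mm
  ), class = "run_config")
}

# deterministic stage seeds below 2^31
stage_seed <- function(config, k) (config$seed %% 1000000L) * 101L + k

#' Run the complete simulated analysis
#'
#' Executes the whole chain on synthetic data: questionnaire cohort and
#' scale statistics; EEG-cohort behaviour with within-subject ANOVAs and
#' score-RT correlations; EP generation, group-average microstate
#' segmentation with cross-validation model-order selection, per-subject
#' competitive back-fitting, duration/GFP ANOVAs and score correlations
#' with the identified time-map; and (optionally) source localisation of
#' the time-map template. Identical config and seed give identical
#' reports.
#'
#' @param config A [run_config()].
#' @return List of class `run_report`; see the `print` method for the
#'   main components.
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cs <- config$cohort

  # -- questionnaire cohort -------------------------------------------------
  spec_q <- utils::modifyList(cs, list(n_subjects = config$n_questionnaire))
  class(spec_q) <- "cohort_spec"
  cohort_q <- generate_cohort(spec_q, seed = stage_seed(config, 1L))
  scores_q <- score_scales(cohort_q)
  scale_cor <- pearson_test(scores_q$tpas_score, scores_q$pas_score)
  sex_tests <- purrr::map_dfr(
    c(tpas = "tpas_score", pas = "pas_score"),
    function(col) {
      pooled_t_test(scores_q[[col]][scores_q$sex == "F"],
                    scores_q[[col]][scores_q$sex == "M"])
    }, .id = "scale")

  # -- EEG cohort: behaviour ------------------------------------------------
  spec_e <- utils::modifyList(cs, list(n_subjects = config$n_eeg))
  class(spec_e) <- "cohort_spec"
  cohort_e <- generate_cohort(spec_e, seed = stage_seed(config, 2L))
  scores_e <- score_scales(cohort_e)
  trials <- generate_behavior(cohort_e, config$behavior,
                              seed = stage_seed(config, 3L))
  summaries <- summarize_trials(trials)
  rt_anova <- behavior_anova(summaries, "mean_rt")
  acc_anova <- behavior_anova(summaries, "error_rate")
  rt_cor <- correlate_scores_with_behavior(summaries, scores_e, "mean_rt")
  acc_cor <- correlate_scores_with_behavior(summaries, scores_e, "error_rate")

  # -- EP microstates -------------------------------------------------------
  eps <- generate_ep_cohort(cohort_e, config$ep,
                            seed = stage_seed(config, 4L))
  group <- group_average_evokeds(eps)
  sel <- ms_select_q(group, q_range = config$q_range,
                     n_restarts = config$n_restarts,
                     seed = stage_seed(config, 5L),
                     polarity = config$polarity)
  fit_tbl <- backfit_cohort(eps, sel$fit$templates,
                            polarity = config$polarity)
  map_stats <- duration_statistics(fit_tbl)
  timemap <- identify_timemap(map_stats)
  timemap_cor <- correlate_map_stats(
    dplyr::filter(fit_tbl, .data$template == timemap), scores_e)
  timemap_durations <- fit_tbl |>
    dplyr::filter(.data$template == timemap) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(mean_duration_ms = mean(.data$duration_ms),
                     sd_duration_ms = sd(.data$duration_ms),
                     .groups = "drop")

  # -- source localisation --------------------------------------------------
  source_peaks <- NULL
  if (isTRUE(config$do_source)) {
    head <- head_model(eps$montage)
    grid <- source_grid(head, config$grid_spacing_mm)
    lf <- generate_forward(head, grid)
    op <- build_inverse(lf)
    est <- apply_inverse(op, sel$fit$templates[, timemap])
    source_peaks <- dplyr::filter(est$estimate, .data$peak)
  }

  structure(list(
    config = config,
    scores_questionnaire = scores_q,
    scale_correlation = scale_cor,
    sex_tests = sex_tests,
    scores_eeg = scores_e,
    behavior_summaries = summaries,
    rt_anova = rt_anova, accuracy_anova = acc_anova,
    rt_correlations = rt_cor, accuracy_correlations = acc_cor,
    ep_cohort = eps,
    model_selection = sel,
    backfit = fit_tbl,
    map_statistics = map_stats,
    timemap = timemap,
    timemap_durations = timemap_durations,
    timemap_correlations = timemap_cor,
    source_peaks = source_peaks
  ), class = "run_report")
}

#' Group-average evoked potentials per condition
#'
#' Averages an EP cohort's evokeds over subjects within each condition and
#' returns the condition averages concatenated along time (the input the
#' group-level segmentation expects), together with per-condition
#' matrices.
#'
#' @param eps An `ep_cohort`.
#' @return List: `concatenated` (channels x (3 x samples)), `by_condition`
#'   (named list of matrices), `sfreq`.
#' @export
group_average_evokeds <- function(eps) {
  tab <- eps$evokeds
  by_cond <- purrr::map(setNames(nm = task_conditions()), function(cond) {
    mats <- purrr::map(tab$evoked[tab$condition == cond], "data")
    Reduce(`+`, mats) / length(mats)
  })
  structure(list(concatenated = do.call(cbind, by_cond),
                 by_condition = by_cond,
                 sfreq = eps$spec$sampling_rate),
            class = "group_evoked")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Self-projection-in-time analysis report (synthetic cohort)\n")
  cat(sprintf("  master seed: %d\n", x$config$seed))
  cat(sprintf("  questionnaire cohort: n = %d; tPAS-PAS r = %.2f (p = %.3g)\n",
              nrow(x$scores_questionnaire), x$scale_correlation$estimate,
              x$scale_correlation$p.value))
  g <- glance(x$rt_anova)
  cat(sprintf("  RT ANOVA: F(%g, %g) = %.2f, p = %.3g\n",
              g$df1, g$df2, g$statistic, g$p.value))
  rt <- x$rt_correlations
  cat(sprintf("  tPAS-RT r = %.2f; PAS-RT r = %.2f\n",
              rt$estimate[rt$scale == "tpas"], rt$estimate[rt$scale == "pas"]))
  cat(sprintf("  selected q = %d maps; time-map = template %d\n",
              x$model_selection$best_q, x$timemap))
  print(x$timemap_durations)
  tc <- dplyr::filter(x$timemap_correlations, .data$measure == "duration_ms")
  cat(sprintf("  time-map duration: tPAS r = %.2f (p = %.3g); PAS r = %.2f (p = %.3g)\n",
              tc$estimate[tc$scale == "tpas"], tc$p.value[tc$scale == "tpas"],
              tc$estimate[tc$scale == "pas"], tc$p.value[tc$scale == "pas"]))
  if (!is.null(x$source_peaks)) {
    cat(sprintf("  time-map source peaks: %d (coordinates in mm relative to the sphere centre;\n    spherical model, no anatomical labels)\n",
                nrow(x$source_peaks)))
  }
  invisible(x)
}

#' Write the report's tables to delimited files
#'
#' Writes every tabular component of a [run_all()] report as tab-separated
#' text under `dir`, plus a small JSON provenance file when jsonlite is
#' available.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- list(
    scores_questionnaire = report$scores_questionnaire,
    sex_tests = report$sex_tests,
    scale_correlation = report$scale_correlation,
    scores_eeg = report$scores_eeg,
    behavior_summaries = report$behavior_summaries,
    rt_correlations = report$rt_correlations,
    accuracy_correlations = report$accuracy_correlations,
    rt_anova = glance(report$rt_anova),
    accuracy_anova = glance(report$accuracy_anova),
    cv_scores = report$model_selection$scores,
    backfit = report$backfit,
    map_statistics = report$map_statistics,
    timemap_durations = report$timemap_durations,
    timemap_correlations = report$timemap_correlations
  )
  if (!is.null(report$source_peaks)) tabs$source_peaks <- report$source_peaks
  for (nm in names(tabs)) {
    utils::write.table(tabs[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    prov <- list(seed = report$config$seed, timemap = report$timemap,
                 best_q = report$model_selection$best_q,
                 package_version = as.character(utils::packageVersion("timemapr")))
    jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(dir)
}
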