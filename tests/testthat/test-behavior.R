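test_that("noise-free behaviour generation hits condition means exactly", {
  co <- generate_cohort(cohort_spec(n_subjects = 4), seed = 2)
  sp <- behavior_spec(rt_sd_between = 0, rt_sd_within = 0,
                      trait_rt_slope = 0, n_trials_per_condition = 10,
                      error_rates = c(Past = 0, Now = 0, Future = 0))
  tr <- generate_behavior(co, sp, seed = 3)
  expect_true(all(tr$correct))
  by_cond <- tapply(tr$rt, tr$condition, unique)
  expect_equal(unname(by_cond[["Now"]]), 401.1)
  expect_equal(unname(by_cond[["Past"]]), 475.3)
  expect_equal(unname(by_cond[["Future"]]), 480.1)
})

test_that("trial summaries match a naive loop recomputation", {
  co <- generate_cohort(cohort_spec(n_subjects = 6), seed = 8)
  tr <- generate_behavior(co, behavior_spec(n_trials_per_condition = 40),
                          seed = 9)
  su <- summarize_trials(tr)
  expect_equal(nrow(su), 6 * 3)
  # independent oracle: explicit loop over cells
  for (i in sample(nrow(su), 5)) {
    rows <- tr[tr$subject == su$subject[i] &
                 tr$condition == su$condition[i], ]
    expect_equal(su$mean_rt[i], mean(rows$rt[rows$correct]))
    expect_equal(su$error_rate[i], sum(!rows$correct) / nrow(rows))
  }
  # arithmetic example: 120 trials, 12 incorrect -> error rate 0.10
  tr2 <- tibble::tibble(subject = "s1", condition = "Now",
                        rt = rep(400, 120),
                        correct = rep(c(FALSE, TRUE), c(12, 108)))
  expect_equal(summarize_trials(tr2)$error_rate, 0.10)
  expect_equal(summarize_trials(tr2)$mean_rt, 400)
})

test_that("summaries fail loudly on cells without correct trials", {
  tr <- tibble::tibble(subject = "s1", condition = "Past",
                       rt = rep(300, 4), correct = FALSE)
  expect_error(summarize_trials(tr), "s1.*Past")
})

test_that("rm_anova equals the explicit sum-of-squares decomposition", {
  withr::with_seed(31, {
    d <- tidyr::expand_grid(subject = sprintf("s%d", 1:6),
                            condition = c("A", "B", "C"))
    d$y <- rnorm(nrow(d), mean = rep(c(10, 12, 11), 6))
  })
  a <- rm_anova(d, "y")
  # independent oracle: textbook SS decomposition by explicit loops
  grand <- mean(d$y)
  ss_cond <- 0; ss_subj <- 0; ss_tot <- 0
  for (cc in unique(d$condition)) {
    ss_cond <- ss_cond + 6 * (mean(d$y[d$condition == cc]) - grand)^2
  }
  for (s in unique(d$subject)) {
    ss_subj <- ss_subj + 3 * (mean(d$y[d$subject == s]) - grand)^2
  }
  for (i in seq_len(nrow(d))) ss_tot <- ss_tot + (d$y[i] - grand)^2
  ss_res <- ss_tot - ss_cond - ss_subj
  f_hand <- (ss_cond / 2) / (ss_res / 10)
  expect_equal(a$statistic, f_hand)
  expect_equal(a$df1, 2)
  expect_equal(a$df2, 10)
  expect_equal(a$p.value, pf(f_hand, 2, 10, lower.tail = FALSE))
  # independent route: base R aov with an Error stratum
  fit <- stats::aov(y ~ condition + Error(subject), data = d)
  tab <- summary(fit)[["Error: Within"]][[1]]
  expect_equal(a$statistic, tab["condition", "F value"], tolerance = 1e-10)
  expect_equal(a$p.value, tab["condition", "Pr(>F)"], tolerance = 1e-10)
})

test_that("rm_anova removes subject effects and flags degenerate inputs", {
  withr::with_seed(12, {
    d <- tidyr::expand_grid(subject = sprintf("s%d", 1:5),
                            condition = c("A", "B", "C"))
    d$y <- rnorm(nrow(d))
  })
  base <- rm_anova(d, "y")
  shifted <- d
  shifted$y <- shifted$y + rep(c(100, -50, 3, 0, 7), each = 3)
  expect_equal(rm_anova(shifted, "y")$statistic, base$statistic)
  # equal condition means (with within-subject variation) -> F = 0
  flat <- d   # rows are subject-major: each triple sums per condition to 10
  flat$y <- c(1, 2, 3, 3, 1, 2, 2, 3, 1, 1, 2, 3, 3, 2, 1)
  expect_equal(rm_anova(flat, "y")$statistic, 0)
  # zero residual with a real effect: perfect separation, no division
  sep <- d; sep$y <- rep(c(1, 2, 3), 5)
  fit <- rm_anova(sep, "y")
  expect_true(fit$perfect_separation)
  expect_true(is.na(fit$statistic))
  # missing cell -> error
  expect_error(rm_anova(d[-1, ], "y"), "one observation per subject")
})

test_that("tidiers expose the decomposition and the test summary", {
  withr::with_seed(5, {
    d <- tidyr::expand_grid(subject = sprintf("s%d", 1:4),
                            condition = c("A", "B", "C"))
    d$y <- rnorm(nrow(d))
  })
  a <- rm_anova(d, "y")
  td <- tidy(a)
  expect_setequal(td$term, c("condition", "subject", "residual"))
  expect_equal(sum(td$sumsq), sum((d$y - mean(d$y))^2))
  g <- glance(a)
  expect_equal(g$statistic, a$statistic)
  expect_false(g$perfect_separation)
})

test_that("score-behaviour correlations recover exact and null cases", {
  co <- score_scales(generate_cohort(cohort_spec(n_subjects = 40), seed = 14))
  su <- tidyr::expand_grid(subject = co$subject,
                           condition = c("Past", "Now", "Future"))
  # aggregate identical to the score: r = 1
  su$mean_rt <- rep(co$tpas_score, each = 3)
  out <- correlate_scores_with_behavior(su, co, "mean_rt")
  expect_equal(out$estimate[out$scale == "tpas"], 1)
  # uncoupled aggregate: |r| small
  n <- 400
  co2 <- score_scales(generate_cohort(cohort_spec(n_subjects = n), seed = 15))
  sp0 <- behavior_spec(trait_rt_slope = 0, n_trials_per_condition = 20)
  su2 <- summarize_trials(generate_behavior(co2, sp0, seed = 16))
  out2 <- correlate_scores_with_behavior(su2, co2, "mean_rt")
  expect_lt(max(abs(out2$estimate)), 3 / sqrt(n))
})

test_that("RT and accuracy ANOVAs share one code path and report (2, 26) dfs", {
  co <- generate_cohort(cohort_spec(n_subjects = 14), seed = 17)
  tr <- generate_behavior(co, behavior_spec(n_trials_per_condition = 30),
                          seed = 18)
  su <- summarize_trials(tr)
  rt <- glance(behavior_anova(su, "mean_rt"))
  acc <- glance(behavior_anova(su, "error_rate"))
  expect_equal(c(rt$df1, rt$df2), c(2, 26))
  expect_equal(c(acc$df1, acc$df2), c(2, 26))
  expect_gt(rt$statistic, 1)  # planted condition effect present
})
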