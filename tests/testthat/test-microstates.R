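test_that("GFP has its closed-form values and invariances", {
  expect_equal(gfp(matrix(c(3, 3, 3), 3, 1)), 0)
  expect_equal(gfp(matrix(c(1, -1), 2, 1)), 1)
  expect_equal(gfp(matrix(c(2, 0), 2, 1)), 1)
  withr::with_seed(3, x <- matrix(rnorm(12 * 30), 12, 30))
  expect_equal(gfp(average_reference(x)), gfp(x))     # reference-free
  expect_equal(gfp(2.5 * x), 2.5 * gfp(x))            # linear in voltage
})

test_that("spatial correlation handles scaling, polarity and flat maps", {
  withr::with_seed(4, m <- rnorm(16))
  expect_equal(spatial_corr(m, 3 * m), 1)
  expect_equal(spatial_corr(m, -m), -1)
  expect_equal(spatial_corr(m, -m, polarity = FALSE), 1)
  tpl <- generate_template_maps(tiny_montage(16), 2, seed = 5)
  expect_lt(abs(spatial_corr(tpl[, 1], tpl[, 2])), 1e-10)
  expect_error(spatial_corr(m, rep(1, 16)), "flat")
})

test_that("segmentation recovers a noiseless two-template alternation", {
  d <- make_two_template_data()
  fit <- ms_segment(d$x, q = 2, n_restarts = 10, seed = 6)
  # labels equal the planted alternation up to template permutation
  perm <- if (fit$labels[1] == 1) c(1, 2) else c(2, 1)
  expect_equal(perm[fit$labels], d$labels)
  for (j in 1:2) {
    expect_gt(abs(spatial_corr(fit$templates[, perm == j], d$templates[, j])),
              0.999)
  }
  expect_gt(fit$gev, 0.999)
  expect_lt(max(abs(colMeans(fit$templates))), 1e-9)
  expect_equal(unname(sqrt(colMeans(fit$templates^2))), rep(1, 2))
})

test_that("q = 1 segmentation equals the dominant spatial eigenvector", {
  withr::with_seed(7, x <- average_reference(matrix(rnorm(12 * 40), 12, 40)))
  fit <- ms_segment(x, q = 1, n_restarts = 3, seed = 8, polarity = FALSE)
  # independent oracle: direct eigendecomposition of the map covariance
  ed <- eigen(tcrossprod(x), symmetric = TRUE)
  v1 <- ed$vectors[, 1]
  expect_gt(abs(cor(fit$templates[, 1], v1)), 1 - 1e-9)
  expect_equal(fit$gev, ed$values[1] / sum(ed$values), tolerance = 1e-9)
})

test_that("tiny-instance assignment matches exhaustive search", {
  # 8 samples, 4 channels, q = 2: enumerate all 2^8 labellings, score each
  # with the same objective (GEV with polarity-aligned mean templates)
  withr::with_seed(9, {
    tpl <- generate_template_maps(tiny_montage(4), 2, seed = 10)
    lab_true <- c(1, 1, 2, 2, 1, 2, 1, 2)
    x <- tpl[, lab_true] + matrix(rnorm(4 * 8, 0, 0.15), 4, 8)
    x <- average_reference(x)
  })
  gev_for <- function(labels) {
    tp <- vapply(1:2, function(j) {
      idx <- labels == j
      if (!any(idx)) return(rep(0, 4))
      m <- rowMeans(x[, idx, drop = FALSE])
      m <- m - mean(m)
      g <- sqrt(mean(m^2))
      if (g == 0) rep(0, 4) else m / g
    }, numeric(4))
    num <- 0; den <- 0
    for (t in 1:8) {
      v <- x[, t]
      r <- suppressWarnings(cor(v, tp[, labels[t]]))
      if (is.na(r)) r <- 0
      g2 <- mean((v - mean(v))^2)
      num <- num + g2 * r^2; den <- den + g2
    }
    num / den
  }
  best_gev <- 0
  for (code in 0:(2^8 - 1)) {
    labels <- as.integer(intToBits(code))[1:8] + 1L
    g <- gev_for(labels)
    if (g > best_gev) best_gev <- g
  }
  fit <- ms_segment(x, q = 2, n_restarts = 50, seed = 11)
  expect_equal(fit$gev, best_gev, tolerance = 1e-8)
})

test_that("the cross-validation criterion equals its long-hand evaluation", {
  withr::with_seed(12, x <- average_reference(matrix(rnorm(10 * 25), 10, 25)))
  fit <- ms_segment(x, q = 3, n_restarts = 5, seed = 13)
  got <- ms_cv(fit$templates, x, labels = fit$labels)
  # long-hand: unit-norm templates, residual power per sample
  n <- 10
  a <- apply(fit$templates, 2, function(v) v / sqrt(sum(v^2)))
  acc <- 0
  for (t in 1:25) {
    u <- x[, t]
    acc <- acc + sum(u^2) - sum(a[, fit$labels[t]] * u)^2
  }
  sigma2_hand <- acc / (25 * (n - 1))
  expect_equal(got$sigma2, sigma2_hand)
  expect_equal(got$cv, sigma2_hand * ((n - 1) / (n - 1 - 3))^2)
  expect_error(ms_cv(matrix(rnorm(10 * 9), 10, 9), x), "q < N - 1")
})

test_that("the CV penalty grows strictly with q at fixed residual variance", {
  n <- 20
  pen <- function(q) ((n - 1) / (n - 1 - q))^2
  expect_true(all(diff(vapply(1:10, pen, numeric(1))) > 0))
})

test_that("model-order selection recovers a planted two-map structure", {
  d <- make_two_template_data(n_channels = 12, block = 10, n_blocks = 5)
  sel <- ms_select_q(d$x, q_range = 1:6, n_restarts = 8, seed = 14)
  expect_equal(sel$best_q, 2)
  # argmin rule agrees on noiseless planted-order data
  sel2 <- ms_select_q(d$x, q_range = 1:6, n_restarts = 8, seed = 14,
                      rule = "argmin")
  expect_equal(sel2$best_q, 2)
  expect_lt(sel$scores$sigma2[sel$scores$q == 2], 1e-20)
})

test_that("back-fitting a pure-template evoked gives it the whole window", {
  tpl <- generate_template_maps(tiny_montage(16), 3, seed = 15)
  x <- tpl[, 2] %o% rep(1.5, 40)
  bf <- ms_backfit(tpl, x, sfreq = 100)
  expect_equal(bf$fit$duration_ms[2], 40 * 10)
  expect_equal(bf$fit$duration_ms[-2], c(0, 0))
  expect_true(all(is.na(bf$fit$mean_gfp[-2])))
  # durations partition the window
  withr::with_seed(16, y <- average_reference(matrix(rnorm(16 * 40), 16, 40)))
  bf2 <- ms_backfit(tpl, y, sfreq = 100)
  expect_equal(sum(bf2$fit$duration_ms), 400)
  # planted-template identity on noiseless data
  d <- make_two_template_data()
  bf3 <- ms_backfit(d$templates, d$x, sfreq = 100)
  expect_equal(bf3$labels, d$labels)
})

test_that("back-fit windows and minimum-duration smoothing behave", {
  tpl <- generate_template_maps(tiny_montage(8), 2, seed = 17)
  x <- cbind(tpl[, c(1, 1, 1, 1)], tpl[, 2], tpl[, c(1, 1, 1)]) * 2
  # lone one-sample run of template 2 is absorbed at min duration 2
  bf <- ms_backfit(tpl, x, sfreq = 1000, min_duration_samples = 2)
  expect_equal(bf$fit$n_samples, c(8L, 0L))
  bf2 <- ms_backfit(tpl, x, sfreq = 1000)
  expect_equal(bf2$fit$n_samples, c(7L, 1L))
  # half-open window selects the right samples
  bf3 <- ms_backfit(tpl, x, sfreq = 1000, window_ms = c(2, 6))
  expect_equal(sum(bf3$fit$n_samples), 4L)
  expect_equal(which(!is.na(bf3$labels)), 3:6)
  expect_error(ms_backfit(tpl, x, sfreq = 1000, window_ms = c(50, 60)),
               "Empty")
})

test_that("planted time-map durations are recovered within two samples", {
  # parameter recovery across seeded cohorts at reduced size
  errs <- vapply(1:6, function(s) {
    co <- generate_cohort(cohort_spec(n_subjects = 6), seed = 100 + s)
    spec <- ep_spec(n_channels = 24, sampling_rate = 512)
    eps <- generate_ep_cohort(co, spec, seed = 200 + s)
    grp <- group_average_evokeds(eps)
    fit <- ms_segment(grp, q = 6, n_restarts = 10, seed = 300 + s)
    ft <- backfit_cohort(eps, fit$templates)
    tm <- identify_timemap(duration_statistics(ft, "duration_ms"))
    ft_tm <- ft[ft$template == tm, ]
    ord <- order(ft_tm$subject, ft_tm$condition)
    truth <- eps$evokeds[order(eps$evokeds$subject, eps$evokeds$condition), ]
    mean(abs(ft_tm$duration_ms[ord] - truth$planted_duration_ms))
  }, numeric(1))
  expect_lt(mean(errs), 2 * 1000 / 512)
})

test_that("map statistics and correlations find the planted coupling", {
  co <- score_scales(generate_cohort(cohort_spec(n_subjects = 30), seed = 40))
  spec <- ep_spec(n_channels = 24, sampling_rate = 512)
  eps <- generate_ep_cohort(co, spec, seed = 41)
  grp <- group_average_evokeds(eps)
  fit <- ms_segment(grp, q = 6, n_restarts = 10, seed = 42)
  ft <- backfit_cohort(eps, fit$templates)
  st <- duration_statistics(ft)
  expect_setequal(unique(st$measure), c("duration_ms", "mean_gfp"))
  tm <- identify_timemap(st)
  st_tm <- st[st$template == tm & st$measure == "duration_ms", ]
  expect_lt(st_tm$p.value, 0.001)
  cc <- correlate_map_stats(ft[ft$template == tm, ], co)
  r_tpas <- cc$estimate[cc$measure == "duration_ms" & cc$scale == "tpas"]
  expect_gt(r_tpas, 0.2)   # positive trait coupling visible at n = 30
  # a duration vector equal to the score vector correlates perfectly
  ft_id <- tidyr::expand_grid(subject = co$subject,
                              condition = c("Past", "Now", "Future"))
  ft_id$template <- 1L
  ft_id$duration_ms <- rep(co$tpas_score, each = 3)
  cc_id <- correlate_map_stats(ft_id, co, measures = "duration_ms")
  expect_equal(cc_id$estimate[cc_id$scale == "tpas"], 1)
})
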