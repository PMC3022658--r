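test_that("amplitude rejection drops exactly the artifact epochs", {
  clean <- make_epoch_fixture(artifact_epochs = integer(0))
  out <- reject_epochs(clean, 100)
  expect_true(all(out$kept))
  expect_equal(nrow(out$log), 0)

  planted <- c(2, 5, 9)
  dirty <- make_epoch_fixture(artifact_epochs = planted)
  out2 <- reject_epochs(dirty, 100)
  expect_equal(which(!out2$kept), planted)
  expect_equal(dim(out2$epochs)[1], dim(dirty)[1] - length(planted))
  expect_equal(sort(out2$log$epoch), planted)
  expect_true(all(out2$log$max_abs_uv > 100))

  all_bad <- make_epoch_fixture(artifact_epochs = 1:12)
  expect_error(reject_epochs(all_bad, 100), "All epochs")
})

test_that("band-pass preserves the passband and kills out-of-band energy", {
  sfreq <- 2048
  t <- seq(0, 1, by = 1 / sfreq)
  mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
  x10 <- rbind(sin(2 * pi * 10 * t), cos(2 * pi * 10 * t))
  y10 <- bandpass_filter(x10, sfreq)
  ratio10 <- sqrt(mean(y10[1, mid]^2) / mean(x10[1, mid]^2))
  expect_gt(ratio10, 0.95)
  expect_lt(ratio10, 1.05)

  x100 <- rbind(sin(2 * pi * 100 * t), sin(2 * pi * 100 * t))
  y100 <- bandpass_filter(x100, sfreq)
  ratio100 <- sqrt(mean(y100[1, mid]^2) / mean(x100[1, mid]^2))
  expect_lt(ratio100, 0.2)   # > 80% attenuation
  # oracle: the filter's own frequency response at 100 Hz, applied twice
  bf <- signal::butter(2, c(1, 40) / (sfreq / 2), type = "pass")
  h <- signal::freqz(bf$b, bf$a, Fs = sfreq, n = 4096)
  h100 <- abs(h$h[which.min(abs(h$f - 100))])^2   # forward-backward
  expect_equal(ratio100, h100, tolerance = 0.25 * h100 + 0.005)

  # DC is removed by the 1 Hz high-pass edge (away from edge transients)
  dc <- matrix(5, 2, 3 * 2048)
  dc_mid <- bandpass_filter(dc, sfreq)[, 2048:4096]
  expect_lt(max(abs(dc_mid)), 0.1)
  expect_error(bandpass_filter(x10, sfreq, low = 0), "Nyquist")
  expect_error(bandpass_filter(x10, sfreq, high = 2000), "Nyquist")
})

test_that("average referencing zeroes the spatial mean and is idempotent", {
  withr::with_seed(2, x <- matrix(rnorm(8 * 40), 8, 40))
  y <- average_reference(x)
  expect_lt(max(abs(colMeans(y))), 1e-9)
  expect_equal(average_reference(y), y)
  expect_equal(average_reference(matrix(5, 4, 3)), matrix(0, 4, 3))
  expect_error(average_reference(matrix(1, 1, 3)), "2 channels")
})

test_that("epoch averaging reduces noise around a planted template", {
  expect_equal(average_epochs(make_epoch_fixture(n_epochs = 1)),
               matrix(make_epoch_fixture(n_epochs = 1)[1, , ], 8, 64))
  v <- matrix(rnorm(8 * 64), 8, 64)
  two <- array(c(v, -v), dim = c(8, 64, 2))
  two <- aperm(two, c(3, 1, 2))
  expect_equal(average_epochs(two), matrix(0, 8, 64), tolerance = 1e-12)
  # noisy copies of a template: evoked correlates better than any epoch
  withr::with_seed(77, {
    tpl <- matrix(rnorm(8 * 64), 8, 64)
    eps <- array(0, dim = c(10, 8, 64))
    for (e in 1:10) eps[e, , ] <- tpl + rnorm(8 * 64, 0, 2)
  })
  ev <- average_epochs(eps)
  r_ev <- cor(as.vector(ev), as.vector(tpl))
  r_single <- vapply(1:10, function(e) {
    cor(as.vector(eps[e, , ]), as.vector(tpl))
  }, numeric(1))
  expect_gt(r_ev, max(r_single))
  # correct-only selection
  flags <- rep(c(TRUE, FALSE), 5)
  sel <- average_epochs(eps, flags)
  expect_equal(sel, apply(eps[flags, , ], c(2, 3), mean))
  expect_error(average_epochs(eps, rep(FALSE, 10)), "No qualifying")
})

test_that("the 0-800 ms window at 2048 Hz spans 1638 samples", {
  expect_equal(ep_n_samples(ep_spec()), 1638L)
})

test_that("averaging and re-referencing commute (linearity)", {
  withr::with_seed(9, eps <- array(rnorm(6 * 8 * 32), dim = c(6, 8, 32)))
  a <- average_reference(average_epochs(eps))
  reref <- eps
  for (e in 1:6) reref[e, , ] <- average_reference(matrix(eps[e, , ], 8, 32))
  b <- average_epochs(reref)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("the preprocessing pipeline logs its provenance", {
  eps <- make_epoch_fixture(artifact_epochs = 3)
  ev <- preprocess_epochs(eps, sfreq = 512,
                          correct = rep(TRUE, 12), condition = "Now",
                          subject = "s1")
  expect_s3_class(ev, "evoked")
  expect_equal(ev$reference, "average")
  expect_length(ev$log, 4)
  expect_match(ev$log[1], "11/12 kept")
  expect_lt(max(abs(colMeans(ev$data))), 1e-9)
  expect_equal(nrow(ev$rejection), 1)
})
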