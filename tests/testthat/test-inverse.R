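test_that("with no neighbourhood the operator is the minimum-norm inverse", {
  fx <- make_forward_fixture(n_channels = 32, spacing_mm = 30)
  # disabled neighbourhood: A = 0, W = I
  op <- build_inverse(fx$lf, lambda = 1e-3 * mean(diag(tcrossprod(fx$lf$L))),
                      exponent = 0, neighbor_radius = 0)
  withr::with_seed(21, map <- as.numeric(fx$lf$L %*% rnorm(ncol(fx$lf$L), 0, 1e-9)))
  est <- apply_inverse(op, map)
  # independent oracle: direct regularised pseudoinverse L'(LL' + lambda I)^-1
  L <- fx$lf$L
  j_direct <- t(L) %*% solve(L %*% t(L) + diag(op$lambda, nrow(L)), map)
  j_got <- as.numeric(t(cbind(est$estimate$jx, est$estimate$jy,
                              est$estimate$jz)))
  expect_equal(j_got, as.numeric(j_direct), tolerance = 1e-8)
})

test_that("estimates shrink monotonically toward zero as lambda grows", {
  fx <- make_forward_fixture(n_channels = 24, spacing_mm = 35)
  op <- build_inverse(fx$lf)
  withr::with_seed(22, map <- as.numeric(fx$lf$L[, 5]))
  norms <- vapply(c(1, 100, 10000) * op$lambda, function(l) {
    sqrt(sum(apply_inverse(op, map, lambda = l)$estimate$magnitude^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("the inverse is linear and null on a zero map", {
  fx <- make_forward_fixture(n_channels = 24, spacing_mm = 35)
  op <- build_inverse(fx$lf)
  n_e <- nrow(fx$lf$L)
  zero <- apply_inverse(op, rep(0, n_e))
  expect_true(all(zero$estimate$magnitude == 0))
  withr::with_seed(23, {
    m1 <- rnorm(n_e); m2 <- rnorm(n_e)
  })
  j <- function(m) with(apply_inverse(op, m)$estimate, c(jx, jy, jz))
  expect_equal(j(2 * m1 - 3 * m2), 2 * j(m1) - 3 * j(m2), tolerance = 1e-9)
  expect_error(apply_inverse(op, rep(0, n_e + 1)), "electrode count")
})

test_that("operator construction is deterministic and validates the grid", {
  fx <- make_forward_fixture(n_channels = 24, spacing_mm = 35)
  op1 <- build_inverse(fx$lf)
  op2 <- build_inverse(fx$lf)
  expect_identical(op1$Winv_Lt, op2$Winv_Lt)
  expect_true(all(is.finite(op1$Winv_Lt)))
  expect_error(build_inverse(fx$lf, neighbor_radius = 1e-6),
               "no neighbours")  # exponent -2 with empty neighbourhoods
})

test_that("a noiseless superficial dipole is localised within the grid spacing", {
  fx <- make_forward_fixture(n_channels = 64, spacing_mm = 25)
  op <- build_inverse(fx$lf, lambda = 1e-6 * mean(diag(tcrossprod(fx$lf$L))))
  bench <- localization_benchmark(fx$lf, op, n_sources = 12, seed = 3)
  expect_lte(stats::median(bench$error_mm), 25)
  # fixed seed reproduces the table exactly
  bench2 <- localization_benchmark(fx$lf, op, n_sources = 12, seed = 3)
  expect_identical(bench, bench2)
})

test_that("localisation degrades with sensor noise in expectation", {
  fx <- make_forward_fixture(n_channels = 48, spacing_mm = 28)
  op <- build_inverse(fx$lf, lambda = 1e-4 * mean(diag(tcrossprod(fx$lf$L))))
  med <- vapply(c(0, 0.5, 2), function(ns) {
    b <- localization_benchmark(fx$lf, op, n_sources = 15,
                                noise_sd = ns, seed = 5)
    mean(b$error_mm)
  }, numeric(1))
  expect_lte(med[1], med[3] + 1e-9)
  expect_lte(med[1], stats::median(med) + 28)  # no catastrophic reversal
})

test_that("deep sources localise worse than superficial ones", {
  fx <- make_forward_fixture(n_channels = 48, spacing_mm = 28)
  op <- build_inverse(fx$lf, lambda = 1e-5 * mean(diag(tcrossprod(fx$lf$L))))
  nodes <- fx$lf$grid$nodes
  r <- sqrt(rowSums(nodes^2))
  err_at <- function(idx) {
    mean(vapply(idx, function(i) {
      map <- fx$lf$L[, 3 * (i - 1) + 1:3] %*% c(0.6, 0.8, 0)
      peak <- which.max(apply_inverse(op, map)$estimate$magnitude)
      sqrt(sum((nodes[i, ] - nodes[peak, ])^2)) * 1000
    }, numeric(1)))
  }
  deep <- which(r < 0.4 * max(r))
  shallow <- which(r > 0.8 * max(r))
  withr::with_seed(8, {
    deep <- sample(deep, min(8, length(deep)))
    shallow <- sample(shallow, min(8, length(shallow)))
  })
  expect_gte(err_at(deep), err_at(shallow) - 1e-9)
})

test_that("the L-curve scan returns a lambda inside the scanned range", {
  fx <- make_forward_fixture(n_channels = 24, spacing_mm = 35)
  op <- build_inverse(fx$lf)
  map <- as.numeric(fx$lf$L[, 8])
  pick <- choose_lambda(op, map, n_lambda = 15)
  expect_true(pick$lambda %in% pick$scan$lambda)
  expect_equal(nrow(pick$scan), 15)
  expect_true(all(diff(pick$scan$solution_norm) >= -1e-9 * max(pick$scan$solution_norm)))
})
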