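#' One-way within-subject (repeated measures) ANOVA
#'
#' Classical full decomposition for a single repeated factor: total sum of
#' squares split into subject, condition and residual
#' (subject x condition) components, with
#' `F = MS_condition / MS_residual` on `(k - 1, (k - 1)(n - 1))` degrees of
#' freedom and an uncorrected p value. Every subject must contribute every
#' level. When the residual sum of squares is numerically zero (noise-free
#' synthetic data) the F ratio is undefined; the result is then flagged as
#' perfect separation instead of dividing by zero.
#'
#' @param data Data frame with one row per subject x condition.
#' @param value Name of the numeric outcome column (string).
#' @param subject,condition Names of the subject and factor columns.
#' @param gg Apply the Greenhouse-Geisser sphericity correction to the
#'   degrees of freedom and p value (off by default; the conventional
#'   report for this design is the plain F).
#' @return An object of class `rm_anova`; see [tidy.rm_anova()] and
#'   [glance.rm_anova()].
#' @examples
#' d <- tidyr::expand_grid(s = factor(1:6), g = factor(1:3))
#' d$y <- rnorm(nrow(d))
#' glance(rm_anova(d, "y", "s", "g"))
#' @export
rm_anova <- function(data, value, subject = "subject",
                     condition = "condition", gg = FALSE) {
  stopifnot(is.data.frame(data))
  for (col in c(value, subject, condition)) {
    if (!col %in% names(data)) abort(sprintf("Column `%s` not found.", col))
  }
  y <- as.numeric(data[[value]])
  s <- factor(data[[subject]])
  g <- factor(as.character(data[[condition]]))
  if (anyNA(y)) abort("Missing outcome values.")
  tab <- table(s, g)
  if (any(tab != 1L)) {
    bad <- which(tab != 1L, arr.ind = TRUE)
    abort(sprintf(
      "Design must be one observation per subject x condition; first offender: subject %s, condition %s.",
      rownames(tab)[bad[1, 1]], colnames(tab)[bad[1, 2]]))
  }
  n <- nlevels(s); k <- nlevels(g)
  if (n < 2L || k < 2L) abort("Need >= 2 subjects and >= 2 conditions.")
  grand <- mean(y)
  m_s <- tapply(y, s, mean)
  m_g <- tapply(y, g, mean)
  ss_total <- sum((y - grand)^2)
  ss_subj <- k * sum((m_s - grand)^2)
  ss_cond <- n * sum((m_g - grand)^2)
  ss_res <- max(0, ss_total - ss_subj - ss_cond)
  df1 <- k - 1L
  df2 <- (k - 1L) * (n - 1L)
  eps <- 1
  if (gg) {
    eps <- gg_epsilon(y, s, g)
    df1 <- df1 * eps
    df2 <- df2 * eps
  }
  tol <- 1e-12 * max(1, ss_total)
  # zero residual with a real condition effect: "perfect separation",
  # F -> infinity; zero residual and zero effect: nothing to test at all
  separated <- ss_res <= tol && ss_cond > tol
  undefined <- ss_res <= tol
  statistic <- if (undefined) NA_real_ else (ss_cond / (k - 1)) / (ss_res / ((k - 1) * (n - 1)))
  structure(list(
    statistic = statistic, df1 = df1, df2 = df2,
    p.value = if (undefined) NA_real_ else pf(statistic, df1, df2, lower.tail = FALSE),
    ss = tibble::tibble(
      term = c("condition", "subject", "residual"),
      df = c(k - 1L, n - 1L, (k - 1L) * (n - 1L)),
      sumsq = c(ss_cond, ss_subj, ss_res)
    ),
    epsilon = eps, gg = gg,
    n_subjects = n, n_conditions = k,
    perfect_separation = separated
  ), class = "rm_anova")
}

# Greenhouse-Geisser epsilon from the condition x condition covariance of
# the subject x condition score matrix
gg_epsilon <- function(y, s, g) {
  m <- tapply(y, list(s, g), mean)
  S <- stats::cov(m)
  k <- ncol(S)
  dbar <- mean(diag(S)); sbar <- mean(S)
  num <- (k * (dbar - sbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowMeans(S)^2) + k^2 * sbar^2)
  max(1 / (k - 1), min(1, num / den))
}

#' @export
print.rm_anova <- function(x, ...) {
  if (x$perfect_separation) {
    cat("Within-subject ANOVA: residual SS = 0 (perfect separation); F undefined\n")
  } else {
    cat(sprintf("Within-subject ANOVA: F(%.4g, %.4g) = %.4g, p = %.4g%s\n",
                x$df1, x$df2, x$statistic, x$p.value,
                if (x$gg) sprintf(" (GG eps = %.3f)", x$epsilon) else ""))
  }
  invisible(x)
}

#' Tidiers for within-subject ANOVA fits
#'
#' `tidy()` returns the sum-of-squares decomposition, one row per term;
#' `glance()` returns the one-row test summary.
#'
#' @param x An [rm_anova()] object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.rm_anova <- function(x, ...) x$ss

#' @rdname tidy.rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, df1 = x$df1, df2 = x$df2,
    p.value = x$p.value, n_subjects = x$n_subjects,
    perfect_separation = x$perfect_separation
  )
}
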