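#' Score the temporal Perceptual Aberration Scale (tPAS)
#'
#' The tPAS is a 20-item schizotypy instrument; each statement is rated
#' 1 ("not at all") to 10 ("very much"). The scale score is the mean item
#' rating, so it stays on the 1-10 response metric. There are no
#' reverse-keyed items.
#'
#' @param ratings Numeric vector of exactly 20 integer ratings in 1..10.
#' @return The mean rating, a number in \[1, 10\].
#' @examples
#' score_tpas(rep(c(3, 5), each = 10))  # 4
#' @export
score_tpas <- function(ratings) {
  ratings <- as.numeric(ratings)
  if (length(ratings) != 20L) {
    abort(sprintf("tPAS has 20 items; got %d ratings.", length(ratings)))
  }
  bad <- which(is.na(ratings) | ratings < 1 | ratings > 10 |
                 ratings != round(ratings))
  if (length(bad)) {
    abort(paste0("Invalid tPAS ratings (must be integers in 1..10) at item(s): ",
                 paste(bad, collapse = ", ")))
  }
  mean(ratings)
}

#' Score the Perceptual Aberration Scale (PAS)
#'
#' The PAS is a 35-item true/false schizotypy instrument scored as the
#' number of items endorsed in the keyed direction. The published scoring
#' key lives with the original instrument, not here; by default every item
#' is keyed "true", and a custom logical key may be supplied.
#'
#' @param endorsements Logical vector of exactly 35 responses.
#' @param key Logical vector of 35 keyed directions (default all `TRUE`).
#' @return Integer count in 0..35.
#' @examples
#' score_pas(rep(c(TRUE, FALSE), c(6, 29)))  # 6
#' @export
score_pas <- function(endorsements, key = rep(TRUE, 35L)) {
  if (length(endorsements) != 35L) {
    abort(sprintf("PAS has 35 items; got %d responses.", length(endorsements)))
  }
  if (length(key) != 35L || !is.logical(key) || anyNA(key)) {
    abort("`key` must be 35 non-missing logicals.")
  }
  endorsements <- as.logical(endorsements)
  if (anyNA(endorsements)) abort("PAS responses must be non-missing true/false.")
  sum(endorsements == key)
}

#' Add scale scores to a cohort table
#'
#' Scores every subject of a cohort generated by [generate_cohort()] (or
#' any table with `tpas_01..tpas_20` and `pas_01..pas_35` item columns).
#'
#' @param cohort Data frame with tPAS and PAS item columns.
#' @param pas_key Optional PAS scoring key (see [score_pas()]).
#' @return The input with item columns replaced by `tpas_score` and
#'   `pas_score` columns appended after the identifier columns.
#' @export
score_scales <- function(cohort, pas_key = rep(TRUE, 35L)) {
  stopifnot(is.data.frame(cohort))
  tpas_cols <- sprintf("tpas_%02d", 1:20)
  pas_cols <- sprintf("pas_%02d", 1:35)
  missing_cols <- setdiff(c(tpas_cols, pas_cols), names(cohort))
  if (length(missing_cols)) {
    abort(paste0("Missing item columns: ", paste(missing_cols, collapse = ", ")))
  }
  tpas_mat <- as.matrix(cohort[, tpas_cols])
  pas_mat <- as.matrix(cohort[, pas_cols])
  out <- dplyr::select(cohort, -dplyr::all_of(c(tpas_cols, pas_cols)))
  out$tpas_score <- vapply(seq_len(nrow(cohort)),
                           function(i) score_tpas(tpas_mat[i, ]), numeric(1))
  out$pas_score <- vapply(seq_len(nrow(cohort)),
                          function(i) score_pas(pas_mat[i, ] == 1, pas_key),
                          numeric(1))
  tibble::as_tibble(out)
}

#' Pearson product-moment correlation with two-tailed p
#'
#' Thin tabular wrapper around [stats::cor.test()]: product-moment r and
#' the two-tailed p from the t transform on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return One-row tibble: `estimate` (r), `statistic` (t), `df`,
#'   `p.value`, `n`.
#' @export
pearson_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3L) abort("Need at least 3 paired observations.")
  if (anyNA(x) || anyNA(y)) abort("Missing values are not allowed.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation undefined: a variable has zero variance.")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(
    estimate = unname(ct$estimate),
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p.value = ct$p.value,
    n = length(x)
  )
}

#' Pooled-variance independent-samples t test
#'
#' Two-sample t test with a pooled variance estimate and
#' `df = n_a + n_b - 2`, computable either from raw score vectors or from
#' published summary statistics (mean, SD, n per group) — the latter is how
#' group comparisons reported only as summaries can be reproduced.
#'
#' @param a,b Raw numeric vectors (ignored when summaries are given).
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group summary statistics.
#' @return One-row tibble: `statistic` (t), `df`, `p.value`,
#'   `mean_diff` (a minus b).
#' @examples
#' # women vs men PAS scores from published group summaries
#' pooled_t_test(mean_a = 6.49, sd_a = 5.58, n_a = 85,
#'               mean_b = 5.29, sd_b = 3.75, n_b = 85)
#' @export
pooled_t_test <- function(a = NULL, b = NULL,
                          mean_a = NULL, sd_a = NULL, n_a = NULL,
                          mean_b = NULL, sd_b = NULL, n_b = NULL) {
  from_summary <- !is.null(mean_a)
  if (from_summary) {
    for (v in list(mean_a, sd_a, n_a, mean_b, sd_b, n_b)) {
      if (is.null(v)) abort("Summary input needs mean, sd and n for both groups.")
    }
  } else {
    if (is.null(a) || is.null(b)) abort("Provide raw vectors or full summaries.")
    a <- as.numeric(a); b <- as.numeric(b)
    if (length(a) < 2L || length(b) < 2L) abort("Need n >= 2 per group.")
    mean_a <- mean(a); sd_a <- sd(a); n_a <- length(a)
    mean_b <- mean(b); sd_b <- sd(b); n_b <- length(b)
  }
  if (n_a < 2 || n_b < 2) abort("Need n >= 2 per group.")
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  if (sp2 <= 0) abort("Zero pooled variance: t statistic undefined.")
  tval <- (mean_a - mean_b) / sqrt(sp2 * (1 / n_a + 1 / n_b))
  tibble::tibble(
    statistic = tval,
    df = df,
    p.value = 2 * pt(-abs(tval), df),
    mean_diff = mean_a - mean_b
  )
}

#' tPAS item statements
#'
#' The 20 statements of the temporal Perceptual Aberration Scale, shipped
#' as package data. Item 20 is flagged as emphasised in the source
#' instrument (no scoring consequence).
#'
#' @return Tibble with columns `item`, `statement`, `emphasised`.
#' @export
tpas_items <- function() {
  path <- system.file("extdata", "tpas_items.tsv", package = "timemapr",
                      mustWork = TRUE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  tibble::as_tibble(raw)
}
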