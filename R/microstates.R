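#' Global field power
#'
#' GFP at each time point is the spatial standard deviation of the scalp
#' map: `sqrt(mean((v - mean(v))^2))` across channels. It is a
#' reference-free measure of momentary field strength.
#'
#' @param x Channels x samples matrix, or an `evoked` object.
#' @return Numeric vector, one value per sample.
#' @examples
#' gfp(matrix(c(1, -1), 2, 1))  # 1
#' @export
gfp <- function(x) {
  if (inherits(x, "evoked")) x <- x$data
  stopifnot(is.matrix(x))
  if (nrow(x) < 2L) abort("GFP needs at least 2 channels.")
  centred <- sweep(x, 2, colMeans(x))
  sqrt(colMeans(centred^2))
}

#' Spatial correlation between two scalp maps
#'
#' Pearson correlation across channels. With `polarity = FALSE` the
#' absolute value is returned, which treats a map and its inverse as the
#' same topography (the resting-state microstate convention); the default
#' keeps the sign, appropriate for evoked potentials where component
#' polarity is meaningful.
#'
#' @param a,b Numeric vectors (one value per channel).
#' @param polarity Keep the sign of the correlation?
#' @return A number in \[-1, 1\] (or \[0, 1\] when `polarity = FALSE`).
#' @export
spatial_corr <- function(a, b, polarity = TRUE) {
  if (length(a) != length(b)) abort("Maps must share the channel count.")
  if (sd(a) == 0 || sd(b) == 0) abort("Spatial correlation of a flat map is undefined.")
  r <- cor(a, b)
  if (polarity) r else abs(r)
}

# correlation of every sample column of x with every template column
# (channels x samples, channels x q) -> samples x q matrix
corr_with_templates <- function(x, templates) {
  xc <- sweep(x, 2, colMeans(x))
  tc <- sweep(templates, 2, colMeans(templates))
  xn <- sqrt(colSums(xc^2)); tn <- sqrt(colSums(tc^2))
  xn[xn == 0] <- Inf   # flat samples correlate 0 with everything
  crossprod(xc, tc) / (xn %o% tn)
}

# argmax per row with deterministic lowest-index tie-break
assign_labels <- function(corr, polarity) {
  score <- if (polarity) corr else corr^2
  max.col(score, ties.method = "first")
}

# global explained variance of a labelling (GFP^2-weighted squared
# correlation with the assigned template)
gev_of <- function(x, templates, labels, polarity) {
  cc <- corr_with_templates(x, templates)
  r <- cc[cbind(seq_len(ncol(x)), labels)]
  if (!polarity) r <- abs(r)
  g2 <- gfp(x)^2
  sum(g2 * r^2) / sum(g2)
}

# one k-means pass from given initial template columns
kmeans_once <- function(x, init, polarity, max_iter) {
  templates <- init
  labels <- rep(0L, ncol(x))
  for (iter in seq_len(max_iter)) {
    cc <- corr_with_templates(x, templates)
    new_labels <- assign_labels(cc, polarity)
    if (identical(new_labels, labels)) break
    labels <- new_labels
    for (j in seq_len(ncol(templates))) {
      idx <- which(labels == j)
      if (!length(idx)) {
        # dead cluster: reseed with the worst-explained sample
        r <- cc[cbind(seq_len(ncol(x)), labels)]
        templates[, j] <- x[, which.min(abs(r))]
        next
      }
      maps <- x[, idx, drop = FALSE]
      if (polarity) {
        templates[, j] <- rowMeans(maps)
      } else {
        # dominant spatial eigenvector, polarity-invariant
        sv <- svd(maps, nu = 1, nv = 0)
        templates[, j] <- sv$u[, 1]
      }
    }
    templates <- normalize_maps(templates)
  }
  list(templates = templates, labels = labels,
       gev = gev_of(x, templates, labels, polarity))
}

# centre to average reference and scale to unit GFP, column-wise
normalize_maps <- function(m) {
  m <- sweep(m, 2, colMeans(m))
  g <- sqrt(colMeans(m^2))
  g[g == 0] <- 1
  sweep(m, 2, g, "/")
}

#' Modified spatial k-means microstate segmentation
#'
#' Clusters the time-point topographies of (typically group-averaged,
#' concatenated across conditions) evoked potentials into `q` template
#' maps: initial templates are `q` randomly chosen normalised time-point
#' maps; each sample is then assigned to the template with the highest
#' spatial correlation (squared correlation when `polarity = FALSE`) and
#' each template is re-estimated from its assigned maps (normalised mean,
#' or dominant spatial eigenvector in polarity-invariant mode) until the
#' labelling is stable. The best of `n_restarts` runs by global explained
#' variance is returned.
#'
#' @param x Channels x samples matrix, an `evoked`, or a list of `evoked`
#'   objects (concatenated along time).
#' @param q Number of template maps (>= 1).
#' @param n_restarts Random restarts (default 20).
#' @param seed Integer seed; fixed seed gives a deterministic fit.
#' @param polarity Polarity-sensitive assignment (default `TRUE`).
#' @param max_iter Iteration cap per restart.
#' @return An object of class `ms_fit`: `templates` (channels x q,
#'   zero-mean unit-GFP columns), `labels` (per sample), `gev`, `sigma2`,
#'   `cv`, `q`, `n_channels`, `polarity`.
#' @export
ms_segment <- function(x, q, n_restarts = 20, seed = NULL,
                       polarity = TRUE, max_iter = 200) {
  x <- as_map_matrix(x)
  q <- stop_if_not_count(q, "q")
  if (q > ncol(x)) abort("`q` cannot exceed the number of samples.")
  x <- average_reference(x)
  with_seed_or_not(seed, {
    best <- NULL
    nz <- which(gfp(x) > 0)
    if (length(nz) < q) abort("Not enough non-flat samples to seed `q` maps.")
    for (r in seq_len(n_restarts)) {
      init <- normalize_maps(x[, sample(nz, q), drop = FALSE])
      fit <- kmeans_once(x, init, polarity, max_iter)
      if (is.null(best) || fit$gev > best$gev) best <- fit
    }
    cvs <- ms_cv(best$templates, x, labels = best$labels, polarity = polarity)
    structure(c(best, list(q = q, n_channels = nrow(x),
                           sigma2 = cvs$sigma2, cv = cvs$cv,
                           polarity = polarity)),
              class = "ms_fit")
  })
}

as_map_matrix <- function(x) {
  if (inherits(x, "evoked")) return(x$data)
  if (inherits(x, "group_evoked")) return(x$concatenated)
  if (is.list(x) && !is.matrix(x)) {
    return(do.call(cbind, lapply(x, function(e) {
      if (inherits(e, "evoked")) e$data else e
    })))
  }
  stopifnot(is.matrix(x))
  x
}

#' Cross-validation criterion for the number of template maps
#'
#' Predictive residual variance criterion: with unit-norm templates
#' \eqn{a_q} and the competitive labelling \eqn{L_t},
#' \eqn{\sigma^2 = \sum_t (u_t'u_t - (a_{L_t}'u_t)^2) / (T (N-1))} and
#' \eqn{CV = \sigma^2 ((N-1)/(N-1-q))^2}, minimised over a range of `q` to
#' select model order. Defined only for `q < N - 1` electrodes.
#'
#' @param templates Channels x q template matrix.
#' @param x Data (as in [ms_segment()]).
#' @param labels Optional precomputed labelling; recomputed competitively
#'   when missing.
#' @param polarity Polarity-sensitive assignment.
#' @return One-row tibble: `q`, `sigma2`, `cv`, `n_channels`.
#' @export
ms_cv <- function(templates, x, labels = NULL, polarity = TRUE) {
  x <- as_map_matrix(x)
  n <- nrow(x); q <- ncol(templates)
  if (q >= n - 1L) abort("Cross-validation criterion requires q < N - 1 electrodes.")
  if (is.null(labels)) {
    labels <- assign_labels(corr_with_templates(x, templates), polarity)
  }
  # unit-norm template vectors
  a <- sweep(templates, 2, sqrt(colSums(templates^2)), "/")
  tot <- colSums(x^2)
  expl <- colSums(x * a[, labels, drop = FALSE])^2
  sigma2 <- sum(tot - expl) / (ncol(x) * (n - 1L))
  tibble::tibble(q = q, sigma2 = sigma2,
                 cv = sigma2 * ((n - 1) / (n - 1 - q))^2,
                 n_channels = n)
}

#' Fit a range of model orders and pick the CV-optimal one
#'
#' Runs [ms_segment()] for every `q` in `q_range` and selects the model
#' order from the cross-validation criterion curve. Two rules are
#' available. `"knee"` (default) takes the knee of the curve — the `q`
#' with the largest second difference of `log(cv)` — which is where adding
#' a map stops paying for itself; on data whose CV reaches (numerical)
#' zero the smallest such `q` is taken directly. `"argmin"` takes the
#' global minimiser (first of ties). With dense montages the penalty term
#' of the criterion grows only slowly with `q`, so the raw minimum tends
#' to drift to the top of the range while the knee stays at the planted
#' model order; the knee is therefore the default.
#'
#' @inheritParams ms_segment
#' @param q_range Candidate numbers of maps (default 2:12).
#' @param rule Model-order selection rule (see Details).
#' @return List of class `ms_selection`: `best_q`, `fit` (the winning
#'   `ms_fit`), `scores` (tibble of `q`, `sigma2`, `cv`, `gev`), `rule`.
#' @export
ms_select_q <- function(x, q_range = 2:12, n_restarts = 20, seed = NULL,
                        polarity = TRUE, rule = c("knee", "argmin")) {
  rule <- match.arg(rule)
  x <- as_map_matrix(x)
  fits <- purrr::map(q_range, function(q) {
    ms_segment(x, q, n_restarts = n_restarts,
               seed = if (is.null(seed)) NULL else seed + q,
               polarity = polarity)
  })
  scores <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(q = f$q, sigma2 = f$sigma2, cv = f$cv, gev = f$gev)
  })
  best <- select_order(scores$cv, rule)
  structure(list(best_q = q_range[best], fit = fits[[best]],
                 scores = scores, rule = rule),
            class = "ms_selection")
}

select_order <- function(cv, rule) {
  # numerically zero CV (noiseless planted order): smallest such q wins
  tiny <- 1e-10 * max(cv)
  if (any(cv <= tiny)) return(which(cv <= tiny)[1L])
  if (rule == "argmin" || length(cv) < 3L) return(which.min(cv))
  lcv <- log(cv)
  d2 <- diff(diff(lcv))                 # second difference at interior points
  which.max(d2) + 1L
}

#' @export
print.ms_fit <- function(x, ...) {
  cat(sprintf("Microstate fit: q = %d maps, %d channels, GEV = %.3f, CV = %.4g\n",
              x$q, x$n_channels, x$gev, x$cv))
  invisible(x)
}

#' @export
print.ms_selection <- function(x, ...) {
  cat(sprintf("Model-order selection: best q = %d by cross-validation\n", x$best_q))
  print(x$scores)
  invisible(x)
}

# split a label vector into runs: tibble(template, start, length)
label_runs <- function(labels) {
  r <- rle(labels)
  tibble::tibble(template = r$values,
                 start = cumsum(c(1L, head(r$lengths, -1L))),
                 length = r$lengths)
}

#' Competitive back-fitting of template maps to an individual EP
#'
#' Assigns every sample in the analysis window to the template with the
#' highest spatial correlation (squared when polarity-invariant; ties go
#' to the lowest template index). Runs shorter than
#' `min_duration_samples` are absorbed into whichever flanking run's
#' template correlates better over the short run. Per template the
#' duration (assigned samples x sampling interval) and the mean GFP over
#' assigned samples are returned; a template that captures no samples has
#' zero duration and missing GFP.
#'
#' @param templates Channels x q matrix.
#' @param evoked An `evoked` object, or a channels x samples matrix (then
#'   `sfreq` is required).
#' @param window_ms Optional `c(t0, t1)` fitting window (ms, half-open)
#'   relative to epoch onset; default the whole epoch.
#' @param min_duration_samples Minimum run length (default 1 = no
#'   smoothing).
#' @param polarity Polarity-sensitive assignment.
#' @param sfreq Sampling rate when `evoked` is a bare matrix.
#' @return List of class `ms_backfit`: `labels` (full-length, `NA` outside
#'   the window), `fit` — tibble with `template`, `n_samples`,
#'   `duration_ms`, `mean_gfp`.
#' @export
ms_backfit <- function(templates, evoked, window_ms = NULL,
                       min_duration_samples = 1, polarity = TRUE,
                       sfreq = NULL) {
  if (inherits(evoked, "evoked")) {
    x <- evoked$data; sfreq <- evoked$sfreq
  } else {
    x <- evoked
    if (is.null(sfreq)) abort("Provide `sfreq` when `evoked` is a matrix.")
  }
  stopifnot(is.matrix(x), nrow(x) == nrow(templates))
  n_samp <- ncol(x)
  idx <- seq_len(n_samp)
  if (!is.null(window_ms)) {
    lo <- ceiling(window_ms[1] * sfreq / 1000) + 1L
    hi <- ceiling(window_ms[2] * sfreq / 1000)
    idx <- idx[idx >= lo & idx <= min(hi, n_samp)]
    if (!length(idx)) abort("Empty fitting window.")
  }
  xw <- x[, idx, drop = FALSE]
  cc <- corr_with_templates(xw, templates)
  labels <- assign_labels(cc, polarity)
  if (min_duration_samples > 1) {
    labels <- smooth_short_runs(labels, cc, min_duration_samples, polarity)
  }
  g <- gfp(xw)
  dt <- 1000 / sfreq
  fit <- purrr::map_dfr(seq_len(ncol(templates)), function(j) {
    sel <- labels == j
    tibble::tibble(template = j, n_samples = sum(sel),
                   duration_ms = sum(sel) * dt,
                   mean_gfp = if (any(sel)) mean(g[sel]) else NA_real_)
  })
  full <- rep(NA_integer_, n_samp)
  full[idx] <- labels
  structure(list(labels = full, fit = fit, window_samples = idx,
                 sfreq = sfreq), class = "ms_backfit")
}

# absorb runs shorter than min_len into the better-correlating neighbour
smooth_short_runs <- function(labels, cc, min_len, polarity) {
  score <- if (polarity) cc else abs(cc)
  for (pass in seq_len(100L)) {
    runs <- label_runs(labels)
    short <- which(runs$length < min_len)
    if (!length(short) || nrow(runs) == 1L) break
    i <- short[which.min(runs$length[short])]
    cand <- c(if (i > 1L) runs$template[i - 1L],
              if (i < nrow(runs)) runs$template[i + 1L])
    cand <- unique(cand)
    span <- runs$start[i] + seq_len(runs$length[i]) - 1L
    means <- vapply(cand, function(j) mean(score[span, j]), numeric(1))
    labels[span] <- cand[which.max(means)]
  }
  labels
}

#' Back-fit templates across a whole cohort
#'
#' Applies [ms_backfit()] to every subject x condition evoked of an EP
#' cohort and stacks the per-template duration and GFP rows.
#'
#' @param cohort An `ep_cohort` ([generate_ep_cohort()]) or a tibble with
#'   `subject`, `condition` and an `evoked` list-column.
#' @param templates Channels x q matrix (e.g. from [ms_segment()]).
#' @param ... Passed to [ms_backfit()].
#' @return Tibble: `subject`, `condition`, `template`, `n_samples`,
#'   `duration_ms`, `mean_gfp`.
#' @export
backfit_cohort <- function(cohort, templates, ...) {
  tab <- if (inherits(cohort, "ep_cohort")) cohort$evokeds else cohort
  stopifnot(all(c("subject", "condition", "evoked") %in% names(tab)))
  purrr::pmap_dfr(
    list(tab$subject, as.character(tab$condition), tab$evoked),
    function(subj, cond, ev) {
      bf <- ms_backfit(templates, ev, ...)
      dplyr::mutate(bf$fit, subject = subj, condition = cond,
                    .before = "template")
    }
  ) |>
    dplyr::mutate(condition = as_condition(.data$condition))
}

#' Duration and GFP statistics per template map
#'
#' For every template, a within-subject ANOVA over the three task
#' conditions on back-fitted duration and on mean GFP (missing GFP cells —
#' maps absent from a subject's EP — make that template's GFP ANOVA
#' unavailable and are reported as `NA`).
#'
#' @param fit_tbl Output of [backfit_cohort()].
#' @param measures Columns to analyse.
#' @return Tibble: `template`, `measure`, `statistic`, `df1`, `df2`,
#'   `p.value`, `perfect_separation`.
#' @export
duration_statistics <- function(fit_tbl,
                                measures = c("duration_ms", "mean_gfp")) {
  purrr::map_dfr(measures, function(m) {
    fit_tbl |>
      dplyr::group_by(.data$template) |>
      dplyr::group_modify(function(d, key) {
        if (anyNA(d[[m]])) {
          return(tibble::tibble(measure = m, statistic = NA_real_,
                                df1 = NA_real_, df2 = NA_real_,
                                p.value = NA_real_,
                                perfect_separation = NA))
        }
        a <- rm_anova(d, m, subject = "subject", condition = "condition")
        tibble::tibble(measure = m, statistic = a$statistic,
                       df1 = a$df1, df2 = a$df2, p.value = a$p.value,
                       perfect_separation = a$perfect_separation)
      }) |>
      dplyr::ungroup()
  })
}

#' Identify the condition-modulated "time-map"
#'
#' The time-map is singled out programmatically as the template whose
#' duration differs most reliably between conditions: the smallest
#' duration-ANOVA p value (a perfectly separated template — zero residual
#' variance — outranks any finite p).
#'
#' @param stats_tbl Output of [duration_statistics()].
#' @return The winning template index (integer).
#' @export
identify_timemap <- function(stats_tbl) {
  d <- dplyr::filter(stats_tbl, .data$measure == "duration_ms")
  if (!nrow(d)) abort("No duration statistics to rank.")
  p <- ifelse(!is.na(d$perfect_separation) & d$perfect_separation, -Inf,
              d$p.value)
  d$template[which.min(p)]
}

#' Correlate per-map statistics with questionnaire scores
#'
#' Each subject's measure is averaged over the three conditions
#' (unweighted), then correlated with the tPAS and PAS scores by Pearson
#' product-moment correlation, two-tailed.
#'
#' @param fit_tbl Output of [backfit_cohort()], usually filtered to one
#'   template.
#' @param scores Scored cohort (`subject`, `tpas_score`, `pas_score`).
#' @param measures Columns to correlate.
#' @return Tibble: `template`, `measure`, `scale`, `estimate`,
#'   `statistic`, `df`, `p.value`, `n`.
#' @export
correlate_map_stats <- function(fit_tbl, scores,
                                measures = c("duration_ms", "mean_gfp")) {
  purrr::map_dfr(measures, function(m) {
    agg <- fit_tbl |>
      dplyr::group_by(.data$template, .data$subject) |>
      dplyr::summarise(value = mean(.data[[m]]), .groups = "drop") |>
      dplyr::inner_join(scores, by = "subject")
    agg |>
      dplyr::group_by(.data$template) |>
      dplyr::group_modify(function(d, key) {
        purrr::map_dfr(c(tpas = "tpas_score", pas = "pas_score"),
                       function(col) {
                         if (anyNA(d$value)) {
                           return(tibble::tibble(estimate = NA_real_,
                                                 statistic = NA_real_,
                                                 df = NA_real_,
                                                 p.value = NA_real_,
                                                 n = nrow(d)))
                         }
                         pearson_test(d[[col]], d$value)
                       }, .id = "scale") |>
          dplyr::mutate(measure = m, .before = "scale")
      }) |>
      dplyr::ungroup()
  })
}
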