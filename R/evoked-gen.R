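#' Specification of the synthetic evoked-potential generator
#'
#' Each simulated evoked potential (EP) is a sequence of quasi-stable
#' topographic segments: within a segment the scalp map is a fixed template
#' scaled by a smooth positive amplitude envelope, plus spatial Gaussian
#' noise, average-referenced at every sample. One designated segment — the
#' "time-map", covering roughly 350-500 ms — has a condition-dependent
#' duration that also grows with the subject's latent schizotypy trait.
#' Default condition duration means and between-subject SDs are the
#' published group statistics for this task; the published SDs are treated
#' as total between-subject SDs, so the residual noise SD is
#' `sqrt(sd^2 - slope^2)`.
#'
#' @param n_channels Electrode count (default 192).
#' @param sampling_rate Hz (default 2048).
#' @param epoch_ms Half-open analysis window `[t0, t1)` in ms post-stimulus.
#' @param n_templates Number of planted template maps.
#' @param timemap_index Which template is the condition-modulated time-map.
#' @param pre_durations_ms Fixed durations (ms) of the segments preceding
#'   the time-map (their sum sets the time-map onset, 350 ms by default).
#' @param post_duration_ms Fixed duration of the segment following the
#'   time-map; the last template absorbs the remainder of the epoch.
#' @param timemap_duration_means Named (Past/Now/Future) mean durations, ms.
#' @param timemap_duration_sds Named total between-subject SDs, ms.
#' @param trait_duration_slope Duration increase, ms per trait SD.
#' @param segment_jitter_sd Between-subject SD (ms) of the nominally fixed
#'   segment durations — evoked component latencies vary across subjects;
#'   without this jitter the epoch-remainder segment would be an exact
#'   complement of the time-map.
#' @param noise_sd Spatial Gaussian noise SD, µV.
#' @param amplitude Peak envelope GFP, µV.
#' @param envelope_base Envelope floor as a fraction of `amplitude`
#'   (a raised-sine bump per segment, so GFP varies within segments).
#' @return A list of class `ep_spec`.
#' @export
ep_spec <- function(n_channels = 192,
                    sampling_rate = 2048,
                    epoch_ms = c(0, 800),
                    n_templates = 6,
                    timemap_index = 4,
                    pre_durations_ms = c(120, 110, 120),
                    post_duration_ms = 150,
                    timemap_duration_means = c(Past = 110.2, Now = 39.2,
                                               Future = 105.0),
                    timemap_duration_sds = c(Past = 12.3, Now = 8.4,
                                             Future = 15.2),
                    trait_duration_slope = trait_calibration()$duration_trait_slope,
                    segment_jitter_sd = 12,
                    noise_sd = 1,
                    amplitude = 5,
                    envelope_base = 0.25) {
  n_channels <- stop_if_not_count(n_channels, "n_channels", lower = 2L)
  stop_if_not_scalar_number(sampling_rate, "sampling_rate", lower = 1)
  if (length(epoch_ms) != 2L || epoch_ms[2] <= epoch_ms[1]) {
    abort("`epoch_ms` must be an increasing pair [t0, t1).")
  }
  n_templates <- stop_if_not_count(n_templates, "n_templates", lower = 2L)
  timemap_index <- stop_if_not_count(timemap_index, "timemap_index")
  if (timemap_index >= n_templates) {
    abort("`timemap_index` must leave at least one trailing template.")
  }
  if (length(pre_durations_ms) != timemap_index - 1L) {
    abort("`pre_durations_ms` must have one duration per pre-time-map template.")
  }
  conds <- task_conditions()
  if (!setequal(names(timemap_duration_means), conds) ||
      !setequal(names(timemap_duration_sds), conds)) {
    abort("Duration means and SDs need names Past, Now, Future.")
  }
  stop_if_not_scalar_number(segment_jitter_sd, "segment_jitter_sd", lower = 0)
  stop_if_not_scalar_number(noise_sd, "noise_sd", lower = 0)
  stop_if_not_scalar_number(amplitude, "amplitude", lower = 0)
  stop_if_not_scalar_number(envelope_base, "envelope_base", 0, 1)
  stop_if_not_scalar_number(trait_duration_slope, "trait_duration_slope")
  slope <- trait_duration_slope
  sds <- timemap_duration_sds[conds]
  if (any(sds^2 < slope^2)) {
    abort("Total duration SDs must be at least the trait slope contribution.")
  }
  structure(list(
    n_channels = n_channels, sampling_rate = sampling_rate,
    epoch_ms = epoch_ms, n_templates = n_templates,
    timemap_index = timemap_index,
    pre_durations_ms = pre_durations_ms, post_duration_ms = post_duration_ms,
    timemap_duration_means = timemap_duration_means[conds],
    timemap_duration_sds = sds,
    timemap_resid_sds = sqrt(sds^2 - slope^2),
    trait_duration_slope = slope, segment_jitter_sd = segment_jitter_sd,
    noise_sd = noise_sd, amplitude = amplitude, envelope_base = envelope_base
  ), class = "ep_spec")
}

#' @rdname ep_spec
#' @param spec An `ep_spec`.
#' @return `ep_n_samples()`: number of samples in the half-open epoch
#'   window (1638 for 0-800 ms at 2048 Hz).
#' @export
ep_n_samples <- function(spec) {
  as.integer(floor(diff(spec$epoch_ms) * spec$sampling_rate / 1000))
}

# raised-sine envelope over one segment: positive, smooth, peaks mid-segment
segment_envelope <- function(n, amplitude, base) {
  u <- (seq_len(n) - 0.5) / n
  amplitude * (base + (1 - base) * sin(pi * u)^2)
}

# draw the planted time-map duration (ms -> whole samples, >= 1)
draw_timemap_duration <- function(trait, condition, spec) {
  mu <- spec$timemap_duration_means[[condition]] +
    spec$trait_duration_slope * trait +
    rnorm(1, 0, spec$timemap_resid_sds[[condition]])
  dt <- 1000 / spec$sampling_rate
  n <- round(mu / dt)
  if (n < 1) {
    warn("Planted time-map duration below one sample; clipped to 1 sample.")
    n <- 1
  }
  as.integer(n)
}

# segment layout in samples for one subject x condition; fixed segments
# get subject-level duration jitter (component latency variability)
plan_segments <- function(timemap_samples, spec) {
  dt <- 1000 / spec$sampling_rate
  n_total <- ep_n_samples(spec)
  j <- spec$segment_jitter_sd
  pre_ms <- spec$pre_durations_ms + rnorm(length(spec$pre_durations_ms), 0, j)
  post_ms <- spec$post_duration_ms + rnorm(1, 0, j)
  pre <- pmax(1L, as.integer(round(pre_ms / dt)))
  post <- pmax(1L, as.integer(round(post_ms / dt)))
  used <- sum(pre) + timemap_samples + post
  if (used >= n_total) {
    abort("Planted segments exceed the epoch; shorten durations or widen the epoch.")
  }
  lens <- c(pre, timemap_samples, post, n_total - used)
  onset <- cumsum(c(0L, head(lens, -1L)))
  tibble::tibble(
    template = seq_along(lens),
    onset_sample = onset,
    n_samples = lens,
    onset_ms = onset * dt,
    duration_ms = lens * dt
  )
}

#' Generate one synthetic evoked potential
#'
#' Builds a channels x samples voltage matrix from the planted segment
#' sequence: at each sample the active template map, scaled by the segment
#' envelope, plus spatial Gaussian noise; average-referenced at every
#' sample. The planted segment boundaries are returned as ground truth.
#'
#' @param trait The subject's latent trait value.
#' @param condition `"Past"`, `"Now"` or `"Future"`.
#' @param spec An [ep_spec()].
#' @param templates Channels x templates matrix
#'   ([generate_template_maps()]), at least `spec$n_templates` columns.
#' @param seed Integer seed.
#' @return A list of class `evoked`: `data` (channels x samples, µV),
#'   `sfreq`, `condition`, `segments` (ground-truth tibble),
#'   `timemap_duration_ms` (planted, after rounding to samples).
#' @export
generate_evoked <- function(trait, condition, spec = ep_spec(),
                            templates, seed = NULL) {
  stopifnot(inherits(spec, "ep_spec"))
  condition <- match.arg(condition, task_conditions())
  if (ncol(templates) < spec$n_templates) {
    abort("`templates` has fewer columns than `spec$n_templates`.")
  }
  if (nrow(templates) != spec$n_channels) {
    abort("`templates` channel count does not match `spec$n_channels`.")
  }
  with_seed_or_not(seed, {
    tm_samples <- draw_timemap_duration(trait, condition, spec)
    segs <- plan_segments(tm_samples, spec)
    n_total <- ep_n_samples(spec)
    data <- matrix(0, spec$n_channels, n_total)
    for (i in seq_len(nrow(segs))) {
      idx <- segs$onset_sample[i] + seq_len(segs$n_samples[i])
      env <- segment_envelope(segs$n_samples[i], spec$amplitude,
                              spec$envelope_base)
      data[, idx] <- templates[, segs$template[i]] %o% env
    }
    if (spec$noise_sd > 0) {
      data <- data + matrix(rnorm(length(data), 0, spec$noise_sd),
                            nrow(data), ncol(data))
    }
    data <- average_reference(data)
    structure(list(
      data = data, sfreq = spec$sampling_rate, condition = condition,
      segments = segs,
      timemap_duration_ms = segs$duration_ms[spec$timemap_index]
    ), class = "evoked")
  })
}

#' Generate a full synthetic EP cohort
#'
#' One evoked potential per subject and condition, all sharing one montage
#' and one planted template set. Returned in long nested form so the table
#' pipes straight into back-fitting.
#'
#' @param subjects Cohort tibble (needs `subject`, `trait`).
#' @param spec An [ep_spec()].
#' @param seed Integer seed; drives montage templates and every evoked.
#' @return List of class `ep_cohort`: `montage`, `templates`, and `evokeds`
#'   — a tibble with `subject`, `condition`, `planted_duration_ms` and an
#'   `evoked` list-column.
#' @export
generate_ep_cohort <- function(subjects, spec = ep_spec(), seed = 1L) {
  stopifnot(all(c("subject", "trait") %in% names(subjects)))
  with_seed_or_not(seed, {
    montage <- spherical_montage(spec$n_channels)
    templates <- generate_template_maps(montage, spec$n_templates,
                                        seed = NULL)
    grid <- tidyr::expand_grid(i = seq_len(nrow(subjects)),
                               condition = task_conditions())
    evokeds <- purrr::pmap(grid, function(i, condition) {
      generate_evoked(subjects$trait[i], condition, spec, templates,
                      seed = NULL)
    })
    tab <- tibble::tibble(
      subject = subjects$subject[grid$i],
      condition = as_condition(grid$condition),
      planted_duration_ms = purrr::map_dbl(evokeds, "timemap_duration_ms"),
      evoked = evokeds
    )
    structure(list(montage = montage, templates = templates,
                   spec = spec, evokeds = tab),
              class = "ep_cohort")
  })
}
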