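#' Reject epochs on an absolute amplitude criterion
#'
#' Removes every epoch in which any channel exceeds `threshold_uv` in
#' absolute value at any sample (the conventional +/-100 µV artifact
#' criterion), and logs which epochs were dropped and which channel was the
#' worst offender. An optional peak-to-peak criterion per channel can be
#' enabled for gradient-like artifacts.
#'
#' @param epochs 3-D numeric array, epochs x channels x samples.
#' @param threshold_uv Absolute amplitude threshold in µV (> 0).
#' @param ptp_uv Optional peak-to-peak threshold per channel (µV);
#'   `NULL` (default) disables it.
#' @return List: `epochs` (surviving sub-array, epoch dimension kept),
#'   `kept` (logical per input epoch), `log` — tibble with one row per
#'   rejected epoch (`epoch`, `channel`, `max_abs_uv`, `criterion`).
#' @export
reject_epochs <- function(epochs, threshold_uv = 100, ptp_uv = NULL) {
  stopifnot(is.array(epochs), length(dim(epochs)) == 3L)
  stop_if_not_scalar_number(threshold_uv, "threshold_uv", lower = 1e-12)
  n_ep <- dim(epochs)[1]
  max_abs <- apply(abs(epochs), c(1, 2), max)        # epochs x channels
  bad_amp <- apply(max_abs, 1, max) > threshold_uv
  bad_ptp <- rep(FALSE, n_ep)
  if (!is.null(ptp_uv)) {
    ptp <- apply(epochs, c(1, 2), function(v) diff(range(v)))
    bad_ptp <- apply(ptp, 1, max) > ptp_uv & !bad_amp
  }
  bad <- bad_amp | bad_ptp
  if (all(bad)) abort("All epochs exceed the rejection criteria.")
  log <- tibble::tibble(
    epoch = which(bad),
    channel = apply(max_abs[bad, , drop = FALSE], 1, which.max),
    max_abs_uv = apply(max_abs[bad, , drop = FALSE], 1, max),
    criterion = ifelse(bad_amp[bad], "amplitude", "peak_to_peak")
  )
  list(epochs = epochs[!bad, , , drop = FALSE], kept = !bad, log = log)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Filters each channel with a Butterworth band-pass applied
#' forward-backward ([signal::filtfilt()]), so the output has zero phase
#' shift and the same length as the input. The default 1-40 Hz band is the
#' conventional evoked-potential analysis band; the 1 Hz high-pass edge
#' also removes DC.
#'
#' @param x Channels x samples numeric matrix.
#' @param sfreq Sampling rate in Hz.
#' @param low,high Band edges in Hz; `0 < low < high < sfreq/2`.
#' @param order Butterworth order of each (low/high) section (default 2).
#' @return Filtered matrix, same dimensions.
#' @export
bandpass_filter <- function(x, sfreq, low = 1, high = 40, order = 2) {
  stopifnot(is.matrix(x))
  stop_if_not_scalar_number(sfreq, "sfreq", lower = 1e-9)
  if (!(low > 0 && high > low && high < sfreq / 2)) {
    abort("Need 0 < low < high < Nyquist (sfreq/2).")
  }
  bf <- signal::butter(order, c(low, high) / (sfreq / 2), type = "pass")
  t(apply(x, 1, function(ch) signal::filtfilt(bf, ch)))
}

#' Re-reference to the common average
#'
#' Subtracts the spatial mean across channels at every sample. Idempotent;
#' after it every column (sample) of the matrix has zero mean, which is the
#' reference-free representation topographic analysis assumes.
#'
#' @param x Channels x samples numeric matrix (>= 2 channels).
#' @return Average-referenced matrix.
#' @export
average_reference <- function(x) {
  stopifnot(is.matrix(x))
  if (nrow(x) < 2L) abort("Average reference needs at least 2 channels.")
  sweep(x, 2, colMeans(x))
}

#' Average epochs into an evoked potential
#'
#' Sample-wise mean over qualifying epochs (by convention only epochs from
#' correct trials enter the evoked average).
#'
#' @param epochs 3-D array, epochs x channels x samples.
#' @param correct Logical vector per epoch; `NULL` means all qualify.
#' @param correct_only If `TRUE` (default) only correct epochs are
#'   averaged.
#' @return Channels x samples matrix.
#' @export
average_epochs <- function(epochs, correct = NULL, correct_only = TRUE) {
  stopifnot(is.array(epochs), length(dim(epochs)) == 3L)
  keep <- rep(TRUE, dim(epochs)[1])
  if (correct_only && !is.null(correct)) {
    stopifnot(length(correct) == dim(epochs)[1])
    keep <- as.logical(correct)
  }
  if (!any(keep)) abort("No qualifying epochs to average.")
  sub <- epochs[keep, , , drop = FALSE]
  out <- apply(sub, c(2, 3), mean)
  matrix(out, dim(epochs)[2], dim(epochs)[3])
}

#' Epochs-to-evoked preprocessing pipeline
#'
#' The standard order: amplitude-based epoch rejection on the raw epochs
#' (the threshold is defined on recorded amplitudes), averaging of correct
#' surviving epochs, zero-phase band-pass filtering of the evoked, and
#' average referencing. Every step is recorded in a provenance log.
#'
#' @param epochs Epochs x channels x samples array.
#' @param sfreq Sampling rate (Hz).
#' @param correct Logical per epoch (correct response), or `NULL`.
#' @param condition,subject Labels carried into the result.
#' @param threshold_uv Rejection threshold (µV).
#' @param low,high,order Band-pass parameters (see [bandpass_filter()]).
#' @return An `evoked` list: `data`, `sfreq`, `condition`, `subject`,
#'   `reference = "average"`, `log` (character vector of applied steps),
#'   `rejection` (the rejection log tibble).
#' @export
preprocess_epochs <- function(epochs, sfreq, correct = NULL,
                              condition = NA_character_,
                              subject = NA_character_,
                              threshold_uv = 100,
                              low = 1, high = 40, order = 2) {
  rej <- reject_epochs(epochs, threshold_uv)
  correct_kept <- if (is.null(correct)) NULL else correct[rej$kept]
  ev <- average_epochs(rej$epochs, correct_kept)
  ev <- bandpass_filter(ev, sfreq, low, high, order)
  ev <- average_reference(ev)
  structure(list(
    data = ev, sfreq = sfreq, condition = condition, subject = subject,
    reference = "average",
    log = c(
      sprintf("reject_epochs(threshold_uv=%g): %d/%d kept",
              threshold_uv, sum(rej$kept), length(rej$kept)),
      sprintf("average_epochs(correct_only=%s)", !is.null(correct)),
      sprintf("bandpass_filter(%g-%g Hz, order %d, zero-phase)",
              low, high, order),
      "average_reference"
    ),
    rejection = rej$log
  ), class = "evoked")
}
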