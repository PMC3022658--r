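#' Synthetic equidistant spherical electrode montage
#'
#' Places `n_channels` electrodes quasi-uniformly on the upper part of a unit
#' sphere using a Fibonacci lattice. This stands in for a high-density EEG
#' cap (the default elsewhere in the package is 192 channels) when no
#' manufacturer layout is available; it is a synthetic layout, adequate for
#' topographic analysis and spherical forward modelling.
#'
#' @param n_channels Number of electrodes (>= 2).
#' @param coverage Fraction of the sphere covered from the vertex down
#'   (1 = whole sphere). EEG caps do not cover the underside of the head;
#'   the default 0.65 leaves the lower cap free.
#' @return A tibble with columns `channel` (label), `x`, `y`, `z`
#'   (unit-sphere coordinates).
#' @examples
#' mon <- spherical_montage(32)
#' all(abs(mon$x^2 + mon$y^2 + mon$z^2 - 1) < 1e-12)
#' @export
spherical_montage <- function(n_channels = 192, coverage = 0.65) {
  n_channels <- stop_if_not_count(n_channels, "n_channels", lower = 2L)
  stop_if_not_scalar_number(coverage, "coverage", lower = 0.05, upper = 1)
  i <- seq_len(n_channels) - 0.5
  # z descends from the vertex over the covered spherical cap
  z <- 1 - 2 * coverage * i / n_channels
  golden <- pi * (3 - sqrt(5))
  theta <- golden * (seq_len(n_channels) - 1L)
  r <- sqrt(pmax(0, 1 - z^2))
  tibble::tibble(
    channel = sprintf("E%03d", seq_len(n_channels)),
    x = r * cos(theta),
    y = r * sin(theta),
    z = z
  )
}

montage_positions <- function(montage) {
  stopifnot(all(c("channel", "x", "y", "z") %in% names(montage)))
  if (anyDuplicated(montage$channel)) abort("Montage channel labels must be unique.")
  as.matrix(montage[, c("x", "y", "z")])
}

#' Read / write electrode positions
#'
#' Plain-text electrode position files with one `label x y z` row per
#' channel, whitespace-delimited.
#'
#' @param montage A montage tibble as returned by [spherical_montage()].
#' @param path File path.
#' @return `read_montage()` returns a montage tibble.
#' @export
write_montage <- function(montage, path) {
  stopifnot(is.data.frame(montage))
  utils::write.table(montage[, c("channel", "x", "y", "z")], path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  raw <- utils::read.table(path, header = FALSE,
                           col.names = c("channel", "x", "y", "z"),
                           colClasses = c("character", rep("numeric", 3)))
  tibble::as_tibble(raw)
}
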