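#' Generate smooth orthogonal template topographies
#'
#' Builds `k` mutually orthogonal scalp maps that are zero-mean across
#' channels (average-referenced) and unit global field power. Maps are
#' random rotations of low-order real spherical harmonics evaluated at the
#' electrode positions, so they are spatially smooth like physiological EP
#' topographies rather than white noise.
#'
#' @param montage Montage tibble ([spherical_montage()]).
#' @param k Number of templates (>= 1, at most the number of available
#'   harmonic basis functions and `n_channels`).
#' @param seed Integer seed; fixed seed gives identical output.
#' @return A numeric matrix, channels x k; columns have channel mean 0 and
#'   GFP 1, and are pairwise orthogonal.
#' @examples
#' tpl <- generate_template_maps(spherical_montage(64), k = 4, seed = 1)
#' round(crossprod(tpl) / 64, 10)  # identity: unit GFP, orthogonal
#' @export
generate_template_maps <- function(montage, k, seed = NULL) {
  k <- stop_if_not_count(k, "k")
  pos <- montage_positions(montage)
  n <- nrow(pos)
  if (k > n) abort("`k` cannot exceed the number of channels.")
  x <- pos[, 1]; y <- pos[, 2]; z <- pos[, 3]
  # real spherical harmonics of degree 1-3 (unnormalised polynomial forms)
  basis <- cbind(
    x, y, z,
    x * y, x * z, y * z, x^2 - y^2, 3 * z^2 - 1,
    x * (5 * z^2 - 1), y * (5 * z^2 - 1), z * (5 * z^2 - 3),
    x * y * z, z * (x^2 - y^2)
  )
  if (k > ncol(basis)) {
    abort(sprintf("`k` larger than the %d available harmonic basis maps.", ncol(basis)))
  }
  with_seed_or_not(seed, {
    mix <- matrix(rnorm(ncol(basis) * ncol(basis)), ncol(basis))
    mixed <- basis %*% mix
    # orthonormalise within the average-reference subspace
    centred <- sweep(mixed, 2, colMeans(mixed))
    qr_dec <- qr(centred)
    ortho <- qr.Q(qr_dec)[, seq_len(k), drop = FALSE]
    ortho <- sweep(ortho, 2, colMeans(ortho))   # re-centre (numerical)
    gfps <- sqrt(colMeans(ortho^2))
    tpl <- sweep(ortho, 2, gfps, "/")
    dimnames(tpl) <- list(montage$channel, sprintf("map%02d", seq_len(k)))
    tpl
  })
}
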