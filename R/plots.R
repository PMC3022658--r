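# simple azimuthal-equidistant projection of electrode positions for 2-D
# topographic displays
project_montage <- function(montage) {
  pos <- montage_positions(montage)
  theta <- acos(pmin(1, pmax(-1, pos[, 3])))
  phi <- atan2(pos[, 2], pos[, 1])
  tibble::tibble(channel = montage$channel,
                 px = theta * cos(phi), py = theta * sin(phi))
}

#' Plot microstate template topographies
#'
#' One panel per template map, electrodes projected to 2-D and coloured by
#' voltage.
#'
#' @param object An `ms_fit` from [ms_segment()].
#' @param montage The montage the data were recorded with.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ms_fit <- function(object, montage, ...) {
  proj <- project_montage(montage)
  d <- purrr::map_dfr(seq_len(object$q), function(j) {
    dplyr::mutate(proj, template = sprintf("map %d", j),
                  voltage = object$templates[, j])
  })
  ggplot2::ggplot(d, ggplot2::aes(.data$px, .data$py, colour = .data$voltage)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_gradient2(low = "#2166ac", mid = "white",
                                    high = "#b2182b") +
    ggplot2::facet_wrap(~template) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "a.u.")
}

#' Plot a back-fitted segmentation over the GFP trace
#'
#' Global field power over time with the competitive template assignment
#' shown as a coloured band.
#'
#' @param object An `ms_backfit`.
#' @param evoked The evoked the fit was computed on.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ms_backfit <- function(object, evoked, ...) {
  x <- if (inherits(evoked, "evoked")) evoked$data else evoked
  g <- gfp(x)
  t_ms <- (seq_along(g) - 1L) * 1000 / object$sfreq
  d <- tibble::tibble(t_ms = t_ms, gfp = g,
                      template = factor(object$labels))
  ggplot2::ggplot(d, ggplot2::aes(.data$t_ms, .data$gfp)) +
    ggplot2::geom_area(ggplot2::aes(fill = .data$template), alpha = 0.6) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "GFP (µV)", fill = "map") +
    ggplot2::theme_minimal()
}

#' Plot the cross-validation curve of a model-order selection
#'
#' @param object An `ms_selection` from [ms_select_q()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ms_selection <- function(object, ...) {
  ggplot2::ggplot(object$scores, ggplot2::aes(.data$q, .data$cv)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_q, linetype = 2) +
    ggplot2::labs(x = "number of template maps q",
                  y = "cross-validation criterion") +
    ggplot2::theme_minimal()
}

#' Plot a distributed source estimate
#'
#' Current-density magnitude of every grid node, shown as three orthogonal
#' scatter projections; peaks are highlighted.
#'
#' @param object A `source_estimate` from [apply_inverse()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.source_estimate <- function(object, ...) {
  e <- object$estimate
  d <- dplyr::bind_rows(
    dplyr::transmute(e, view = "axial", u = .data$x_mm, v = .data$y_mm,
                     magnitude = .data$magnitude, peak = .data$peak),
    dplyr::transmute(e, view = "coronal", u = .data$x_mm, v = .data$z_mm,
                     magnitude = .data$magnitude, peak = .data$peak),
    dplyr::transmute(e, view = "sagittal", u = .data$y_mm, v = .data$z_mm,
                     magnitude = .data$magnitude, peak = .data$peak)
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$u, .data$v, colour = .data$magnitude)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_point(data = dplyr::filter(d, .data$peak),
                        colour = "red", shape = 4, size = 3) +
    ggplot2::facet_wrap(~view) +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(u = "mm", v = "mm") +
    ggplot2::theme_minimal()
}

#' @rdname tidy.rm_anova
#' @export
glance.ms_fit <- function(x, ...) {
  tibble::tibble(q = x$q, gev = x$gev, sigma2 = x$sigma2, cv = x$cv,
                 n_channels = x$n_channels)
}

#' @rdname tidy.rm_anova
#' @export
tidy.ms_backfit <- function(x, ...) x$fit
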