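#' Plot tracked trajectories
#'
#' One path per identity, coloured by id, in image coordinates (y axis
#' reversed so the plot matches the video).
#'
#' @param object A `flytrax_tracking` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.flytrax_tracking <- function(object, ...) {
  tr <- object$trajectories
  ggplot2::ggplot(tr, ggplot2::aes(.data$x, .data$y,
                                   colour = factor(.data$id),
                                   group = .data$id)) +
    ggplot2::geom_path(linewidth = 0.4) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(colour = "id", x = "x [px]", y = "y [px]",
                  title = "Tracked trajectories") +
    ggplot2::theme_minimal()
}

#' Plot per-frame detections
#'
#' Detection centroids with heading arrows where the wing scoring reached a
#' verdict.
#'
#' @param object A `flytrax_detections` tibble from [detect_all()].
#' @param frames Optional subset of frames to show.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.flytrax_detections <- function(object, frames = NULL, ...) {
  d <- tibble::as_tibble(object)
  if (!is.null(frames)) d <- d[d$frame %in% frames, , drop = FALSE]
  arrow_len <- if (nrow(d) > 0) mean(d$a, na.rm = TRUE) else 1
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_segment(
      data = d[which(d$heading_valid), , drop = FALSE],
      ggplot2::aes(xend = .data$x + arrow_len * .data$heading_dx,
                   yend = .data$y + arrow_len * .data$heading_dy),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "pt"))) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::facet_wrap(ggplot2::vars(.data$frame)) +
    ggplot2::labs(x = "x [px]", y = "y [px]",
                  title = "Detections and headings") +
    ggplot2::theme_minimal()
}

#' Show a frame as a raster plot
#'
#' @param frame A grayscale frame matrix.
#' @return A ggplot.
#' @export
plot_frame <- function(frame) {
  df <- tidyr::expand_grid(y = seq_len(nrow(frame)) - 1L,
                           x = seq_len(ncol(frame)) - 1L)
  df$value <- as.vector(t(frame))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none")
}
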