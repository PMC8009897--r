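#' Plot a spine report
#'
#' Displacement-signal view of a pipeline run: the smoothed MA-CSL
#' displacement per row, the epsilon tolerance band, the detected curve
#' segments and their SEV/AV/IEV landmarks. Rows increase downward, matching
#' image orientation.
#'
#' @param object A `spine_report` from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spine_report
#' @export
autoplot.spine_report <- function(object, ...) {
  disp <- object$disp_smooth
  eps <- object$config$epsilon
  p <- ggplot2::ggplot(disp, ggplot2::aes(x = .data$d, y = .data$row)) +
    ggplot2::annotate("rect", xmin = -eps, xmax = eps, ymin = -Inf, ymax = Inf,
                      alpha = 0.15, fill = "grey40") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_path(linewidth = 0.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "MA - CSL displacement (px)", y = "row (superior at top)",
                  title = "MA-CSL displacement and detected curves") +
    ggplot2::theme_minimal()
  if (nrow(object$segments) > 0) {
    segs <- object$segments
    p <- p +
      ggplot2::geom_hline(yintercept = c(segs$start_row, segs$end_row),
                          linetype = 3, colour = "steelblue") +
      ggplot2::geom_point(
        data = dplyr::mutate(object$landmarks, d = .data$x - disp$csl_x[1]),
        ggplot2::aes(x = .data$d, y = .data$row, shape = .data$landmark),
        size = 2.5, colour = "firebrick"
      )
  }
  p
}

#' Plot a phantom case
#'
#' Renders the synthetic radiograph with its analytic ground truth overlaid:
#' the true midline, the vertebra centroids and the true segment spans.
#'
#' @param object A `phantom_case` from [render_radiograph()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phantom_case
#' @export
autoplot.phantom_case <- function(object, ...) {
  img <- object$image
  df <- tibble::tibble(
    row = rep(seq_len(nrow(img)) - 1L, times = ncol(img)),
    col = rep(seq_len(ncol(img)) - 1L, each = nrow(img)),
    intensity = as.vector(img)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::geom_path(data = object$true_midline,
                       ggplot2::aes(x = .data$x, y = .data$row),
                       colour = "red", linewidth = 0.4) +
    ggplot2::geom_point(data = object$true_centroids,
                        ggplot2::aes(x = .data$x, y = .data$row),
                        colour = "cyan", size = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "row") +
    ggplot2::theme_void()
}

#' Overlay pipeline results on the radiograph
#'
#' Fig.-style composite: the input image with the extracted MA (red), the
#' vertical CSL (blue) and the SEV/AV/IEV landmark markers.
#'
#' @param report A `spine_report`.
#' @param image The intensity matrix the report was computed from.
#' @return A ggplot object.
#' @export
plot_overlay <- function(report, image) {
  df <- tibble::tibble(
    row = rep(seq_len(nrow(image)) - 1L, times = ncol(image)),
    col = rep(seq_len(ncol(image)) - 1L, each = nrow(image)),
    intensity = as.vector(image)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::geom_path(data = report$ma,
                       ggplot2::aes(x = .data$x, y = .data$row),
                       colour = "red", linewidth = 0.4) +
    ggplot2::annotate("segment", x = report$csl$x, xend = report$csl$x,
                      y = report$csl$top_row, yend = report$csl$bottom_row,
                      colour = "dodgerblue", linewidth = 0.4) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (nrow(report$landmarks) > 0) {
    p <- p + ggplot2::geom_point(
      data = report$landmarks,
      ggplot2::aes(x = .data$x, y = .data$row, shape = .data$landmark),
      colour = "yellow", size = 2
    )
  }
  p
}
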