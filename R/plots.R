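#' Plot a trial scanpath over the task layout
#'
#' Draws the cue box and grid cells, the fixation sequence (points sized
#' by duration, connected in order) and, optionally, the target cell.
#'
#' @param fixations Fixation tibble for one trial (`x`, `y`, `duration`).
#' @param layout A [task_layout()].
#' @param target_cell Optional cell index to highlight.
#' @return A ggplot object.
#' @export
plot_scanpath <- function(fixations, layout = task_layout(),
                          target_cell = NULL) {
  boxes <- aois(layout)
  boxes$kind <- ifelse(boxes$aoi == "cue", "cue", "cell")
  if (!is.null(target_cell)) {
    boxes$kind[boxes$aoi == cell_label(target_cell)] <- "target"
  }
  fx <- mutate(as_tibble(fixations), order = dplyr::row_number())
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = boxes,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax,
                   fill = .data$kind),
      colour = "grey40", alpha = 0.15) +
    ggplot2::geom_path(data = fx,
                       ggplot2::aes(.data$x, .data$y),
                       colour = "grey30") +
    ggplot2::geom_point(data = fx,
                        ggplot2::aes(.data$x, .data$y,
                                     size = .data$duration,
                                     colour = .data$order),
                        alpha = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(cue = "steelblue",
                                          cell = "grey70",
                                          target = "goldenrod")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", size = "duration (ms)",
                  colour = "fixation #") +
    ggplot2::theme_minimal()
}

#' Plot a recurrence matrix
#'
#' @param labels AOI label sequence or a [recurrence_matrix()].
#' @param exclude Passed to [recurrence_matrix()].
#' @return A ggplot object (tile plot of recurrent pairs).
#' @export
plot_recurrence <- function(labels, exclude = "outside") {
  m <- if (is.matrix(labels)) labels else recurrence_matrix(labels, exclude)
  df <- tibble(i = as.vector(row(m)), j = as.vector(col(m)),
               recurrent = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$j, .data$i,
                                   fill = .data$recurrent)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey92",
                                          `TRUE` = "firebrick")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "fixation j", y = "fixation i", fill = "recurrent") +
    ggplot2::theme_minimal()
}

#' Plot group distributions behind a one-way ANOVA
#'
#' @param object A `vs_anova` object.
#' @param ... Unused.
#' @return A ggplot object: per-group boxplots with jittered points.
#' @export
autoplot.vs_anova <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$g, .data$y)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, colour = "steelblue") +
    ggplot2::labs(
      x = "group", y = object$variable,
      subtitle = sprintf("F(%d, %d) = %.2f, p = %.3g, eta^2 = %.2f",
                         object$df[1], object$df[2], object$f, object$p,
                         object$eta_squared)) +
    ggplot2::theme_minimal()
}
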