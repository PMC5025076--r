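# ggplot2 displays for selection reports, accuracy matrices and scalp
# topographies.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot st-BCI accuracies per trial
#'
#' One point per trial: zero-accuracy round-1 bad trials highlighted, the
#' second-round mean threshold as a horizontal dashed line.
#'
#' @param object A [selection_report].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.selection_report <- function(object, ...) {
  d <- object$data
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$trial_index, y = .data$R_j,
                                       colour = .data$round1_good)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$trial_index, yend = 0),
                          linewidth = 0.3, show.legend = FALSE) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "grey25",
                                            `FALSE` = "red"),
                                 labels = c(`TRUE` = "good", `FALSE` = "bad"),
                                 name = "round 1") +
    ggplot2::labs(x = "trial", y = expression(R[j]),
                  title = "Single-trial BCI accuracies") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!is.na(object$threshold))
    p <- p + ggplot2::geom_hline(yintercept = object$threshold,
                                 linetype = "dashed")
  p
}

#' Heat map of an accuracy matrix
#'
#' Segment index against trial index; sentinel cells (no BCI) are drawn
#' in grey. Low columns localize artifact trials, low cells localize
#' artifact segments.
#'
#' @param object An `accuracy_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.accuracy_matrix <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$trial, y = .data$segment,
                                  fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey70") +
    ggplot2::labs(x = "trial j", y = "segment i", fill = "accuracy",
                  title = sprintf("Accuracy matrix (%s → %s)",
                                  object$train_id, object$test_id)) +
    ggplot2::theme_minimal()
}

#' Simple scalp topography of a spatial pattern
#'
#' Draws one mixing-matrix column (or any per-channel weight vector) as
#' colored discs at the approximate 10-20 electrode positions — a quick
#' look at where a component projects, not an interpolated scalp map.
#'
#' @param weights Numeric vector, one value per channel.
#' @param labels Channel labels (must be known to the built-in montage).
#' @param title Plot title.
#' @return A ggplot.
#' @export
plot_topography <- function(weights, labels, title = "spatial pattern") {
  xy <- montage_coords(labels)
  d <- tibble::tibble(x = xy[, 1], y = xy[, 2], w = as.numeric(weights),
                      label = labels)
  circ <- tibble::tibble(x = cos(seq(0, 2 * pi, length.out = 181)),
                         y = sin(seq(0, 2 * pi, length.out = 181)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = circ, linewidth = 0.3, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(fill = .data$w), shape = 21, size = 9) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 2.5,
                       vjust = -2.2) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", name = "weight") +
    ggplot2::coord_equal(xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3)) +
    ggplot2::labs(title = title) +
    ggplot2::theme_void()
}
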