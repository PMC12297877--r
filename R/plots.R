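#' Plot cell trajectories
#'
#' Draws each track as a path of box centres over the sequence, coloured
#' by identity, with coasted (filter-predicted) boxes marked as open
#' points.
#'
#' @param object A `"cell_tracks"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cell_tracks <- function(object, ...) {
  d <- mutate(object$results,
              cx = .data$x + .data$w / 2, cy = .data$y + .data$h / 2,
              track = factor(.data$track_id))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cx, y = .data$cy,
                                  group = .data$track, colour = .data$track)) +
    ggplot2::geom_path(alpha = 0.7) +
    ggplot2::geom_point(data = d[d$source == "predicted", , drop = FALSE],
                        shape = 1, size = 1.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = "track",
                  title = "Cell trajectories",
                  subtitle = "open points: coasted (filter-predicted) boxes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot per-frame recall of an evaluation
#'
#' Per-frame fraction of ground-truth boxes recovered, with the
#' sequence-level Modified Recall as a horizontal reference line.
#'
#' @param object A `"track_eval"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.track_eval <- function(object, ...) {
  d <- mutate(object$per_frame,
              recall = 100 * .data$tp / pmax(.data$tp + .data$fn, 1L))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frame, y = .data$recall)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_hline(yintercept = object$modified_recall,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "frame", y = "per-frame recall (%)",
                  title = sprintf("Modified Recall %.2f%%, Average IoU %.2f%%",
                                  object$modified_recall, object$average_iou)) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
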