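#' Plot a confusion matrix
#'
#' Row-normalized heat map with counts overlaid and the three macro-class
#' blocks (healthy / ischemic / haemorrhagic) outlined.
#'
#' @param object A `confusion_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.confusion_result <- function(object, ...) {
  df <- tidy.confusion_result(object)
  blocks <- tibble::tibble(
    xmin = c(0.5, 1.5, 5.5), xmax = c(1.5, 5.5, 9.5),
    ymin = c(0.5, 1.5, 5.5), ymax = c(1.5, 5.5, 9.5),
    macro = c("healthy", "ischemic", "haemorrhagic")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$proportion), colour = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$count > 0, .data$count, "")),
                       size = 3) +
    ggplot2::geom_rect(data = blocks,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = .data$ymin, ymax = .data$ymax,
                                    colour = .data$macro),
                       fill = NA, linewidth = 0.8, inherit.aes = FALSE) +
    ggplot2::scale_colour_manual(values = c(healthy = "goldenrod",
                                            ischemic = "forestgreen",
                                            haemorrhagic = "firebrick")) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_discrete(limits = rev(class_levels())) +
    ggplot2::labs(x = "predicted class", y = "true class",
                  fill = "row\nproportion", colour = "macro class") +
    ggplot2::theme_minimal()
}

#' Plot a per-pair error or amplitude matrix in dB
#'
#' Heat map over antenna pairs, e.g. of the Born linearization error from
#' [born_error()] or of 20 log10 |S|.
#'
#' @param mat Numeric Ma x Ma matrix (dB).
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_pair_matrix <- function(mat, title = "per-pair level (dB)") {
  Ma <- nrow(mat)
  df <- tibble::tibble(p = rep(seq_len(Ma), times = Ma),
                       q = rep(seq_len(Ma), each = Ma),
                       db = as.vector(mat))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q, y = .data$p, fill = .data$db)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "transmitter q", y = "receiver p", fill = "dB",
                  title = title) +
    ggplot2::theme_minimal()
}

#' Plot the per-class composition of a dataset
#' @param object A `stroke_dataset`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stroke_dataset <- function(object, ...) {
  df <- dplyr::count(tibble::tibble(label = object$label), .data$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$n,
                                   fill = macro_class(.data$label))) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(healthy = "goldenrod",
                                          ischemic = "forestgreen",
                                          haemorrhagic = "firebrick")) +
    ggplot2::labs(x = "class", y = "records", fill = "macro class") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
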