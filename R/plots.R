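#' Plot a local feature spectrum
#'
#' Bar chart of atom usage counts for one candidate.
#'
#' @param object A `spectrum_feature`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spectrum_feature <- function(object, ...) {
  df <- tibble::tibble(atom = seq_along(object$counts),
                       count = object$counts)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$atom, y = .data$count)) +
    ggplot2::geom_col(width = 1, fill = "grey25") +
    ggplot2::labs(x = "dictionary atom", y = "usage count",
                  title = object$candidate_id) +
    ggplot2::theme_minimal()
}

#' Plot a learning curve
#'
#' Mean accuracy with a +/- 1 sd ribbon against training-set size, one line
#' per classifier.
#'
#' @param object An `lfsa_learning_curve` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lfsa_learning_curve <- function(object, ...) {
  summ <- object |>
    dplyr::group_by(.data$classifier, .data$size) |>
    dplyr::summarise(mean = mean(.data$accuracy),
                     sd = stats::sd(.data$accuracy), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$size, y = .data$mean,
                                     colour = .data$classifier,
                                     fill = .data$classifier)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "disc training samples", y = "test accuracy") +
    ggplot2::theme_minimal()
}

#' Plot a parameter-grid result
#'
#' Accuracy (and optionally reconstruction error) against dictionary size,
#' one panel per patch size, one line per dictionary method.
#'
#' @param object An `lfsa_grid` tibble from [run_grid()].
#' @param metric `"mean_accuracy"` or `"r_error"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lfsa_grid <- function(object, metric = c("mean_accuracy", "r_error"),
                               ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$Dsize, y = .data[[metric]],
                               colour = .data$dict_method,
                               linetype = .data$classifier)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$M), scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "dictionary size", y = metric) +
    ggplot2::theme_minimal()
}

#' Reconstruction diagnostic panel
#'
#' Draws original, reconstruction and error image side by side for one
#' candidate.
#'
#' @param report A `reconstruction_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_reconstruction <- function(report, ...) {
  stopifnot(inherits(report, "reconstruction_report"))
  as_df <- function(m, panel) {
    tibble::tibble(row = as.vector(row(m)), col = as.vector(col(m)),
                   value = as.vector(m), panel = panel)
  }
  orig <- report$reconstructed + report$error_image
  df <- dplyr::bind_rows(as_df(orig, "original"),
                         as_df(report$reconstructed, "reconstructed"),
                         as_df(report$error_image, "error"))
  df$panel <- factor(df$panel, c("original", "reconstructed", "error"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(ggplot2::vars(.data$panel)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
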