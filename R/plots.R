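#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot paired PLS scores
#'
#' Scatter of context scores against shape scores for one PLS dimension,
#' optionally coloured by a habitat label.
#'
#' @param object A `shape_pls`.
#' @param dimension Which dimension to plot.
#' @param habitat Optional named character vector (species -> label) used
#'   for colour.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shape_pls <- function(object, dimension = 1, habitat = NULL, ...) {
  ids <- rownames(object$x_scores) %||% as.character(seq_len(nrow(object$x_scores)))
  df <- tibble::tibble(
    species_id = ids,
    shape = object$x_scores[, dimension],
    context = object$y_scores[, dimension],
    habitat = if (is.null(habitat)) "all" else habitat[ids]
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$context, y = .data$shape)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$habitat), size = 2) +
    ggplot2::labs(
      x = sprintf("Context scores, dimension %d", dimension),
      y = sprintf("Shape scores, dimension %d", dimension),
      title = sprintf("PLS %d (%.1f%% of summed squared covariance)",
                      dimension, object$pct_sq_cov[dimension])
    ) +
    ggplot2::theme_minimal()
  if (is.null(habitat)) p <- p + ggplot2::guides(colour = "none")
  p
}

#' Plot pair-type average distances
#'
#' Bar chart of the four pair-type mean Procrustes distances; convergence
#' shows as the analogue bar sitting below the other three.
#'
#' @param object A `convergence_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.convergence_report <- function(object, ...) {
  df <- tidy(object)
  df$label <- factor(df$label, levels = df$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = NULL, y = "Mean Procrustes distance",
      title = sprintf("Non-analogue excess %.1f%% (p = %.3g)",
                      object$excess_pct, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Plot leave-k-out stability
#'
#' Distribution of the non-analogue excess percentage across replicates;
#' a stable convergence conclusion keeps all replicates above zero.
#'
#' @param object A `stability_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stability_report <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), !.data$skipped)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$excess_pct)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = "Non-analogue excess (%)", y = "Replicates",
      title = sprintf("Leave-%s-out stability", attr(object, "mode") %||% "k")
    ) +
    ggplot2::theme_minimal()
}
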