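#' Heatmap of an acceptance or Fisher-mean matrix
#'
#' Convenience ggplot2 heatmap of a features-by-windows matrix, with
#' features in registry order on the y axis and windows from the reference
#' down to 10 s on the x axis. Requires ggplot2 (suggested dependency).
#'
#' @param mat A matrix from an `acceptance_matrix` (`$pct`) or
#'   `correlation_summary` (`$fisher_mean` / `$sig_pct`).
#' @param label Fill legend label.
#' @return A ggplot object.
#' @export
plot_reliability_matrix <- function(mat, label = "value") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_reliability_matrix needs the ggplot2 package", call. = FALSE)
  }
  df <- expand.grid(feature_id = rownames(mat), window = colnames(mat),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$value <- as.vector(mat)
  df$feature_id <- factor(df$feature_id, levels = rev(rownames(mat)))
  df$window <- factor(df$window, levels = colnames(mat))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$window, y = .data$feature_id,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = label, na.value = "grey85") +
    ggplot2::labs(x = "extraction window", y = NULL) +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot for one feature/window/run
#'
#' @param summary A `bland_altman_summary` from [bland_altman()].
#' @param title Optional plot title.
#' @return A ggplot object showing the paired differences with the median
#'   bias and the 2.5/97.5-percentile limits of agreement.
#' @export
plot_bland_altman <- function(summary, title = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_bland_altman needs the ggplot2 package", call. = FALSE)
  }
  df <- data.frame(index = seq_along(summary$d), d = summary$d)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$d)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = summary$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(summary$loa_low, summary$loa_high),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "pair index (reference instants)",
                  y = "difference (short - reference)", title = title) +
    ggplot2::theme_minimal()
}
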