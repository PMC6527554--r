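#' Plot a power curve
#'
#' @param object A [power_curve()] result.
#' @param target Optional horizontal reference line (e.g. 0.8).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cp_power_curve <- function(object, target = 0.8, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$n, y = .data$power)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(color = "steelblue") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "samples per group", y = "power",
      title = sprintf(
        "Power curve (Δ = %g, α = %g, μ = %g, σ = %g)",
        attr(object, "delta"), attr(object, "alpha"),
        attr(object, "mu"), attr(object, "sigma")
      )
    ) +
    ggplot2::theme_minimal()
  if (!is.null(target)) {
    p <- p + ggplot2::geom_hline(yintercept = target, linetype = "dashed")
  }
  p
}

#' Plot gene detectability on the log2CPM-BCOV plane
#'
#' Mean expression against biological variability, split by detectability
#' status (power at or below the cutoff).
#'
#' @param object A [genewise_power()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cp_detectability <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$log2cpm, y = .data$bcov, color = .data$detectable)
  ) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::scale_color_manual(
      values = c(`TRUE` = "#2166ac", `FALSE` = "#b2182b"),
      labels = c(`TRUE` = "power ≥ cutoff", `FALSE` = "power < cutoff")
    ) +
    ggplot2::labs(
      x = "average log2 CPM", y = "BCOV", color = NULL,
      title = "Gene-wise detectability"
    ) +
    ggplot2::theme_minimal()
}

#' MA plot of a differential-expression result
#'
#' @param object A `cp_de` tibble.
#' @param de_fdr_cutoff FDR cutoff for highlighting.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cp_de <- function(object, de_fdr_cutoff = 0.05, ...) {
  ma <- ma_data(object, de_fdr_cutoff)
  ggplot2::ggplot(
    ma,
    ggplot2::aes(
      x = .data$mean_log2cpm, y = .data$log2_fc, color = .data$significant
    )
  ) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::scale_color_manual(
      values = c(`TRUE` = "#d7301f", `FALSE` = "grey50")
    ) +
    ggplot2::labs(
      x = "average log2 CPM (A)", y = "log2 fold change (M)",
      color = sprintf("FDR < %g", de_fdr_cutoff), title = "MA plot"
    ) +
    ggplot2::theme_minimal()
}

#' Bar plot of triage category counts
#'
#' Gene counts (log10 scale) in the DE / NDE_DT / NDE_NDT classes.
#'
#' @param object A [triage()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cp_triage <- function(object, ...) {
  cnt <- tibble::as_tibble(as.data.frame(attr(object, "counts")))
  names(cnt) <- c("label", "n")
  ggplot2::ggplot(cnt, ggplot2::aes(x = .data$label, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = NULL, y = "genes (log10)",
      title = "Differential expression and detectability triage"
    ) +
    ggplot2::theme_minimal()
}

#' Scatter plot of an embedding
#'
#' @param object A [pca_embedding()] or [tsne_embedding()] result.
#' @param color Optional vector (one value per sample) to color points by.
#' @param ... Unused.
#' @return A ggplot of the first two dimensions.
#' @export
autoplot.cp_embedding <- function(object, color = NULL, ...) {
  tab <- tidy.cp_embedding(object)
  if (!is.null(color)) tab$color <- color
  aes <- if (is.null(color)) {
    ggplot2::aes(x = .data$dim1, y = .data$dim2)
  } else {
    ggplot2::aes(x = .data$dim1, y = .data$dim2, color = .data$color)
  }
  ggplot2::ggplot(tab, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "dimension 1", y = "dimension 2", color = NULL,
      title = toupper(object$method)
    ) +
    ggplot2::theme_minimal()
}

#' Correlation heatmap of samples
#'
#' @param cor_mat A [correlation_matrix()] result.
#' @return A ggplot tile heatmap (samples ordered as given).
#' @export
plot_correlation_heatmap <- function(cor_mat) {
  tab <- tibble::as_tibble(cor_mat, rownames = "sample_a") |>
    tidyr::pivot_longer(-"sample_a",
      names_to = "sample_b", values_to = "r"
    )
  tab$sample_a <- factor(tab$sample_a, levels = rownames(cor_mat))
  tab$sample_b <- factor(tab$sample_b, levels = colnames(cor_mat))
  ggplot2::ggplot(
    tab,
    ggplot2::aes(x = .data$sample_a, y = .data$sample_b, fill = .data$r)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "#2166ac", mid = "white", high = "#b2182b",
      midpoint = stats::median(cor_mat)
    ) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
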