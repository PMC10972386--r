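#' @name plots
#' @title ggplot2 methods for pipeline results
NULL

#' PCA score plot
#'
#' @param object A [pca_diagnostics()] result.
#' @param colour Metadata column to colour by (`"batch"`, `"injury"`,
#'   `"sex"`).
#' @param components Two component names (default PC1/PC2).
#' @param ellipse Draw 95% normal confidence ellipses per colour group.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pca_diag
#' @export
autoplot.pca_diag <- function(object, colour = "batch",
                              components = c("PC1", "PC2"),
                              ellipse = TRUE, ...) {
  df <- object$scores
  df$.grp <- factor(df[[colour]])
  idx <- as.integer(sub("PC", "", components))
  labs <- sprintf("%s (%.1f%%)", components,
                  100 * object$variance_fraction[idx])
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data[[components[1]]], y = .data[[components[2]]],
    colour = .data$.grp)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = labs[1], y = labs[2], colour = colour) +
    ggplot2::theme_minimal()
  if (ellipse && all(base::table(df$.grp) >= 3)) {
    p <- p + ggplot2::stat_ellipse(level = 0.95)
  }
  p
}

#' Volcano plot
#'
#' @param object A [volcano()] result.
#' @param ... Unused.
#' @return A ggplot object: log2 fold change vs -log10 Tukey-adjusted p, with
#'   the up/down classification coloured and thresholds drawn.
#' @method autoplot volcano_result
#' @export
autoplot.volcano_result <- function(object, ...) {
  df <- as_tibble(object)
  alpha <- attr(object, "alpha")
  fc <- attr(object, "fc_threshold")
  ggplot2::ggplot(df, ggplot2::aes(x = log2(.data$fold_change),
                                   y = -log10(pmax(.data$p_tukey, 1e-300)),
                                   colour = .data$volcano_class)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-log2(fc), log2(fc)),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2980b9",
                                            ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p",
                  colour = NULL, title = df$contrast[1]) +
    ggplot2::theme_minimal()
}

#' Subclass direction bar chart
#'
#' @param tally A [subclass_tally()] result.
#' @return A ggplot object: per-subclass counts of increased (+) and
#'   decreased (-) species.
#' @export
plot_subclass_tally <- function(tally) {
  df <- tally |>
    tidyr::pivot_longer(c("n_increased", "n_decreased"),
                        names_to = "direction", values_to = "n") |>
    mutate(direction = ifelse(.data$direction == "n_increased",
                              "increased", "decreased"),
           n = ifelse(.data$direction == "decreased", -.data$n, .data$n))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subclass, y = .data$n,
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "species (+ up / - down)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Correlation heatmap
#'
#' @param object A [correlation_matrix()] result.
#' @param ... Unused.
#' @return A ggplot tile heatmap of Spearman rho.
#' @method autoplot lipid_cytokine_cor
#' @export
autoplot.lipid_cytokine_cor <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cytokine, y = .data$lipid,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2980b9", mid = "white",
                                  high = "#c0392b", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Cytokine z-score heatmap
#'
#' @param panel A [cytokine_panel()] (after [linear_range_filter()]).
#' @return A ggplot tile heatmap of per-analyte z-scores with animals grouped
#'   by injury.
#' @export
plot_cytokine_heatmap <- function(panel) {
  z <- zscore_by_analyte(panel)
  an <- panel_animals(panel)
  df <- z |>
    tidyr::pivot_longer(-"analyte", names_to = "sample_id",
                        values_to = "z") |>
    left_join(an, by = "sample_id") |>
    mutate(sample_id = factor(.data$sample_id,
                              levels = an$sample_id[order(an$injury, an$batch)]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$analyte,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2980b9", mid = "white",
                                  high = "#c0392b") +
    ggplot2::facet_grid(~injury, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
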