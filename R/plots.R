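#' Plot the scale-free topology fit across candidate powers
#'
#' @param threshold Result of [pick_soft_threshold()].
#' @param target_fit Horizontal reference line (default 0.9).
#' @return A ggplot object.
#' @export
plot_scale_free_fit <- function(threshold, target_fit = 0.9) {
  ggplot2::ggplot(threshold$fit_table,
                  ggplot2::aes(x = .data$power, y = .data$sft_r_sq)) +
    ggplot2::geom_hline(yintercept = target_fit, linetype = "dashed",
                        colour = "red") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = threshold$power, colour = "steelblue") +
    ggplot2::labs(x = "soft-threshold power",
                  y = expression("signed scale-free fit" ~ R^2),
                  title = sprintf("Selected power: %d", threshold$power)) +
    ggplot2::theme_minimal()
}

#' Heatmap of cross-network module overlap significance
#'
#' Tiles are `-log10(p)` of the per-cell Fisher test, annotated with the
#' overlap count.
#'
#' @param overlap Tibble from [module_overlap_fisher()].
#' @param cap Upper cap on `-log10(p)` for the fill scale (default 50).
#' @return A ggplot object.
#' @export
plot_overlap_heatmap <- function(overlap, cap = 50) {
  overlap$neg_log10_p_capped <- pmin(overlap$neg_log10_p, cap)
  ggplot2::ggplot(overlap,
                  ggplot2::aes(x = factor(.data$module_a),
                               y = factor(.data$module_b),
                               fill = .data$neg_log10_p_capped)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_both), size = 3) +
    ggplot2::scale_fill_viridis_c(name = expression(-log[10] ~ p)) +
    ggplot2::labs(x = "modules (network A)", y = "modules (network B)") +
    ggplot2::theme_minimal()
}

#' Zsummary preservation plot
#'
#' Zsummary against module size (log scale) with the strong (>10) and
#' no-evidence (<2) reference lines.
#'
#' @param report A `preservation_report` ([preservation_stats()]).
#' @return A ggplot object.
#' @export
plot_preservation <- function(report) {
  ggplot2::ggplot(report, ggplot2::aes(x = .data$size, y = .data$z_summary,
                                       label = .data$module)) +
    ggplot2::geom_hline(yintercept = c(2, 10), linetype = "dashed",
                        colour = c("red", "darkgreen")) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$module == "gold"),
                        show.legend = FALSE) +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "module size", y = "Zsummary") +
    ggplot2::theme_minimal()
}

#' Module-trait association grid
#'
#' One tile per module x trait level, coloured by evidence label and marked
#' with the direction of the pooled effect.
#'
#' @param assoc Tibble from [run_multitree_association()].
#' @return A ggplot object.
#' @export
plot_module_trait_grid <- function(assoc) {
  assoc$cell <- paste(assoc$trait, assoc$level, sep = ":")
  ggplot2::ggplot(assoc, ggplot2::aes(x = .data$cell, y = .data$module,
                                      fill = .data$label)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$significant,
                     ifelse(.data$direction == "positive", "+", "-"), "")),
      size = 4) +
    ggplot2::scale_fill_manual(values = c(none = "grey95", weak = "gold",
                                          strong = "firebrick")) +
    ggplot2::labs(x = "trait level", y = "module") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Eigengene expression profile plot
#'
#' @param eigengenes An `eigengene_set`.
#' @param meta Sample metadata (`sample`, `species`).
#' @param modules Optional subset of module names (e.g. `"ME1"`).
#' @return A ggplot object.
#' @export
plot_eigengenes <- function(eigengenes, meta, modules = NULL) {
  df <- tidy(eigengenes)
  df$species <- meta$species[match(df$sample, meta$sample)]
  if (!is.null(modules)) df <- df[df$module %in% modules, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$species, y = .data$value)) +
    ggplot2::geom_hline(yintercept = c(-1, 1), linetype = "dotted") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~module) +
    ggplot2::labs(x = NULL, y = "eigengene expression") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
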