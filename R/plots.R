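#' Plot ddPCR / RNA-seq concordance
#'
#' Scatter of normalized mean read values against ddPCR means (log10 axes),
#' one facet per normalization method, annotated with the pooled Pearson r.
#'
#' @param object A `circ_concordance` from [concordance_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.circ_concordance <- function(object, ...) {
  pairs <- attr(object, "pairs")
  labs <- object %>%
    filter(.data$stratum == "all") %>%
    mutate(label = sprintf("r = %.2f", .data$r))
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$cp_per_ug, y = .data$mean)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$organ), alpha = 0.8) +
    ggplot2::geom_text(data = labs, ggplot2::aes(label = .data$label),
                       x = -Inf, y = Inf, hjust = -0.15, vjust = 1.5,
                       inherit.aes = FALSE, size = 3) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~method, scales = "free_y") +
    ggplot2::labs(x = "ddPCR (cp/µg)", y = "normalized reads",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Pairwise differential-accumulation scatter
#'
#' Mean-versus-mean scatter (log10 + pseudocount) for one or more organ
#' pairs, with the fold-change cutoff as dashed lines and significant
#' circRNAs highlighted in red.
#'
#' @param results Tibble from [pairwise_diff()] or [all_pairwise_diff()].
#' @param fc_cutoff Fold-change cutoff drawn as dashed lines.
#' @param pseudocount Offset used for the log axes.
#' @return A ggplot object.
#' @export
plot_diff_pairs <- function(results, fc_cutoff = 2, pseudocount = 0.5) {
  pc <- pseudocount
  d <- mutate(results,
              pair = paste(.data$organ_a, "vs", .data$organ_b),
              a = .data$mean_a + pc, b = .data$mean_b + pc)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$b, y = .data$a)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_abline(slope = 1, intercept = log10(fc_cutoff),
                         linetype = "dashed", colour = "grey40") +
    ggplot2::geom_abline(slope = 1, intercept = -log10(fc_cutoff),
                         linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant),
                        alpha = 0.7, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "red")) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~pair) +
    ggplot2::labs(x = "mean normalized reads (B)",
                  y = "mean normalized reads (A)", colour = "significant") +
    ggplot2::theme_minimal()
}

#' Abundance-class heatmap
#'
#' Tile heatmap of the discrete abundance classes (high / medium / low /
#' not detected) per circRNA and organ, with rows ordered by hierarchical
#' clustering of the underlying abundances when provided.
#'
#' @param classes Tibble from [classify_abundance()].
#' @param organ_means Optional aggregated abundances used to order rows
#'   via [cluster_order()]; otherwise rows keep their input order.
#' @return A ggplot object.
#' @export
plot_abundance_classes <- function(classes, organ_means = NULL) {
  d <- classes
  if (!is.null(organ_means) &&
      length(unique(d$circ_id)) >= 2L) {
    ord <- cluster_order(organ_means)
    d <- mutate(d, circ_id = factor(.data$circ_id, levels = ord))
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$organ, y = .data$circ_id,
                                  fill = .data$class)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(high = "#b2182b",
                                          medium = "#ef8a62",
                                          low = "#fddbc7",
                                          not_detected = "#2166ac")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "abundance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Circular versus linear abundance scatter
#'
#' @param object A `circ_linear` from [circ_linear_analysis()].
#' @param ratio_cutoff Enrichment cutoff drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.circ_linear <- function(object, ratio_cutoff = 1.5, ...) {
  d <- filter(object$pairs, !is.na(.data$linear))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$linear + 1, y = .data$circ + 1)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_abline(slope = 1, intercept = log10(ratio_cutoff),
                         linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$organ), alpha = 0.7,
                        size = 1) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "linear transcript (normalized + 1)",
                  y = "circRNA (normalized + 1)", colour = NULL) +
    ggplot2::theme_minimal()
}
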