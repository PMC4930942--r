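# ggplot2 figure helpers for the main result types.

#' Fold-change quadrant scatterplot
#'
#' Each gene's night-contrast log2 fold change (WT-SD vs WT-LL) against its
#' genotype-contrast fold change (pifq-SD vs WT-SD), colored by class:
#' reciprocal-sign quadrants hold the induced and repressed sets.
#'
#' @param classification Tibble from [classify_genes()].
#' @param drop_none Drop unregulated genes from the plot (default TRUE).
#' @return A ggplot.
#' @export
plot_quadrants <- function(classification, drop_none = TRUE) {
  df <- classification
  if (drop_none) df <- df[df$label != "none", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sd_log2fc, y = .data$pif_log2fc,
                                   colour = .data$label)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(x = "log2 FC (WT SD vs WT LL)",
                  y = "log2 FC (pifq SD vs WT SD)", colour = "class") +
    ggplot2::theme_minimal()
}

#' Bar graph of set-mean log2 fold changes relative to WT-LL
#'
#' @param set_means Tibble from [set_mean_fc()] rows (columns group,
#'   mean_fc, se).
#' @return A ggplot.
#' @export
plot_set_means <- function(set_means) {
  ggplot2::ggplot(set_means, ggplot2::aes(x = .data$group, y = .data$mean_fc)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_fc - .data$se,
                                        ymax = .data$mean_fc + .data$se),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "mean log2 FC vs WT-LL") +
    ggplot2::theme_minimal()
}

#' Radial phase-enrichment plot (count / expected per phase bin)
#'
#' @param enrichment Tibble from [phase_bin_enrichment()].
#' @return A ggplot in polar coordinates.
#' @export
plot_phase_enrichment <- function(enrichment) {
  ggplot2::ggplot(enrichment,
                  ggplot2::aes(x = .data$bin_start + (.data$bin_end - .data$bin_start) / 2,
                               y = .data$fold)) +
    ggplot2::geom_col(fill = "steelblue", width = enrichment$bin_end[1] - enrichment$bin_start[1]) +
    ggplot2::coord_polar(start = 0) +
    ggplot2::scale_x_continuous(limits = c(0, max(enrichment$bin_end)),
                                breaks = seq(0, max(enrichment$bin_end), by = 4)) +
    ggplot2::labs(x = "phase (h)", y = "count / expected") +
    ggplot2::theme_minimal()
}

#' Median and quartile diurnal profile of a gene set
#'
#' @param profile Tibble from [set_median_profile()].
#' @return A ggplot.
#' @export
plot_median_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$time_h)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), linewidth = 1) +
    ggplot2::labs(x = "time (h)", y = "log2 expression") +
    ggplot2::theme_minimal()
}
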