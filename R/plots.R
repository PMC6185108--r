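#' Volcano plot of a differential-result table
#'
#' @param results A differential-result tibble
#'   (from [paired_protein_test()] or [glyco_site_test()]).
#' @param use_q Colour by q-value calls instead of p-value calls when
#'   available (default: automatic from the table).
#' @return A ggplot object.
#' @export
plot_volcano <- function(results, use_q = NULL) {
  df <- results[!is.na(results$p_value), , drop = FALSE]
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$log2_fold_change,
                 y = -log10(.data$p_value),
                 colour = .data$status)
  ) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(
      decreased = "#c0392b", increased = "#2980b9", unchanged = "grey60",
      exclusive_control = "#8e44ad", exclusive_mutant = "#16a085"
    )) +
    ggplot2::labs(
      x = "log2 fold change (mutant - control)",
      y = expression(-log[10] ~ p),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot multiplicity-threshold enrichment
#'
#' Fold enrichment of high-multiplicity glycoproteins among the decreased
#' set, per threshold; the >= 1 bar is the no-enrichment anchor.
#'
#' @param enrichment The tibble returned by [multiplicity_enrichment()].
#' @return A ggplot object.
#' @export
plot_multiplicity_enrichment <- function(enrichment) {
  df <- dplyr::mutate(enrichment,
                      label = paste0("≥", .data$threshold),
                      significant = .data$p_value < 0.05)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label,
                                   y = .data$fold_enrichment,
                                   fill = .data$significant)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey40") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#c0392b",
                                          `FALSE` = "grey65"),
                               guide = "none") +
    ggplot2::labs(x = "N-glycosylation multiplicity",
                  y = "fold enrichment among decreased") +
    ggplot2::theme_minimal()
}

#' Plot sequon-position motif enrichment
#'
#' Per-position, per-residue fold enrichment within decreased sites, sized by
#' significance; headline class features are excluded (they are summary
#' rows, not single residues).
#'
#' @param motif The list returned by [sequon_position_enrichment()].
#' @return A ggplot object.
#' @export
plot_motif_enrichment <- function(motif) {
  df <- motif$features |>
    dplyr::filter(!.data$feature %in% c("minus2_nonaromatic", "plus2_ser"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$feature)) +
    ggplot2::geom_point(ggplot2::aes(size = -log10(.data$p_value),
                                     colour = log2(.data$fold_enrichment))) +
    ggplot2::scale_colour_gradient2(low = "#2980b9", mid = "grey80",
                                    high = "#c0392b", midpoint = 0) +
    ggplot2::scale_x_continuous(breaks = sort(unique(df$position))) +
    ggplot2::labs(x = "position relative to Asn", y = "residue",
                  size = expression(-log[10] ~ p),
                  colour = expression(log[2] ~ fold)) +
    ggplot2::theme_minimal()
}

#' @rdname nxs_multiplicity_correlation
#' @param object An `nxs_correlation` object.
#' @param ... Unused.
#' @method autoplot nxs_correlation
#' @export
autoplot.nxs_correlation <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$bin, y = .data$pct_nxs,
                               colour = .data$series,
                               linetype = .data$series)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::scale_colour_manual(values = c(decreased = "black",
                                            unchanged = "grey55")) +
    ggplot2::labs(x = "protein N-glycosylation multiplicity (pooled at cap)",
                  y = "% NxS sequons") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano plot of the glyco branch of a pipeline run
#'
#' @param object A `glyco_pipeline` object.
#' @param ... Passed to [plot_volcano()].
#' @method autoplot glyco_pipeline
#' @export
autoplot.glyco_pipeline <- function(object, ...) {
  plot_volcano(object$glyco_results, ...)
}
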