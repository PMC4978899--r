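#' Male-vs-female expression scatter for an exon-DE fit
#'
#' Plots the per-region mean ln-RPKM of one condition against the other
#' (male TRAP vs female TRAP by default), colouring each exonic region
#' by its significance tier in the chosen contrast: not significant,
#' significant at the primary FDR threshold, and significant at the
#' strict threshold.
#'
#' @param object An `exon_de` object.
#' @param contrast Contrast whose significance tiers colour the points
#'   (default `"MT-FT"`).
#' @param x_condition,y_condition Conditions on the axes (defaults `"FT"`
#'   and `"MT"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.exon_de <- function(object, contrast = "MT-FT",
                             x_condition = "FT", y_condition = "MT", ...) {
  means <- object$group_stats |>
    dplyr::filter(.data$condition %in% c(x_condition, y_condition)) |>
    tidyr::pivot_wider(id_cols = "region_id", names_from = "condition",
                       values_from = "mean")
  tiers <- object$results |>
    dplyr::filter(.data$contrast == !!contrast) |>
    dplyr::mutate(tier = dplyr::case_when(
      .data$significant_strict ~
        sprintf("FDR < %.2g", object$config$fdr_strict),
      .data$significant ~
        sprintf("FDR <= %.2g", object$config$fdr_primary),
      TRUE ~ "NS"
    )) |>
    dplyr::select("region_id", "tier")
  dat <- dplyr::inner_join(means, tiers, by = "region_id")
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data[[x_condition]], y = .data[[y_condition]],
    colour = .data$tier
  )) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = setNames(
      c("grey30", "steelblue", "orange"),
      c("NS", sprintf("FDR <= %.2g", object$config$fdr_primary),
        sprintf("FDR < %.2g", object$config$fdr_strict))
    )) +
    ggplot2::labs(
      x = paste("mean ln-RPKM,", x_condition),
      y = paste("mean ln-RPKM,", y_condition),
      colour = paste("contrast", contrast)
    ) +
    ggplot2::theme_minimal()
}

#' Observed vs expected gene counts per chromosome
#'
#' Bar plot of a [chromosome_enrichment()] table: observed list-gene
#' counts next to the counts expected from the universe's chromosome
#' composition, with chromosomes significant at p < 0.001 starred.
#'
#' @param enrichment Tibble from [chromosome_enrichment()] (optionally
#'   with a `gene_list` facet column, as produced by
#'   [run_trap_pipeline()]).
#' @return A ggplot object.
#' @export
plot_chromosome_enrichment <- function(enrichment) {
  long <- enrichment |>
    tidyr::pivot_longer(c("observed", "expected"),
                        names_to = "kind", values_to = "genes")
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$chromosome, y = .data$genes, fill = .data$kind
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(
      data = dplyr::filter(enrichment, .data$significant),
      ggplot2::aes(x = .data$chromosome,
                   y = pmax(.data$observed, .data$expected),
                   label = "***"),
      inherit.aes = FALSE, vjust = -0.3
    ) +
    ggplot2::scale_fill_manual(values = c(observed = "darkgreen",
                                          expected = "darkseagreen2")) +
    ggplot2::labs(x = "chromosome", y = "genes", fill = NULL) +
    ggplot2::theme_minimal()
  if ("gene_list" %in% names(enrichment)) {
    p <- p + ggplot2::facet_wrap(~gene_list, scales = "free_y")
  }
  p
}
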