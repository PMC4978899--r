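#' Directional exon-level calls
#'
#' Converts contrast results into per-exon boolean calls, imposing the
#' direction requirement: an exon is declared TRAP-enriched only when the
#' abundance is higher in the TRAP sample than in the input from the same
#' sex (the within-sex contrast estimate is positive), never merely
#' significantly different. Sex bias is read from the sign of the
#' between-sex contrasts, so male- and female-biased calls are mutually
#' exclusive for one exon.
#'
#' @param de An `exon_de` object from [run_exon_de()], or its `results`
#'   tibble.
#' @param fdr Significance threshold on the adjusted p-value (inclusive;
#'   default the fit's primary threshold, 0.2).
#' @param trap_male,trap_female,sex_trap,sex_input Names of the contrasts
#'   carrying male TRAP enrichment, female TRAP enrichment, TRAP sex bias
#'   and input sex bias. Defaults match [default_contrasts()]; the sex
#'   contrasts must be oriented male minus female.
#' @return A tibble with `region_id` and logical columns
#'   `trap_enriched_male`, `trap_enriched_female`, `male_biased_trap`,
#'   `female_biased_trap`, `male_biased_input`, `female_biased_input`.
#' @export
classify_exons <- function(de, fdr = NULL,
                           trap_male = "MT-MI", trap_female = "FT-FI",
                           sex_trap = "MT-FT", sex_input = "MI-FI") {
  results <- if (inherits(de, "exon_de")) de$results else de
  if (is.null(fdr)) {
    fdr <- if (inherits(de, "exon_de")) de$config$fdr_primary else 0.2
  }
  need <- c(trap_male, trap_female, sex_trap, sex_input)
  missing <- setdiff(need, unique(results$contrast))
  if (length(missing) > 0L) {
    stop("contrast(s) missing from results: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  wide <- results |>
    dplyr::filter(.data$contrast %in% need) |>
    tidyr::pivot_wider(id_cols = "region_id", names_from = "contrast",
                       values_from = c("estimate", "p_fdr"))
  est <- function(name) wide[[paste0("estimate_", name)]]
  sig <- function(name) wide[[paste0("p_fdr_", name)]] <= fdr
  for (nm in need) {
    if (anyNA(wide[[paste0("p_fdr_", nm)]])) {
      stop("contrast '", nm, "' missing for some region(s)", call. = FALSE)
    }
  }
  tibble::tibble(
    region_id = wide$region_id,
    trap_enriched_male = sig(trap_male) & est(trap_male) > 0,
    trap_enriched_female = sig(trap_female) & est(trap_female) > 0,
    male_biased_trap = sig(sex_trap) & est(sex_trap) > 0,
    female_biased_trap = sig(sex_trap) & est(sex_trap) < 0,
    male_biased_input = sig(sex_input) & est(sex_input) > 0,
    female_biased_input = sig(sex_input) & est(sex_input) < 0
  )
}

exon_flag_names <- c(
  "trap_enriched_male", "trap_enriched_female",
  "male_biased_trap", "female_biased_trap",
  "male_biased_input", "female_biased_input"
)

#' Roll exon calls up to gene-level categories
#'
#' A gene carries a category when at least one of its exonic regions has
#' the corresponding call. Derived categories: TRAP-enriched in both sexes
#' is the intersection of the per-sex enrichments and the "uniquely"
#' enriched sets are their set differences; sex-specific exon usage
#' (input) requires at least one male-biased and one female-biased input
#' exon in the same gene; the sex-biased-exon category (TRAP) is the
#' analogue for TRAP sex bias, so a gene can be both male- and
#' female-biased when different exons go in different directions;
#' sex-specific exon enrichment requires one exon enriched only in the
#' male TRAP and another enriched only in the female TRAP. Regions shared
#' by several genes contribute their calls to every owning gene.
#'
#' @param exon_calls Tibble from [classify_exons()].
#' @param regions Region catalog ([build_exonic_regions()]).
#' @param core_genes Optional character vector of core genes (detected in
#'   the TRAP fraction of both sexes, [detect_genes()] with
#'   `class = "core"`); fills the `core` column.
#' @return A tibble with one row per gene and logical category columns.
#' @export
rollup_genes <- function(exon_calls, regions, core_genes = NULL) {
  map <- region_gene_map(regions)
  calls <- dplyr::inner_join(exon_calls, map, by = "region_id")
  orphan <- setdiff(exon_calls$region_id, map$region_id)
  if (length(orphan) > 0L) {
    stop("exon call(s) for region(s) absent from the catalog: ",
         paste(head(orphan, 5L), collapse = ", "), call. = FALSE)
  }
  per_gene <- calls |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(exon_flag_names), any),
      sex_specific_exon_usage_input =
        any(.data$male_biased_input) & any(.data$female_biased_input),
      sex_biased_exon_trap =
        any(.data$male_biased_trap) & any(.data$female_biased_trap),
      sex_specific_exon_enrichment =
        any(.data$trap_enriched_male & !.data$trap_enriched_female) &
        any(.data$trap_enriched_female & !.data$trap_enriched_male),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      trap_enriched_both =
        .data$trap_enriched_male & .data$trap_enriched_female,
      trap_enriched_male_only =
        .data$trap_enriched_male & !.data$trap_enriched_female,
      trap_enriched_female_only =
        .data$trap_enriched_female & !.data$trap_enriched_male
    )
  all_genes <- sort(unique(c(map$gene_id, core_genes)))
  out <- tibble::tibble(gene_id = all_genes) |>
    dplyr::left_join(per_gene, by = "gene_id") |>
    dplyr::mutate(dplyr::across(dplyr::where(is.logical),
                                \(x) tidyr::replace_na(x, FALSE)),
                  core = .data$gene_id %in% (core_genes %||% character()))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

gene_category_names <- c(
  "male_biased_input", "female_biased_input",
  "sex_specific_exon_usage_input",
  "trap_enriched_male", "trap_enriched_female", "trap_enriched_both",
  "trap_enriched_male_only", "trap_enriched_female_only",
  "sex_specific_exon_enrichment",
  "male_biased_trap", "female_biased_trap", "sex_biased_exon_trap",
  "core"
)

# which exon flag (if any) backs each gene category's exon count
category_exon_flag <- c(
  male_biased_input = "male_biased_input",
  female_biased_input = "female_biased_input",
  trap_enriched_male = "trap_enriched_male",
  trap_enriched_female = "trap_enriched_female",
  male_biased_trap = "male_biased_trap",
  female_biased_trap = "female_biased_trap"
)

#' Gene and exon counts per category
#'
#' Summarises a gene call table into the familiar two-column layout: the
#' number of genes in each category and, for the categories defined
#' directly by an exon call, the number of distinct exonic regions
#' carrying that call. Derived categories (both / unique / exon-usage /
#' core) have no exon-level counterpart and report `NA` exons.
#'
#' @param gene_calls Tibble from [rollup_genes()].
#' @param exon_calls Optional tibble from [classify_exons()] for the exon
#'   counts.
#' @return A tibble with columns `category`, `genes`, `exons`.
#' @export
category_summary <- function(gene_calls, exon_calls = NULL) {
  cats <- intersect(gene_category_names, names(gene_calls))
  tibble::tibble(
    category = cats,
    genes = vapply(cats, function(cc) sum(gene_calls[[cc]]), integer(1L),
                   USE.NAMES = FALSE),
    exons = vapply(cats, function(cc) {
      flag <- category_exon_flag[cc]
      if (is.null(exon_calls) || is.na(flag)) return(NA_integer_)
      sum(exon_calls[[flag]])
    }, integer(1L), USE.NAMES = FALSE)
  )
}
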