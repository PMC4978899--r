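#' Run the full exon-level differential-translatome pipeline
#'
#' Orchestrates the stages end to end: library sizes, replicate-based
#' region filtering, RPKM and ln-RPKM normalisation, per-exon
#' heteroscedastic contrasts with a pooled Benjamini-Hochberg correction,
#' directional exon calls, gene-level category rollup (including core
#' genes, detected in the TRAP fraction of both sexes), and — when
#' annotation inputs are supplied — chromosome, list-overlap and motif
#' enrichment of the sex-biased TRAP gene lists against the TRAP-detected
#' universe. The run is deterministic given its inputs; when `out_dir`
#' is set, the result tables are written as TSV with a config-hash
#' comment header plus a JSON metadata file.
#'
#' @param counts Count tibble (`region_id` + sample columns).
#' @param regions Region catalog ([build_exonic_regions()] or the
#'   simulator's).
#' @param design Sample design tibble.
#' @param offset Log offset for [ln_transform()].
#' @param lib_sizes Optional external library sizes ([library_sizes()]).
#' @param contrasts Contrast tibble (default [default_contrasts()]).
#' @param fdr_primary,fdr_strict,fdr_pool,variance_floor,df_method Passed
#'   to [run_exon_de()].
#' @param chrom_map Optional `gene_id`/`chromosome` tibble; triggers
#'   chromosome enrichment of the male- and female-biased TRAP gene
#'   lists.
#' @param gene_lists Optional named list of character vectors (external
#'   gene lists); each is tested for overlap with the male-biased TRAP
#'   genes.
#' @param motif_flags Optional long `gene_id`/`motif`/`present` tibble;
#'   triggers motif enrichment of the male-biased TRAP genes.
#' @param universe Optional background gene set for the enrichment
#'   stages; defaults to the TRAP-detected genes.
#' @param out_dir Optional output directory.
#' @param quiet Suppress per-stage log lines (default `FALSE`).
#' @return A list of class `trap_pipeline`: `detection`, `detected`
#'   (per-class gene sets), `de` (the `exon_de` fit), `exon_calls`,
#'   `gene_calls`, `summary`, `enrichment` (list or `NULL`), `meta`.
#' @export
run_trap_pipeline <- function(counts, regions, design,
                              offset = 0.001, lib_sizes = NULL,
                              contrasts = default_contrasts(),
                              fdr_primary = 0.2, fdr_strict = 0.05,
                              fdr_pool = c("pooled", "per_contrast"),
                              variance_floor = 1e-8,
                              df_method = c("satterthwaite", "residual"),
                              chrom_map = NULL, gene_lists = NULL,
                              motif_flags = NULL, universe = NULL,
                              out_dir = NULL, quiet = FALSE) {
  fdr_pool <- match.arg(fdr_pool)
  df_method <- match.arg(df_method)
  validate_design(design)
  validate_counts(counts)
  say <- function(...) if (!quiet) message("[trapdiff] ", ...)

  libs <- library_sizes(counts, lib_sizes)
  detection <- filter_regions(counts, design)
  say("filter: ", length(detection$analyzable_regions), "/", nrow(counts),
      " regions analyzable")

  detected <- list(
    MI = detect_genes(counts, regions, design, "MI"),
    FI = detect_genes(counts, regions, design, "FI"),
    MT = detect_genes(counts, regions, design, "MT"),
    FT = detect_genes(counts, regions, design, "FT"),
    input = detect_genes(counts, regions, design, "input"),
    TRAP = detect_genes(counts, regions, design, "TRAP"),
    core = detect_genes(counts, regions, design, "core")
  )
  say("detect: ", length(detected$core), " core genes (",
      length(detected$TRAP), " TRAP-detected)")

  rpkm <- compute_rpkm(counts, regions, libs)
  expr <- ln_transform(
    dplyr::filter(rpkm, .data$region_id %in% detection$analyzable_regions),
    offset
  )
  de <- run_exon_de(expr, design, contrasts, fdr_pool,
                    fdr_primary, fdr_strict, variance_floor, df_method)
  say("test: ", nrow(de$results), " tests, ",
      sum(de$results$significant), " significant at FDR <= ", fdr_primary)

  exon_calls <- classify_exons(de)
  gene_calls <- rollup_genes(exon_calls, regions,
                             core_genes = detected$core)
  summary_tbl <- category_summary(gene_calls, exon_calls)
  say("classify: ", sum(gene_calls$male_biased_trap), " male-biased / ",
      sum(gene_calls$female_biased_trap), " female-biased TRAP genes")

  enrichment <- NULL
  if (!is.null(chrom_map) || !is.null(gene_lists) || !is.null(motif_flags)) {
    if (is.null(universe)) universe <- detected$TRAP
    male_list <- intersect(
      gene_calls$gene_id[gene_calls$male_biased_trap], universe)
    female_list <- intersect(
      gene_calls$gene_id[gene_calls$female_biased_trap], universe)
    enrichment <- list()
    if (!is.null(chrom_map)) {
      enrichment$chromosome <- dplyr::bind_rows(
        male_biased_trap =
          chromosome_enrichment(male_list, chrom_map, universe),
        female_biased_trap =
          chromosome_enrichment(female_list, chrom_map, universe),
        .id = "gene_list"
      )
    }
    if (!is.null(gene_lists)) {
      enrichment$overlap <- purrr::map_dfr(gene_lists, function(gl) {
        overlap_enrichment(intersect(gl, universe), male_list, universe)
      }, .id = "gene_list")
    }
    if (!is.null(motif_flags)) {
      enrichment$motif <- motif_enrichment(male_list, motif_flags, universe)
    }
    say("enrich: ", length(enrichment), " enrichment table(s)")
  }

  meta <- list(
    config = list(
      offset = offset, fdr_primary = fdr_primary, fdr_strict = fdr_strict,
      fdr_pool = fdr_pool, variance_floor = variance_floor,
      df_method = df_method, contrasts = contrasts$contrast
    ),
    n_regions_in = nrow(counts),
    n_regions_analyzable = length(detection$analyzable_regions),
    n_tests = nrow(de$results),
    n_core_genes = length(detected$core)
  )
  meta$config_hash <- rlang::hash(meta$config)

  result <- structure(
    list(detection = detection, detected = detected, de = de,
         exon_calls = exon_calls, gene_calls = gene_calls,
         summary = summary_tbl, enrichment = enrichment, meta = meta),
    class = "trap_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf(
    "# trapdiff config_hash=%s offset=%g fdr_primary=%g fdr_strict=%g",
    result$meta$config_hash, result$meta$config$offset,
    result$meta$config$fdr_primary, result$meta$config$fdr_strict
  )
  write_with_header <- function(tbl, file) {
    path <- file.path(out_dir, file)
    writeLines(hdr, path)
    readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  }
  write_with_header(result$de$results, "exon_tests.tsv")
  write_with_header(result$gene_calls, "gene_calls.tsv")
  detection_tbl <- dplyr::bind_rows(
    tibble::tibble(region_id = result$detection$analyzable_regions,
                   status = "analyzable", reason = NA_character_),
    dplyr::mutate(result$detection$removed_regions, status = "removed") |>
      dplyr::select("region_id", "status", "reason")
  )
  write_with_header(detection_tbl, "detection.tsv")
  write_with_header(result$summary, "category_summary.tsv")
  if (!is.null(result$enrichment)) {
    for (nm in names(result$enrichment)) {
      write_with_header(result$enrichment[[nm]],
                        paste0("enrichment_", nm, ".tsv"))
    }
  }
  jsonlite::write_json(result$meta, file.path(out_dir, "run_meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.trap_pipeline <- function(x, ...) {
  cat("trapdiff pipeline run\n")
  cat("  regions:", x$meta$n_regions_analyzable, "analyzable of",
      x$meta$n_regions_in, "\n")
  cat("  core genes:", x$meta$n_core_genes, "\n")
  print(x$summary, n = Inf)
  invisible(x)
}

#' @rdname run_trap_pipeline
#' @param x A `trap_pipeline` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.trap_pipeline <- function(x, ...) {
  x$de$results
}

#' @rdname run_trap_pipeline
#' @exportS3Method generics::glance
glance.trap_pipeline <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      n_regions_in = x$meta$n_regions_in,
      n_regions_analyzable = x$meta$n_regions_analyzable,
      n_core_genes = x$meta$n_core_genes,
      n_male_biased_trap = sum(x$gene_calls$male_biased_trap),
      n_female_biased_trap = sum(x$gene_calls$female_biased_trap)
    ),
    glance(x$de)[c("n_tests", "n_significant", "n_significant_strict")]
  )
}
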