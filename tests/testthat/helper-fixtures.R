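# Hand-built fixtures shared between the classification unit tests and the
# rule-fixture acceptance checks.

# Region catalog for ten genes with two exonic regions each.
fixture_regions <- function() {
  tibble::tibble(
    region_id = paste0(rep(paste0("g", 1:10), each = 2), "_e", 1:2),
    chromosome = "chrX",
    start = seq(0L, by = 1000L, length.out = 20L),
    end = seq(500L, by = 1000L, length.out = 20L),
    length_bp = 500L,
    gene_ids = as.list(rep(paste0("g", 1:10), each = 2))
  )
}

# Contrast-result table covering all default contrasts for every region,
# null (estimate 0, p_fdr 1) except for the listed overrides.
fixture_results <- function(overrides) {
  regions <- fixture_regions()$region_id
  base <- tidyr::expand_grid(
    region_id = regions,
    contrast = default_contrasts()$contrast
  ) |>
    dplyr::mutate(estimate = 0, p_fdr = 1)
  for (ov in overrides) {
    hit <- base$region_id == ov$region_id & base$contrast == ov$contrast
    stopifnot(sum(hit) == 1L)
    base$estimate[hit] <- ov$estimate
    base$p_fdr[hit] <- ov$p_fdr
  }
  base
}

# The ten-gene classification fixture:
#   g1-g3 male-biased TRAP (one exon up in MT vs FT)
#   g4    female-biased TRAP
#   g5    one exon male-biased and one female-biased (sex-biased exon)
#   g6-g7 TRAP-enriched in males only
#   g8    TRAP-enriched in both sexes (same exon)
#   g9    significant MT-MI but LOWER in TRAP: must never count as enriched
#   g10   all null
fixture_classification <- function() {
  ov <- list(
    list(region_id = "g1_e1", contrast = "MT-FT", estimate = 2, p_fdr = 0.01),
    list(region_id = "g2_e1", contrast = "MT-FT", estimate = 1.5, p_fdr = 0.05),
    list(region_id = "g3_e2", contrast = "MT-FT", estimate = 0.8, p_fdr = 0.2),
    list(region_id = "g4_e1", contrast = "MT-FT", estimate = -2, p_fdr = 0.01),
    list(region_id = "g5_e1", contrast = "MT-FT", estimate = 1, p_fdr = 0.05),
    list(region_id = "g5_e2", contrast = "MT-FT", estimate = -1, p_fdr = 0.05),
    list(region_id = "g6_e1", contrast = "MT-MI", estimate = 1.5, p_fdr = 0.01),
    list(region_id = "g7_e1", contrast = "MT-MI", estimate = 1.2, p_fdr = 0.1),
    list(region_id = "g8_e1", contrast = "MT-MI", estimate = 1.5, p_fdr = 0.01),
    list(region_id = "g8_e1", contrast = "FT-FI", estimate = 1.2, p_fdr = 0.02),
    list(region_id = "g9_e1", contrast = "MT-MI", estimate = -1.5, p_fdr = 0.01)
  )
  fixture_results(ov)
}

# Hand-enumerated gene counts for the fixture above.
fixture_expected_gene_counts <- c(
  male_biased_trap = 4L,      # g1, g2, g3, g5
  female_biased_trap = 2L,    # g4, g5
  sex_biased_exon_trap = 1L,  # g5
  trap_enriched_male = 3L,    # g6, g7, g8
  trap_enriched_female = 1L,  # g8
  trap_enriched_both = 1L,    # g8
  trap_enriched_male_only = 2L,   # g6, g7
  trap_enriched_female_only = 0L,
  sex_specific_exon_enrichment = 0L,
  male_biased_input = 0L,
  female_biased_input = 0L,
  sex_specific_exon_usage_input = 0L
)

# Detection/filter fixture: 5 replicates per condition; four regions with
# hand-worked filter outcomes.
fixture_detection <- function() {
  design <- make_sample_design(5L)
  zero <- rep(0L, 20L)
  reads_in <- function(cond_reps) {
    # cond_reps: named list condition -> replicate indices with one read
    x <- zero
    for (cc in names(cond_reps)) {
      idx <- design$condition == cc & design$replicate %in% cond_reps[[cc]]
      x[idx] <- 1L
    }
    x
  }
  rows <- list(
    all_zero = zero,
    # >= 1 read in exactly 3/5 replicates of every condition: analyzable
    three_of_five = reads_in(list(MI = 1:3, FI = 1:3, MT = 1:3, FT = 1:3)),
    # full coverage except 2/5 in FT: removed (3 zeros >= half of 5)
    ft_short = reads_in(list(MI = 1:5, FI = 1:5, MT = 1:5, FT = 1:2)),
    all_present = reads_in(list(MI = 1:5, FI = 1:5, MT = 1:5, FT = 1:5))
  )
  counts <- dplyr::bind_cols(
    tibble::tibble(region_id = names(rows)),
    tibble::as_tibble(do.call(rbind, rows), .name_repair = ~design$sample_id)
  )
  list(design = design, counts = counts)
}
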