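#' Reads per kilobase per million (RPKM)
#'
#' Normalises raw region counts for sequencing depth and region length:
#' `RPKM = count * 1e9 / (library_size * length_bp)`. A zero count gives
#' RPKM 0 regardless of library size.
#'
#' @param counts Count tibble (`region_id` + sample columns).
#' @param regions Region catalog from [build_exonic_regions()]; supplies
#'   `length_bp` for every region in `counts`.
#' @param lib_sizes Optional library-size tibble from [library_sizes()];
#'   defaults to the column sums of `counts`.
#' @return A tibble of the same shape as `counts` holding RPKM values.
#' @export
compute_rpkm <- function(counts, regions, lib_sizes = NULL) {
  if (is.null(lib_sizes)) lib_sizes <- library_sizes(counts)
  lengths <- regions$length_bp[match(counts$region_id, regions$region_id)]
  if (anyNA(lengths)) {
    stop("region(s) missing from the catalog: ",
         paste(head(counts$region_id[is.na(lengths)], 5L), collapse = ", "),
         call. = FALSE)
  }
  samples <- setdiff(names(counts), "region_id")
  libs <- lib_sizes$library_size[match(samples, lib_sizes$sample_id)]
  mat <- as.matrix(counts[samples])
  zero_lib <- libs == 0
  if (any(zero_lib & colSums(mat) > 0)) {
    stop("library size 0 for a sample with nonzero counts", call. = FALSE)
  }
  libs[zero_lib] <- 1 # all-zero column stays all-zero
  rpkm <- mat * 1e9 / outer(lengths, libs)
  dplyr::bind_cols(counts["region_id"], tibble::as_tibble(rpkm))
}

#' Natural-log transform of RPKM
#'
#' Computes `ln(RPKM + offset)` elementwise. The small positive offset
#' keeps regions with zero-count replicates finite; it is recorded as the
#' `"offset"` attribute of the result and propagated into run metadata.
#'
#' @param rpkm RPKM tibble from [compute_rpkm()].
#' @param offset Positive pseudo-RPKM added before the log (default 0.001).
#' @return A tibble of ln-RPKM values with attribute `offset`.
#' @export
ln_transform <- function(rpkm, offset = 0.001) {
  if (!is.numeric(offset) || length(offset) != 1L || offset <= 0) {
    stop("offset must be a single positive number", call. = FALSE)
  }
  samples <- setdiff(names(rpkm), "region_id")
  out <- dplyr::bind_cols(
    rpkm["region_id"],
    tibble::as_tibble(log(as.matrix(rpkm[samples]) + offset))
  )
  attr(out, "offset") <- offset
  out
}

#' Replicate-based detection filter for exonic regions
#'
#' A region is kept for testing only if, in every one of the four
#' conditions, at least half of the replicates have at least one read
#' (threshold `ceiling(n_reps / 2)`; 3 of 5 at the default design).
#' Equivalently, regions with no coverage in all replicates, or with no
#' coverage in half or more of the replicates of any one condition, are
#' removed.
#'
#' @param counts Count tibble.
#' @param design Sample design tibble.
#' @return A list of class `detection_report` with elements
#'   `analyzable_regions` (character vector) and `removed_regions`
#'   (tibble `region_id`, `reason` in `all_zero` /
#'   `half_or_more_zero_in_a_condition`).
#' @export
filter_regions <- function(counts, design) {
  validate_design(design)
  detected <- detection_by_condition(counts, design)
  n_reps <- table(design$condition)
  if (length(setdiff(CONDITIONS, names(n_reps))) > 0L) {
    stop("design must cover all four conditions (MI, FI, MT, FT)",
         call. = FALSE)
  }
  thresh <- ceiling(as.numeric(n_reps[CONDITIONS]) / 2)
  ok <- sweep(detected[, CONDITIONS, drop = FALSE], 2L, thresh, `>=`)
  analyzable <- counts$region_id[rowSums(ok) == length(CONDITIONS)]
  removed_idx <- which(rowSums(ok) < length(CONDITIONS))
  all_zero <- rowSums(detected) == 0
  removed <- tibble::tibble(
    region_id = counts$region_id[removed_idx],
    reason = as.character(ifelse(unname(all_zero)[removed_idx], "all_zero",
                                 "half_or_more_zero_in_a_condition"))
  )
  structure(
    list(analyzable_regions = analyzable, removed_regions = removed),
    class = "detection_report"
  )
}

# regions x conditions matrix of replicate counts with >= 1 read
detection_by_condition <- function(counts, design) {
  samples <- design$sample_id
  present <- as.matrix(counts[samples]) >= 1
  conds <- sort(unique(design$condition))
  out <- vapply(conds, function(cc) {
    rowSums(present[, samples[design$condition == cc], drop = FALSE])
  }, numeric(nrow(counts)))
  out <- matrix(out, nrow = nrow(counts),
                dimnames = list(counts$region_id, conds))
  out
}

#' @export
print.detection_report <- function(x, ...) {
  cat("Detection report:", length(x$analyzable_regions),
      "analyzable region(s),", nrow(x$removed_regions), "removed\n")
  if (nrow(x$removed_regions) > 0L) {
    print(dplyr::count(x$removed_regions, .data$reason))
  }
  invisible(x)
}

#' Detected genes per condition class
#'
#' A gene is detected in a condition when strictly more than 50% of that
#' condition's replicates have at least one read in at least one exonic
#' region of the gene (3 or more of 5 replicates at the default design).
#' Union classes combine per-condition detection: `input` = MI or FI,
#' `TRAP` = MT or FT, and `core` = MT and FT (genes translated in the
#' target neurons of both sexes).
#'
#' @param counts Count tibble.
#' @param regions Region catalog.
#' @param design Sample design tibble.
#' @param class One of `"MI"`, `"FI"`, `"MT"`, `"FT"`, `"input"`,
#'   `"TRAP"`, `"male_TRAP"`, `"female_TRAP"`, `"core"`.
#' @return Character vector of detected gene ids.
#' @export
detect_genes <- function(counts, regions, design,
                         class = c("core", "MI", "FI", "MT", "FT",
                                   "input", "TRAP", "male_TRAP",
                                   "female_TRAP")) {
  class <- match.arg(class)
  per_cond <- gene_detection_by_condition(counts, regions, design)
  sets <- per_cond$sets
  switch(class,
    MI = sets$MI, FI = sets$FI, MT = sets$MT, FT = sets$FT,
    male_TRAP = sets$MT, female_TRAP = sets$FT,
    input = sort(union(sets$MI, sets$FI)),
    TRAP = sort(union(sets$MT, sets$FT)),
    core = sort(intersect(sets$MT, sets$FT))
  )
}

gene_detection_by_condition <- function(counts, regions, design) {
  map <- region_gene_map(regions)
  samples <- design$sample_id
  present <- as.matrix(counts[samples]) >= 1
  rownames(present) <- counts$region_id
  idx <- match(map$region_id, counts$region_id)
  keep <- !is.na(idx)
  map <- map[keep, ]
  # per gene x sample: any region with a read
  gene_present <- rowsum(present[idx[keep], , drop = FALSE] + 0,
                         group = map$gene_id) > 0
  sets <- lapply(CONDITIONS, function(cc) {
    cols <- samples[design$condition == cc]
    n <- length(cols)
    hits <- rowSums(gene_present[, cols, drop = FALSE])
    sort(rownames(gene_present)[hits > n / 2])
  })
  names(sets) <- CONDITIONS
  list(sets = sets)
}
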