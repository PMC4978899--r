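#' Read exon records from a gene-model file
#'
#' Reads exon features from a GTF/GFF-dialect gene-model file, or from a
#' minimal 6-column BED-like TSV (`chrom`, `start`, `end`, `gene_id`,
#' `exon_id`, `strand`). Coordinates are converted at this boundary to the
#' package-internal convention: 0-based, half-open, so that
#' `length = end - start`. GTF/GFF input is 1-based inclusive and has its
#' `start` decremented by one; BED-like input is taken to already be 0-based
#' half-open.
#'
#' @param path Path to the gene-model file.
#' @param format `"auto"` (default, decided from the file extension),
#'   `"gtf"`, or `"bed"`.
#' @return A tibble with one row per exon and columns `gene_id`, `exon_id`,
#'   `chromosome`, `start`, `end`, `strand`.
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste("chr2L", "src", "exon", "100", "200", ".", "+", ".",
#'                  'gene_id "g1";', sep = "\t"), gtf)
#' read_gene_models(gtf)
#' @export
read_gene_models <- function(path, format = c("auto", "gtf", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff|gff3)(\\.gz)?$", path, ignore.case = TRUE)) {
      "gtf"
    } else {
      "bed"
    }
  }
  exons <- if (format == "gtf") read_exons_gtf(path) else read_exons_bed(path)
  validate_exons(exons)
  exons
}

read_exons_gtf <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff"),
    error = function(e) {
      stop("failed to parse gene-model file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  if ("type" %in% names(S4Vectors::mcols(gr))) {
    gr <- gr[tolower(as.character(gr$type)) == "exon"]
  }
  if (length(gr) == 0L) {
    stop("no exon features found in '", path, "'", call. = FALSE)
  }
  gene_id <- S4Vectors::mcols(gr)$gene_id
  if (is.null(gene_id) || anyNA(gene_id)) {
    bad <- if (is.null(gene_id)) seq_along(gr) else which(is.na(gene_id))
    stop("exon feature(s) without a gene_id attribute (feature ",
         paste(head(bad, 5L), collapse = ", "), ")", call. = FALSE)
  }
  exon_id <- S4Vectors::mcols(gr)$exon_id
  if (is.null(exon_id)) {
    exon_id <- paste0(gene_id, ":e", stats::ave(seq_along(gr), gene_id,
                                                FUN = seq_along))
  }
  tibble::tibble(
    gene_id = as.character(gene_id),
    exon_id = as.character(exon_id),
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    # GTF is 1-based inclusive; internal is 0-based half-open.
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

read_exons_bed <- function(path) {
  cols <- c("chromosome", "start", "end", "gene_id", "exon_id", "strand")
  tab <- suppressWarnings( # parse issues are re-raised as errors below
    readr::read_tsv(path, col_names = cols, col_types = "ciiccc",
                    comment = "#", progress = FALSE)
  )
  probs <- readr::problems(tab)
  if (nrow(probs) > 0L) {
    stop("malformed line ", probs$row[1L], " in '", path, "': ",
         probs$expected[1L], " expected", call. = FALSE)
  }
  dplyr::select(tab, "gene_id", "exon_id", "chromosome", "start", "end",
                "strand")
}

validate_exons <- function(exons) {
  stopifnot(all(c("gene_id", "exon_id", "chromosome", "start", "end",
                  "strand") %in% names(exons)))
  if (any(!nzchar(exons$chromosome)) || anyNA(exons$chromosome)) {
    stop("exon with empty chromosome name", call. = FALSE)
  }
  if (any(exons$start >= exons$end)) {
    bad <- which(exons$start >= exons$end)[1L]
    stop("exon '", exons$exon_id[bad], "' has start >= end after ",
         "coordinate conversion", call. = FALSE)
  }
  if (anyDuplicated(exons[c("gene_id", "exon_id")])) {
    stop("duplicate (gene_id, exon_id) pair", call. = FALSE)
  }
  invisible(exons)
}

#' Build disjoint exonic regions from exon records
#'
#' Collapses the exons of each gene into maximal disjoint intervals
#' ("exonic regions"), the unit at which coverage is quantified and tested.
#' Overlapping or abutting exons of one gene are merged. A region that
#' overlaps exons of more than one gene is listed under every overlapping
#' gene unless `multi_gene = FALSE`, in which case it is assigned only to
#' the gene whose exons produced it.
#'
#' @param exons A tibble of exon records as returned by
#'   [read_gene_models()] (0-based half-open coordinates).
#' @param multi_gene Assign regions overlapping several genes to all of
#'   them (default `TRUE`).
#' @return A tibble with columns `region_id`, `chromosome`, `start`, `end`,
#'   `length_bp` and the list-column `gene_ids`. Use [region_gene_map()]
#'   for a long region-to-gene table.
#' @export
build_exonic_regions <- function(exons, multi_gene = TRUE) {
  validate_exons(exons)
  exon_gr <- GenomicRanges::GRanges(
    exons$chromosome,
    IRanges::IRanges(exons$start + 1L, exons$end),
    gene_id = exons$gene_id
  )
  by_gene <- GenomicRanges::split(exon_gr, exon_gr$gene_id)
  reduced <- GenomicRanges::reduce(by_gene) # merges overlapping + adjacent
  flat <- unlist(reduced, use.names = TRUE)
  owner <- names(flat)
  names(flat) <- NULL

  if (multi_gene) {
    hits <- GenomicRanges::findOverlaps(flat, exon_gr)
    genes <- tapply(
      exon_gr$gene_id[S4Vectors::subjectHits(hits)],
      factor(S4Vectors::queryHits(hits), levels = seq_along(flat)),
      function(g) sort(unique(g)), simplify = FALSE
    )
    gene_ids <- unname(genes)
  } else {
    gene_ids <- as.list(owner)
  }

  regions <- tibble::tibble(
    chromosome = as.character(GenomicRanges::seqnames(flat)),
    start = GenomicRanges::start(flat) - 1L,
    end = GenomicRanges::end(flat),
    gene_ids = gene_ids
  )
  # Identical intervals arising from different genes collapse to one region.
  regions <- regions |>
    dplyr::group_by(.data$chromosome, .data$start, .data$end) |>
    dplyr::summarise(
      gene_ids = list(sort(unique(unlist(.data$gene_ids)))),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chromosome, .data$start, .data$end) |>
    dplyr::mutate(
      region_id = paste0(.data$chromosome, ":", .data$start, "-", .data$end),
      length_bp = .data$end - .data$start
    ) |>
    dplyr::select("region_id", "chromosome", "start", "end", "length_bp",
                  "gene_ids")
  regions
}

#' Long region-to-gene membership table
#'
#' @param regions A region catalog from [build_exonic_regions()].
#' @return A tibble with columns `region_id`, `gene_id`, one row per
#'   membership.
#' @export
region_gene_map <- function(regions) {
  regions |>
    dplyr::select("region_id", "gene_ids") |>
    tidyr::unnest_longer("gene_ids", values_to = "gene_id")
}
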