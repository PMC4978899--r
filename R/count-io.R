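#' Construct the four-condition sample design
#'
#' Builds the sample sheet for the 2-sex x 2-fraction design: male input
#' (MI), female input (FI), male TRAP (MT) and female TRAP (FT), each with
#' `n_reps` replicates.
#'
#' @param n_reps Replicates per condition (default 5).
#' @return A tibble with columns `sample_id`, `sex`, `fraction`,
#'   `replicate` and the derived `condition` code.
#' @examples
#' make_sample_design(2)
#' @export
make_sample_design <- function(n_reps = 5L) {
  stopifnot(n_reps >= 1L)
  design <- tidyr::expand_grid(
    fraction = c("input", "TRAP"),
    sex = c("male", "female"),
    replicate = seq_len(n_reps)
  ) |>
    dplyr::mutate(
      condition = condition_code(.data$sex, .data$fraction),
      sample_id = paste0(.data$condition, "_", .data$replicate)
    ) |>
    dplyr::select("sample_id", "sex", "fraction", "replicate", "condition")
  validate_design(design)
}

#' Read a sample sheet
#'
#' Reads a TSV with columns `sample_id`, `sex` (`male`/`female`),
#' `fraction` (`input`/`TRAP`) and `replicate`, and derives the condition
#' code (MI, FI, MT, FT).
#'
#' @param path Path to the sample-sheet TSV.
#' @return A validated design tibble (see [make_sample_design()]).
#' @export
read_sample_design <- function(path) {
  design <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("sample_id", "sex", "fraction", "replicate")
  if (!all(need %in% names(design))) {
    stop("sample sheet must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  design |>
    dplyr::mutate(condition = condition_code(.data$sex, .data$fraction)) |>
    validate_design()
}

validate_design <- function(design) {
  if (!all(design$sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  if (!all(design$fraction %in% c("input", "TRAP"))) {
    stop("fraction must be 'input' or 'TRAP'", call. = FALSE)
  }
  if (anyDuplicated(design$sample_id)) {
    stop("duplicate sample_id in design", call. = FALSE)
  }
  if (anyDuplicated(design[c("condition", "replicate")])) {
    stop("duplicate replicate index within a condition", call. = FALSE)
  }
  design
}

#' Read an exon-region count matrix
#'
#' Reads a TSV whose first column is `region_id` and whose remaining
#' columns are per-sample non-negative integer read counts. The columns
#' must match the sample ids of `design` exactly (order is harmonised to
#' the design).
#'
#' @param path Path to the counts TSV.
#' @param design Sample design tibble ([make_sample_design()],
#'   [read_sample_design()]).
#' @return A tibble: `region_id` followed by one integer column per sample.
#' @export
read_count_matrix <- function(path, design) {
  counts <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (names(counts)[1L] != "region_id") {
    stop("first column of the count matrix must be 'region_id'",
         call. = FALSE)
  }
  samples <- setdiff(names(counts), "region_id")
  unknown <- setdiff(samples, design$sample_id)
  if (length(unknown) > 0L) {
    stop("unknown sample id(s) in count matrix: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(design$sample_id, samples)
  if (length(missing) > 0L) {
    stop("design sample(s) absent from count matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(counts$region_id)) {
    stop("duplicate region id in count matrix", call. = FALSE)
  }
  counts <- counts[c("region_id", design$sample_id)]
  validate_counts(counts)
  counts
}

validate_counts <- function(counts) {
  vals <- as.matrix(counts[-1L])
  if (!is.numeric(vals) || anyNA(vals)) {
    stop("count matrix cells must be numeric and non-missing", call. = FALSE)
  }
  if (any(vals < 0)) stop("negative count", call. = FALSE)
  if (any(vals != floor(vals))) stop("non-integer count", call. = FALSE)
  invisible(counts)
}

#' Write a count matrix as TSV
#'
#' Inverse of [read_count_matrix()]; for canonical integer TSV input the
#' read/write round trip is byte-identical.
#'
#' @param counts Count tibble (`region_id` + sample columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Per-sample library sizes
#'
#' Returns the total mapped reads per sample used as the RPKM denominator.
#' By default this is the column sum of the analysed count matrix; an
#' external table of total mapped reads (columns `sample_id`,
#' `library_size`) overrides it, and must then be at least the column sums.
#'
#' @param counts Count tibble.
#' @param external Optional tibble with columns `sample_id`,
#'   `library_size`.
#' @return A tibble with columns `sample_id`, `library_size`.
#' @export
library_sizes <- function(counts, external = NULL) {
  sums <- tibble::tibble(
    sample_id = setdiff(names(counts), "region_id"),
    library_size = unname(colSums(counts[setdiff(names(counts), "region_id")]))
  )
  if (is.null(external)) {
    return(sums)
  }
  stopifnot(all(c("sample_id", "library_size") %in% names(external)))
  merged <- dplyr::left_join(sums, external, by = "sample_id",
                             suffix = c(".sum", ""))
  if (anyNA(merged$library_size)) {
    stop("external library sizes missing for sample(s): ",
         paste(merged$sample_id[is.na(merged$library_size)], collapse = ", "),
         call. = FALSE)
  }
  if (any(merged$library_size < merged$library_size.sum)) {
    stop("external library size smaller than the column sum", call. = FALSE)
  }
  dplyr::select(merged, "sample_id", "library_size")
}
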