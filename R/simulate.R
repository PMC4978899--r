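#' Simulate an exon-level TRAP-seq dataset with planted truth
#'
#' Generates a 4-condition (MI, FI, MT, FT) by `n_reps`-replicate
#' exon-region count dataset with the effect structure the pipeline is
#' built to detect, plus the ground-truth labels needed to score
#' recovery. Each gene carries two independent planted labels: a TRAP
#' axis (`none`, `male`, `female`, `both`: `trap_enrichment_lfc` added to
#' the TRAP condition ln-mean of the stated sex or sexes) and a sex-bias
#' axis (`null`, `male_biased`, `female_biased`, `isoform_switch`:
#' `bias_lfc` added to the MT ln-mean, the FT ln-mean, or — for
#' isoform-switch genes — the MT mean of one exon and the FT mean of
#' another, emulating sex-specific transcript isoforms).
#'
#' Replicate ln-means are drawn with a distinct standard deviation per
#' condition (`group_sd`), making the residual variance heteroscedastic
#' as the analysis model assumes, and counts are drawn negative-binomial
#' with mean `exp(ln_mean) * length_bp * library_size / 1e9` (the RPKM
#' relation inverted) and size `dispersion`. A single master seed streams
#' per-gene substreams, so the first `k` genes of a larger simulation are
#' identical to a smaller one.
#'
#' @param n_genes Number of genes.
#' @param exons_per_gene Integer range (length 2) of exon-region counts
#'   per gene.
#' @param n_reps Replicates per condition (default 5).
#' @param baseline_mean,baseline_sd Per-exon baseline ln-RPKM
#'   distribution.
#' @param trap_enrichment_lfc Natural-log fold change of TRAP enrichment.
#' @param frac_trap_enriched_male,frac_trap_enriched_female,frac_trap_enriched_both
#'   Proportions of genes on the TRAP axis (must sum to at most 1).
#' @param frac_male_biased,frac_female_biased Proportions of sex-biased
#'   genes (default 0.08 and 0.02, a 4:1 male:female ratio).
#' @param bias_lfc Natural-log fold change of the sex bias.
#' @param frac_isoform_switch Proportion of genes with one exon biased
#'   toward each sex (forced to have at least 2 exons).
#' @param group_sd Named per-condition SD of replicate ln-means
#'   (heteroscedastic; defaults 0.2, 0.25, 0.3, 0.35 for MI, FI, MT, FT).
#' @param dispersion Negative-binomial size parameter.
#' @param library_size_mean Nominal total mapped reads per sample.
#' @param region_length_range Integer range of region lengths (bp).
#' @param seed Master seed; the output is fully reproducible from it.
#' @return A list of class `trap_sim` with tibbles `regions` (a region
#'   catalog), `counts`, `design`, `lib_sizes`, `truth_genes` (gene
#'   labels and planted effect sizes) and `truth_exons` (realised
#'   per-condition ln-means per region). `lib_sizes` holds the nominal
#'   sequencing depth the counts were generated at, playing the role of
#'   the external total-mapped-reads table: the simulated regions stand
#'   for a subset of the transcriptome, so column sums of `counts`
#'   understate the depth and inherit the planted effect asymmetry.
#' @export
simulate_trap_dataset <- function(n_genes = 200L,
                                  exons_per_gene = c(1L, 4L),
                                  n_reps = 5L,
                                  baseline_mean = 1.5, baseline_sd = 1,
                                  trap_enrichment_lfc = 1.5,
                                  frac_trap_enriched_male = 0.05,
                                  frac_trap_enriched_female = 0.05,
                                  frac_trap_enriched_both = 0.3,
                                  frac_male_biased = 0.08,
                                  frac_female_biased = 0.02,
                                  bias_lfc = 1.5,
                                  frac_isoform_switch = 0.02,
                                  group_sd = c(MI = 0.2, FI = 0.25,
                                               MT = 0.3, FT = 0.35),
                                  dispersion = 50,
                                  library_size_mean = 5e6,
                                  region_length_range = c(200L, 2000L),
                                  seed = 1L) {
  stopifnot(n_genes >= 1L, n_reps >= 2L, all(group_sd > 0),
            baseline_sd >= 0, dispersion > 0, library_size_mean > 0,
            length(exons_per_gene) == 2L,
            exons_per_gene[1L] >= 1L,
            exons_per_gene[1L] <= exons_per_gene[2L])
  trap_fracs <- c(male = frac_trap_enriched_male,
                  female = frac_trap_enriched_female,
                  both = frac_trap_enriched_both)
  bias_fracs <- c(male_biased = frac_male_biased,
                  female_biased = frac_female_biased,
                  isoform_switch = frac_isoform_switch)
  if (any(trap_fracs < 0) || sum(trap_fracs) > 1 ||
      any(bias_fracs < 0) || sum(bias_fracs) > 1) {
    stop("label proportions must be non-negative and sum to at most 1 ",
         "per axis", call. = FALSE)
  }
  group_sd <- group_sd[CONDITIONS]
  if (anyNA(group_sd)) {
    stop("group_sd must be named with MI, FI, MT, FT", call. = FALSE)
  }

  design <- make_sample_design(n_reps)
  cond_of_sample <- design$condition

  # Per-gene substreams derived once from the master seed: gene k's seed
  # does not depend on n_genes (sample.int consumes draws sequentially).
  set.seed(seed)
  gene_seeds <- sample.int(.Machine$integer.max - 1L, n_genes)

  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  regions_l <- vector("list", n_genes)
  counts_l <- vector("list", n_genes)
  truth_g <- vector("list", n_genes)
  truth_e <- vector("list", n_genes)

  for (g in seq_len(n_genes)) {
    set.seed(gene_seeds[g])
    trap_label <- draw_label(trap_fracs, none = "none")
    bias_label <- draw_label(bias_fracs, none = "null")
    n_exons <- sample(exons_per_gene[1L]:exons_per_gene[2L], 1L)
    if (bias_label == "isoform_switch") n_exons <- max(n_exons, 2L)
    lengths <- sample(region_length_range[1L]:region_length_range[2L],
                      n_exons, replace = TRUE)

    mu <- matrix(rnorm(n_exons, baseline_mean, baseline_sd),
                 nrow = n_exons, ncol = 4L,
                 dimnames = list(NULL, CONDITIONS))
    if (trap_label %in% c("male", "both")) {
      mu[, "MT"] <- mu[, "MT"] + trap_enrichment_lfc
    }
    if (trap_label %in% c("female", "both")) {
      mu[, "FT"] <- mu[, "FT"] + trap_enrichment_lfc
    }
    if (bias_label == "male_biased") {
      mu[, "MT"] <- mu[, "MT"] + bias_lfc
    } else if (bias_label == "female_biased") {
      mu[, "FT"] <- mu[, "FT"] + bias_lfc
    } else if (bias_label == "isoform_switch") {
      mu[1L, "MT"] <- mu[1L, "MT"] + bias_lfc
      mu[2L, "FT"] <- mu[2L, "FT"] + bias_lfc
    }

    # replicate ln-means with condition-specific (heteroscedastic) noise
    y <- mu[, cond_of_sample, drop = FALSE] +
      rnorm(n_exons * nrow(design), 0,
            rep(group_sd[cond_of_sample], each = n_exons))
    count_mu <- exp(y) * lengths * library_size_mean / 1e9
    cnt <- matrix(
      rnbinom(length(count_mu), mu = count_mu, size = dispersion),
      nrow = n_exons, dimnames = list(NULL, design$sample_id)
    )

    chrom <- paste0("chr", (g - 1L) %% 5L + 1L)
    starts <- cumsum(c((g - 1L) * 1e5L, lengths[-n_exons] + 100L))
    region_ids <- paste0(gene_ids[g], ":e", seq_len(n_exons))
    regions_l[[g]] <- tibble::tibble(
      region_id = region_ids, chromosome = chrom,
      start = starts, end = starts + lengths, length_bp = lengths,
      gene_ids = lapply(seq_len(n_exons), function(i) gene_ids[g])
    )
    counts_l[[g]] <- tibble::tibble(region_id = region_ids) |>
      dplyr::bind_cols(tibble::as_tibble(cnt))
    truth_g[[g]] <- tibble::tibble(
      gene_id = gene_ids[g], trap_label = trap_label,
      bias_label = bias_label,
      trap_lfc = ifelse(trap_label == "none", 0, trap_enrichment_lfc),
      bias_lfc = ifelse(bias_label == "null", 0, bias_lfc)
    )
    truth_e[[g]] <- tibble::tibble(
      region_id = region_ids, gene_id = gene_ids[g],
      mu_MI = mu[, "MI"], mu_FI = mu[, "FI"],
      mu_MT = mu[, "MT"], mu_FT = mu[, "FT"]
    )
  }

  structure(
    list(
      regions = dplyr::bind_rows(regions_l),
      counts = dplyr::bind_rows(counts_l),
      design = design,
      lib_sizes = tibble::tibble(sample_id = design$sample_id,
                                 library_size = library_size_mean),
      truth_genes = dplyr::bind_rows(truth_g),
      truth_exons = dplyr::bind_rows(truth_e)
    ),
    class = "trap_sim"
  )
}

draw_label <- function(fracs, none) {
  u <- stats::runif(1L)
  cum <- cumsum(fracs)
  hit <- which(u < cum)
  if (length(hit) == 0L) none else names(fracs)[hit[1L]]
}

#' @export
print.trap_sim <- function(x, ...) {
  cat("Simulated TRAP-seq dataset:", nrow(x$truth_genes), "genes,",
      nrow(x$counts), "exonic regions,", nrow(x$design), "samples\n")
  print(dplyr::count(x$truth_genes, .data$trap_label, .data$bias_label))
  invisible(x)
}

#' Write / read simulation ground truth
#'
#' One row per gene with planted labels and effect sizes; the TSV round
#' trip is lossless.
#'
#' @param truth Gene-truth tibble (`truth_genes` of
#'   [simulate_trap_dataset()]).
#' @param path Output path.
#' @return `path` invisibly for `write_truth()`; a tibble for
#'   `read_truth()`.
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(truth, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    trap_label = readr::col_character(),
    bias_label = readr::col_character(),
    trap_lfc = readr::col_double(),
    bias_lfc = readr::col_double()
  ), progress = FALSE)
}
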