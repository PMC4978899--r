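#' Two-tail Fisher exact test for 2x2 tables
#'
#' Exact two-tailed p-value under the hypergeometric null, by the
#' probability-mass rule: the sum of the probabilities of every table
#' with the same margins whose probability does not exceed that of the
#' observed table (a relative tolerance of `1e-7` guards floating-point
#' ties). A table with a zero row or column margin admits only one
#' configuration and returns p = 1. Vectorised over tables; tables
#' sharing margins share one probability-mass computation, so large
#' sweeps are cheap.
#'
#' @param a,b,c,d Non-negative integer cell counts; `a` is conventionally
#'   the in-list, with-property cell. Vectors are recycled to a common
#'   length.
#' @return Numeric vector of two-tailed p-values.
#' @examples
#' fisher_exact_two_tail(3, 1, 1, 3) # 34/70
#' @export
fisher_exact_two_tail <- function(a, b, c, d) {
  cells <- vctrs_recycle(a, b, c, d)
  a <- cells[[1L]]; b <- cells[[2L]]; c <- cells[[3L]]; d <- cells[[4L]]
  if (any(c(a, b, c, d) < 0)) stop("negative cell count", call. = FALSE)
  m <- a + b # row 1
  n <- c + d # row 2
  k <- a + c # column 1
  p <- rep(1, length(a))
  live <- which(m > 0 & n > 0 & k > 0 & (b + d) > 0)
  if (length(live) == 0L) return(p)
  key <- paste(m[live], n[live], k[live])
  for (grp in split(live, key)) {
    mm <- m[grp[1L]]; nn <- n[grp[1L]]; kk <- k[grp[1L]]
    support <- max(0L, kk - nn):min(kk, mm)
    pmf <- dhyper(support, mm, nn, kk)
    s <- sort(pmf)
    cs <- cumsum(s)
    obs <- dhyper(a[grp], mm, nn, kk)
    pos <- findInterval(obs * (1 + 1e-7), s)
    p[grp] <- pmin(cs[pos], 1)
  }
  p
}

vctrs_recycle <- function(...) {
  xs <- list(...)
  len <- max(lengths(xs))
  lapply(xs, rep_len, length.out = len)
}

#' Pearson and likelihood-ratio chi-square for 2x2 tables
#'
#' Expected cells `E_ij = row_i * col_j / N`; the Pearson statistic
#' `sum((O - E)^2 / E)` without continuity correction, and the
#' likelihood-ratio statistic `2 * sum(O * ln(O / E))` with
#' `0 * ln(0) = 0`. Both have 1 degree of freedom.
#'
#' @inheritParams fisher_exact_two_tail
#' @return A tibble with columns `pearson`, `lr`, `df` and the four
#'   expected cells `e_a` .. `e_d`.
#' @export
chisq_stats <- function(a, b, c, d) {
  cells <- vctrs_recycle(a, b, c, d)
  a <- cells[[1L]]; b <- cells[[2L]]; c <- cells[[3L]]; d <- cells[[4L]]
  if (any(c(a, b, c, d) < 0)) stop("negative cell count", call. = FALSE)
  nn <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (any(r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0)) {
    stop("chi-square undefined for a zero margin", call. = FALSE)
  }
  e_a <- r1 * c1 / nn; e_b <- r1 * c2 / nn
  e_c <- r2 * c1 / nn; e_d <- r2 * c2 / nn
  olnoe <- function(o, e) ifelse(o == 0, 0, o * log(o / e))
  tibble::tibble(
    pearson = (a - e_a)^2 / e_a + (b - e_b)^2 / e_b +
      (c - e_c)^2 / e_c + (d - e_d)^2 / e_d,
    lr = 2 * (olnoe(a, e_a) + olnoe(b, e_b) +
                olnoe(c, e_c) + olnoe(d, e_d)),
    df = 1L,
    e_a = e_a, e_b = e_b, e_c = e_c, e_d = e_d
  )
}

# Degenerate margins force O = E exactly, where both statistics are 0.
chisq_or_zero <- function(a, b, c, d) {
  tryCatch(chisq_stats(a, b, c, d)[c("pearson", "lr")],
           error = function(e) tibble::tibble(pearson = 0, lr = 0))
}

two_by_two <- function(in_list, with_property) {
  tibble::tibble(
    a = sum(in_list & with_property),
    b = sum(in_list & !with_property),
    c = sum(!in_list & with_property),
    d = sum(!in_list & !with_property)
  )
}

#' Overlap enrichment between two gene lists
#'
#' Tests whether two gene lists drawn from a common universe overlap more
#' (or less) than expected, via the two-tail Fisher exact test on the 2x2
#' membership table, with the Pearson and likelihood-ratio chi-square
#' statistics alongside. The expected overlap under independence is
#' `|A| * |B| / |U|`.
#'
#' @param list_a,list_b Character vectors of gene ids, subsets of
#'   `universe`.
#' @param universe Character vector, the background gene set.
#' @return A one-row tibble: `n_universe`, `n_a`, `n_b`,
#'   `observed_overlap`, `expected_overlap`, `fisher_p`, `pearson_chisq`,
#'   `lr_chisq`, `df`.
#' @export
overlap_enrichment <- function(list_a, list_b, universe) {
  universe <- unique(universe)
  for (nm in c("list_a", "list_b")) {
    extra <- setdiff(get(nm), universe)
    if (length(extra) > 0L) {
      stop(nm, " contains gene(s) outside the universe: ",
           paste(head(extra, 5L), collapse = ", "), call. = FALSE)
    }
  }
  in_a <- universe %in% list_a
  in_b <- universe %in% list_b
  t22 <- two_by_two(in_a, in_b)
  chisq <- chisq_or_zero(t22$a, t22$b, t22$c, t22$d)
  tibble::tibble(
    n_universe = length(universe),
    n_a = sum(in_a),
    n_b = sum(in_b),
    observed_overlap = t22$a,
    expected_overlap = sum(in_a) * sum(in_b) / length(universe),
    fisher_p = fisher_exact_two_tail(t22$a, t22$b, t22$c, t22$d),
    pearson_chisq = chisq$pearson,
    lr_chisq = chisq$lr,
    df = 1L
  )
}

#' Chromosome distribution of a gene list
#'
#' Compares the observed number of list genes on each chromosome with the
#' count expected from the universe's chromosome composition
#' (`|list| * |universe on chromosome| / |universe|`), testing each
#' chromosome with the two-tail Fisher exact test and flagging
#' `p < 0.001`. An empty list yields observed/expected 0 and no test.
#'
#' @param genes Character vector of gene ids (subset of `universe`).
#' @param chrom_map Tibble with columns `gene_id`, `chromosome` covering
#'   every universe gene.
#' @param universe Character vector, the background gene set.
#' @return A tibble with one row per chromosome: `chromosome`,
#'   `n_universe`, `observed`, `expected`, `fisher_p`, `significant`.
#' @export
chromosome_enrichment <- function(genes, chrom_map, universe) {
  universe <- unique(universe)
  extra <- setdiff(genes, universe)
  if (length(extra) > 0L) {
    stop("gene(s) outside the universe: ",
         paste(head(extra, 5L), collapse = ", "), call. = FALSE)
  }
  chrom <- chrom_map$chromosome[match(universe, chrom_map$gene_id)]
  if (anyNA(chrom)) {
    stop("gene(s) missing from chrom_map: ",
         paste(head(universe[is.na(chrom)], 5L), collapse = ", "),
         call. = FALSE)
  }
  in_list <- universe %in% genes
  out <- purrr::map_dfr(sort(unique(chrom)), function(ck) {
    on_k <- chrom == ck
    t22 <- two_by_two(in_list, on_k)
    tibble::tibble(
      chromosome = ck,
      n_universe = sum(on_k),
      observed = t22$a,
      expected = sum(in_list) * sum(on_k) / length(universe),
      fisher_p = if (sum(in_list) == 0L) NA_real_ else
        fisher_exact_two_tail(t22$a, t22$b, t22$c, t22$d)
    )
  })
  dplyr::mutate(out, significant = !is.na(.data$fisher_p) &
                  .data$fisher_p < 0.001)
}

#' Motif enrichment in a gene list
#'
#' For each motif indicator, builds the 2x2 table of list membership
#' against motif presence over the universe and reports the classic
#' enrichment row: total genes in the list, number with the motif, the
#' expected number under the universe's background rate, Pearson and
#' likelihood-ratio chi-square (df 1) and the two-tail Fisher exact
#' p-value. Motif presence is an input indicator: how the sequence
#' regions were scanned (and with which position weight matrices) is the
#' caller's record.
#'
#' @param genes Character vector of gene ids (subset of `universe`).
#' @param motif_flags Tibble in long form with columns `gene_id`,
#'   `motif`, `present` (0/1 or logical), defined for every universe
#'   gene.
#' @param universe Character vector, the background gene set.
#' @return A tibble with one row per motif: `motif`, `total_genes`,
#'   `n_with_motif`, `expected`, `pearson_chisq`, `df`, `lr_chisq`,
#'   `fisher_p`.
#' @export
motif_enrichment <- function(genes, motif_flags, universe) {
  universe <- unique(universe)
  extra <- setdiff(genes, universe)
  if (length(extra) > 0L) {
    stop("gene(s) outside the universe: ",
         paste(head(extra, 5L), collapse = ", "), call. = FALSE)
  }
  stopifnot(all(c("gene_id", "motif", "present") %in% names(motif_flags)))
  in_list <- universe %in% genes
  purrr::map_dfr(sort(unique(motif_flags$motif)), function(mk) {
    flags <- dplyr::filter(motif_flags, .data$motif == mk)
    present <- flags$present[match(universe, flags$gene_id)]
    if (anyNA(present)) {
      stop("motif '", mk, "' flag missing for universe gene(s): ",
           paste(head(universe[is.na(present)], 5L), collapse = ", "),
           call. = FALSE)
    }
    present <- as.logical(present)
    t22 <- two_by_two(in_list, present)
    chisq <- chisq_or_zero(t22$a, t22$b, t22$c, t22$d)
    tibble::tibble(
      motif = mk,
      total_genes = sum(in_list),
      n_with_motif = t22$a,
      expected = sum(in_list) * mean(present),
      pearson_chisq = chisq$pearson,
      df = 1L,
      lr_chisq = chisq$lr,
      fisher_p = fisher_exact_two_tail(t22$a, t22$b, t22$c, t22$d)
    )
  })
}
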