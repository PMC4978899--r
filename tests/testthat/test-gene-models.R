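gtf_line <- function(chrom, start, end, gene, strand = "+",
                     feature = "exon") {
  paste(chrom, "src", feature, start, end, ".", strand, ".",
        sprintf('gene_id "%s";', gene), sep = "\t")
}

test_that("GTF exons are converted to 0-based half-open coordinates", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    gtf_line("chr2L", 100, 200, "g1"),
    gtf_line("chr2L", 300, 400, "g1"),
    gtf_line("chr3R", 50, 50, "g2", strand = "-")
  ), path)
  exons <- read_gene_models(path)
  expect_equal(nrow(exons), 3L)
  expect_equal(exons$start[1], 99L)
  expect_equal(exons$end[1], 200L)
  expect_equal(sum(exons$gene_id == "g1"), 2L)
  # length-1 exon (start == end in 1-based inclusive)
  len1 <- exons[exons$gene_id == "g2", ]
  expect_equal(len1$end - len1$start, 1L)
  expect_equal(len1$start, 49L)
  expect_equal(len1$strand, "-")
})

test_that("BED-like input is read as-is and bad input is rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t0\t100\tg1\te1\t+", "chr1\t150\t250\tg1\te2\t+"),
             path)
  exons <- read_gene_models(path)
  expect_equal(exons$start, c(0L, 150L))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t0\t100\tg1\te1\t+", "chr1\tnot_a_number\t5\tg1\te2\t+"),
             bad)
  expect_error(read_gene_models(bad), "line 2")

  nogene <- withr::local_tempfile(fileext = ".gtf")
  writeLines(paste("chr1", "src", "exon", "1", "10", ".", "+", ".", "",
                   sep = "\t"), nogene)
  expect_error(read_gene_models(nogene), "gene_id")
})

test_that("exonic regions merge overlapping and adjacent exons per gene", {
  mk <- function(gene, start, end) {
    tibble::tibble(gene_id = gene,
                   exon_id = paste0(gene, "_", start),
                   chromosome = "chr1", start = start, end = end,
                   strand = "+")
  }
  one <- build_exonic_regions(mk("g1", 99L, 200L))
  expect_equal(nrow(one), 1L)
  expect_equal(one$length_bp, 101L)

  merged <- build_exonic_regions(dplyr::bind_rows(mk("g1", 0L, 100L),
                                                  mk("g1", 50L, 150L)))
  expect_equal(nrow(merged), 1L)
  expect_equal(c(merged$start, merged$end, merged$length_bp),
               c(0L, 150L, 150L))

  disjoint <- build_exonic_regions(dplyr::bind_rows(mk("g1", 0L, 100L),
                                                    mk("g1", 200L, 300L)))
  expect_equal(nrow(disjoint), 2L)
  expect_equal(disjoint$length_bp, c(100L, 100L))

  adjacent <- build_exonic_regions(dplyr::bind_rows(mk("g1", 0L, 100L),
                                                    mk("g1", 100L, 180L)))
  expect_equal(nrow(adjacent), 1L)
  expect_equal(adjacent$length_bp, 180L)
})

test_that("region construction is idempotent on disjoint regions", {
  set.seed(11)
  exons <- purrr::map_dfr(1:5, function(g) {
    starts <- sort(sample(0:5000, 4L))
    tibble::tibble(gene_id = paste0("g", g),
                   exon_id = paste0("g", g, "_e", 1:4),
                   chromosome = "chr1",
                   start = starts * 3L,
                   end = starts * 3L + 2L, # short, widely separated
                   strand = "+")
  })
  once <- build_exonic_regions(exons)
  again <- build_exonic_regions(
    dplyr::mutate(region_gene_map(once) |>
                    dplyr::left_join(once, by = "region_id"),
                  exon_id = paste0(region_id, "@", gene_id)) |>
      dplyr::select(gene_id, exon_id, chromosome, start, end) |>
      dplyr::mutate(strand = "+")
  )
  expect_equal(again[c("region_id", "chromosome", "start", "end")],
               once[c("region_id", "chromosome", "start", "end")])
})

test_that("total region length per gene matches the brute-force bp union", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:6, 1L)
    starts <- sample(0:9000, n)
    widths <- sample(50:800, n, replace = TRUE)
    exons <- tibble::tibble(
      gene_id = "g1", exon_id = paste0("e", seq_len(n)),
      chromosome = "chr1", start = starts,
      end = pmin(starts + widths, 10000L), strand = "+"
    )
    regions <- build_exonic_regions(exons)
    expect_equal(sum(regions$length_bp),
                 oracle_gene_bp(exons$start, exons$end))
  }
})

test_that("regions overlapping two genes are assigned per the flag", {
  exons <- tibble::tibble(
    gene_id = c("gA", "gB"), exon_id = c("a1", "b1"),
    chromosome = "chr1", start = c(0L, 50L), end = c(100L, 150L),
    strand = "+"
  )
  shared <- build_exonic_regions(exons)
  expect_equal(nrow(shared), 2L)
  expect_true(all(vapply(shared$gene_ids, function(g)
    setequal(g, c("gA", "gB")), logical(1))))

  unique_assign <- build_exonic_regions(exons, multi_gene = FALSE)
  expect_equal(sort(unlist(unique_assign$gene_ids)), c("gA", "gB"))
  expect_true(all(lengths(unique_assign$gene_ids) == 1L))
})

test_that("count matrix I/O round-trips and validates", {
  design <- make_sample_design(1L)
  counts <- tibble::tibble(
    region_id = c("r1", "r2", "r3"),
    MI_1 = c(1L, 1L, 1L), FI_1 = c(1L, 1L, 1L),
    MT_1 = c(1L, 1L, 1L), FT_1 = c(1L, 1L, 1L)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(counts, path)
  back <- read_count_matrix(path, design)
  expect_equal(back, counts)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(back, path2)
  expect_identical(readLines(path), readLines(path2))

  expect_equal(library_sizes(counts)$library_size, rep(3, 4))
  zero <- dplyr::mutate(counts, dplyr::across(-region_id, ~0L))
  expect_equal(library_sizes(zero)$library_size, rep(0, 4))
  single <- dplyr::mutate(zero, MT_1 = c(7L, 0L, 0L))
  expect_equal(library_sizes(single)$library_size[
    library_sizes(single)$sample_id == "MT_1"], 7)

  bad <- dplyr::rename(counts, bogus = "MT_1")
  pb <- withr::local_tempfile(); write_count_matrix(bad, pb)
  expect_error(read_count_matrix(pb, design), "unknown sample")
  neg <- dplyr::mutate(counts, MI_1 = c(-1L, 0L, 0L))
  pn <- withr::local_tempfile(); write_count_matrix(neg, pn)
  expect_error(read_count_matrix(pn, design), "negative")
  dup <- counts; dup$region_id <- c("r1", "r1", "r3")
  pd <- withr::local_tempfile(); write_count_matrix(dup, pd)
  expect_error(read_count_matrix(pd, design), "duplicate")
})

test_that("external library sizes override column sums", {
  design <- make_sample_design(1L)
  counts <- tibble::tibble(region_id = "r1", MI_1 = 5L, FI_1 = 5L,
                           MT_1 = 5L, FT_1 = 5L)
  ext <- tibble::tibble(sample_id = design$sample_id,
                        library_size = rep(1e6, 4))
  expect_equal(library_sizes(counts, ext)$library_size, rep(1e6, 4))
  too_small <- dplyr::mutate(ext, library_size = 2)
  expect_error(library_sizes(counts, too_small), "smaller than")
})
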