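test_that("group stats are means and unbiased variances with a floor", {
  design <- dplyr::filter(make_sample_design(5L), condition == "MI" |
                            replicate <= 3L)
  # build a design with unequal replicate counts: MI 5, others 3
  mat <- matrix(0, nrow = 3, ncol = nrow(design),
                dimnames = list(c("r1", "r2", "r3"), design$sample_id))
  mat["r1", design$condition == "MI"] <- 1
  mat["r2", design$sample_id[design$condition == "FI"]] <- c(0, 1, 2)
  mat["r3", design$sample_id[design$condition == "MT"][1:2]] <- c(2, 4)
  expr <- expr_tibble(mat, design)
  gs <- fit_group_stats(expr, design)
  pick <- function(r, cc) gs[gs$region_id == r & gs$condition == cc, ]
  expect_equal(pick("r1", "MI")$mean, 1)
  expect_equal(pick("r1", "MI")$var, 1e-8) # constant group floored
  expect_equal(pick("r2", "FI")$mean, 1)
  expect_equal(pick("r2", "FI")$var, 1)
  expect_equal(pick("r2", "FI")$n, 3)
  mt <- pick("r3", "MT")
  expect_equal(mt$mean, 2)       # (2, 4, 0) / 3
  expect_equal(mt$var, 4)        # var of (2, 4, 0)
})

test_that("two-group contrasts reproduce the Welch t-test exactly", {
  design <- make_sample_design(5L)
  set.seed(101)
  for (i in 1:25) {
    mat <- draw_expr_matrix(1L, design,
                            means = c(MI = rnorm(1), FI = rnorm(1),
                                      MT = rnorm(1), FT = rnorm(1)),
                            sds = c(MI = runif(1, 0.1, 1),
                                    FI = runif(1, 0.1, 1),
                                    MT = runif(1, 0.1, 1),
                                    FT = runif(1, 0.1, 1)))
    expr <- expr_tibble(mat, design)
    res <- test_contrasts(fit_group_stats(expr, design, variance_floor = 0))
    mtmi <- res[res$contrast == "MT-MI", ]
    ref <- oracle_welch(mat[1, design$condition == "MT"],
                        mat[1, design$condition == "MI"])
    expect_equal(mtmi$estimate, ref$estimate, tolerance = 1e-12)
    expect_equal(mtmi$t, ref$t, tolerance = 1e-10)
    expect_equal(mtmi$df, ref$df, tolerance = 1e-10)
    expect_equal(mtmi$p_raw, ref$p, tolerance = 1e-10)
  }
})

test_that("equal group means give a null result", {
  design <- make_sample_design(3L)
  mat <- matrix(rep(c(1, 2, 3), times = 4), nrow = 1)
  colnames(mat) <- design$sample_id # identical replicates per condition
  expr <- expr_tibble(mat, design)
  res <- test_contrasts(fit_group_stats(expr, design))
  expect_equal(res$estimate, rep(0, 5))
  expect_equal(res$t, rep(0, 5))
  expect_equal(res$p_raw, rep(1, 5))
})

test_that("Satterthwaite df reduces to 2(n-1) for equal variance and n", {
  design <- make_sample_design(5L)
  base <- c(-2, -1, 0, 1, 2) # identical spread in both groups
  mat <- matrix(0, 1, 20, dimnames = list("r1", design$sample_id))
  mat[1, design$condition == "MT"] <- base + 5
  mat[1, design$condition == "MI"] <- base
  expr <- expr_tibble(mat, design)
  res <- test_contrasts(fit_group_stats(expr, design))
  expect_equal(res$df[res$contrast == "MT-MI"], 8)
})

test_that("Satterthwaite df stays within its theoretical bounds", {
  design <- make_sample_design(5L)
  set.seed(77)
  mat <- draw_expr_matrix(200L, design)
  res <- test_contrasts(fit_group_stats(expr_tibble(mat, design), design))
  w <- default_contrasts()
  for (k in seq_len(nrow(w))) {
    used <- abs(as.numeric(w[k, c("MI", "FI", "MT", "FT")])) > 0
    dfk <- res$df[res$contrast == w$contrast[k]]
    expect_true(all(dfk >= 4 - 1e-9))            # min_i (n_i - 1)
    expect_true(all(dfk <= 4 * sum(used) + 1e-9)) # sum over used groups
  }
})

test_that("negating a contrast flips estimate and t but not p", {
  design <- make_sample_design(5L)
  set.seed(8)
  expr <- expr_tibble(draw_expr_matrix(30L, design), design)
  gs <- fit_group_stats(expr, design)
  fwd <- test_contrasts(gs, tibble::tibble(contrast = "c", MI = 0, FI = 0,
                                           MT = 1, FT = -1))
  rev <- test_contrasts(gs, tibble::tibble(contrast = "c", MI = 0, FI = 0,
                                           MT = -1, FT = 1))
  expect_equal(fwd$estimate, -rev$estimate)
  expect_equal(fwd$t, -rev$t)
  expect_equal(fwd$p_raw, rev$p_raw)
  expect_equal(fwd$df, rev$df)
})

test_that("p-values are location and positive-scale invariant", {
  design <- make_sample_design(5L)
  set.seed(9)
  mat <- draw_expr_matrix(20L, design)
  base <- test_contrasts(fit_group_stats(expr_tibble(mat, design), design,
                                         variance_floor = 0))
  shifted <- test_contrasts(fit_group_stats(
    expr_tibble(mat + 7.3, design), design, variance_floor = 0))
  scaled <- test_contrasts(fit_group_stats(
    expr_tibble(mat * 2.6, design), design, variance_floor = 0))
  expect_equal(shifted$p_raw, base$p_raw, tolerance = 1e-12)
  expect_equal(scaled$p_raw, base$p_raw, tolerance = 1e-12)
})

test_that("an exact additive TRAP effect lands in the right contrasts", {
  design <- make_sample_design(5L)
  base <- rnorm(5)
  delta <- 1.25
  mat <- matrix(0, 1, 20, dimnames = list("r1", design$sample_id))
  mat[1, design$condition == "MI"] <- base
  mat[1, design$condition == "MT"] <- base + delta
  mat[1, design$condition == "FI"] <- base + 0.5
  mat[1, design$condition == "FT"] <- base + 0.5
  res <- test_contrasts(fit_group_stats(expr_tibble(mat, design), design))
  est <- setNames(res$estimate, res$contrast)
  expect_equal(unname(est["MT-MI"]), delta)
  expect_equal(unname(est["FT-FI"]), 0)
  expect_equal(unname(est["(MT-MI)-(FT-FI)"]), delta)
})

test_that("BH adjustment matches the brute-force step-up", {
  expect_equal(adjust_fdr(0.03), 0.03)
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(adjust_fdr(rep(1, 10)), rep(1, 10))
  expect_error(adjust_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(123)
  for (i in 1:1000) {
    p <- runif(sample(1:50, 1L))
    expect_equal(adjust_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("the full fit returns one adjusted result per region x contrast", {
  design <- make_sample_design(5L)
  set.seed(21)
  expr <- expr_tibble(draw_expr_matrix(1L, design), design)
  fit <- run_exon_de(expr, design)
  expect_s3_class(fit, "exon_de")
  expect_equal(nrow(fit$results), 5L)
  expect_false(anyNA(fit$results$p_fdr))
  expect_true(all(fit$results$p_fdr >= fit$results$p_raw))
  expect_equal(tidy(fit), fit$results)
  expect_equal(glance(fit)$n_tests, 5L)
})

test_that("per-contrast FDR pooling adjusts within each contrast", {
  design <- make_sample_design(5L)
  set.seed(31)
  expr <- expr_tibble(draw_expr_matrix(40L, design), design)
  pooled <- run_exon_de(expr, design, fdr_pool = "pooled")
  per <- run_exon_de(expr, design, fdr_pool = "per_contrast")
  expect_equal(pooled$results$p_fdr, adjust_fdr(pooled$results$p_raw))
  one <- per$results[per$results$contrast == "MT-FT", ]
  expect_equal(one$p_fdr, adjust_fdr(one$p_raw))
})

test_that("contrasts touching a 1-replicate condition are rejected", {
  design <- dplyr::filter(make_sample_design(5L),
                          condition != "FT" | replicate == 1L)
  mat <- draw_expr_matrix(2L, design)
  gs <- fit_group_stats(expr_tibble(mat, design), design)
  expect_error(test_contrasts(gs), "fewer than 2 replicates")
  # contrasts avoiding FT still work
  ok <- test_contrasts(gs, tibble::tibble(contrast = "MT-MI", MI = -1,
                                          FI = 0, MT = 1, FT = 0))
  expect_equal(nrow(ok), 2L)
})
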