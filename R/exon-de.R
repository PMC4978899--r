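#' The five default contrasts
#'
#' TRAP enrichment within each sex (MT-MI, FT-FI), the sex-by-fraction
#' interaction ((MT-MI)-(FT-FI)), sex bias in TRAP (MT-FT) and sex bias in
#' input (MI-FI). Each row is a zero-sum weight vector over the four
#' condition means, tested against zero.
#'
#' @return A tibble with columns `contrast`, `MI`, `FI`, `MT`, `FT`.
#' @export
default_contrasts <- function() {
  tibble::tribble(
    ~contrast,            ~MI, ~FI, ~MT, ~FT,
    "MT-MI",               -1,   0,   1,   0,
    "FT-FI",                0,  -1,   0,   1,
    "(MT-MI)-(FT-FI)",     -1,   1,   1,  -1,
    "MT-FT",                0,   0,   1,  -1,
    "MI-FI",                1,  -1,   0,   0
  )
}

validate_contrasts <- function(contrasts) {
  stopifnot(all(c("contrast", CONDITIONS) %in% names(contrasts)))
  w <- as.matrix(contrasts[CONDITIONS])
  if (any(abs(rowSums(w)) > 1e-12)) {
    stop("contrast weights must sum to zero", call. = FALSE)
  }
  if (any(rowSums(abs(w)) == 0)) {
    stop("contrast with all-zero weights", call. = FALSE)
  }
  contrasts
}

#' Per-condition means and variances of ln-RPKM
#'
#' Summarises each region's expression by condition: the arithmetic mean,
#' the unbiased sample variance (divisor `n - 1`), and the replicate
#' count. This is the one-way heteroscedastic model fit: one mean and one
#' residual variance per condition. Variances below `variance_floor` are
#' raised to it so a constant group never yields a zero standard error.
#'
#' @param expr ln-RPKM tibble from [ln_transform()] (`region_id` + sample
#'   columns), usually restricted to analyzable regions.
#' @param design Sample design tibble.
#' @param variance_floor Lower bound for per-condition variances on the
#'   ln-RPKM scale (default `1e-8`).
#' @return A tibble with columns `region_id`, `condition`, `mean`, `var`,
#'   `n`.
#' @export
fit_group_stats <- function(expr, design, variance_floor = 1e-8) {
  validate_design(design)
  samples <- design$sample_id
  mat <- as.matrix(expr[samples])
  if (any(!is.finite(mat))) {
    stop("non-finite ln-RPKM value; check the log offset", call. = FALSE)
  }
  purrr::map_dfr(sort(unique(design$condition)), function(cc) {
    cols <- samples[design$condition == cc]
    sub <- mat[, cols, drop = FALSE]
    n <- length(cols)
    v <- if (n >= 2L) {
      pmax(apply(sub, 1L, var), variance_floor)
    } else {
      rep(NA_real_, nrow(sub))
    }
    tibble::tibble(
      region_id = expr$region_id,
      condition = cc,
      mean = rowMeans(sub),
      var = v,
      n = n
    )
  }) |>
    dplyr::arrange(.data$region_id)
}

#' Test zero-sum contrasts under the heteroscedastic one-way model
#'
#' For each region and contrast with weights `c_i` over condition means
#' `m_i`, variances `s2_i` and replicate counts `n_i`:
#' estimate `= sum c_i m_i`; `SE^2 = sum c_i^2 s2_i / n_i`; `t =`
#' estimate`/SE`; and the degrees of freedom follow the Satterthwaite
#' approximation `df = SE^4 / sum((c_i^2 s2_i / n_i)^2 / (n_i - 1))`, the
#' Welch construction generalised to arbitrary contrasts. Raw p-values are
#' two-sided t tail probabilities; direction lives in the sign of the
#' estimate.
#'
#' @param group_stats Output of [fit_group_stats()].
#' @param contrasts Contrast tibble ([default_contrasts()]).
#' @param df_method `"satterthwaite"` (default) or `"residual"`
#'   (`sum(n_i) - 4`, the pooled-model residual df, for sensitivity
#'   analysis).
#' @return A tibble with columns `region_id`, `contrast`, `estimate`,
#'   `se`, `df`, `t`, `p_raw`.
#' @export
test_contrasts <- function(group_stats, contrasts = default_contrasts(),
                           df_method = c("satterthwaite", "residual")) {
  df_method <- match.arg(df_method)
  validate_contrasts(contrasts)
  wide <- tidyr::pivot_wider(group_stats, id_cols = "region_id",
                             names_from = "condition",
                             values_from = c("mean", "var", "n"))
  m <- as.matrix(wide[paste0("mean_", CONDITIONS)])
  s2 <- as.matrix(wide[paste0("var_", CONDITIONS)])
  n <- as.matrix(wide[paste0("n_", CONDITIONS)])

  purrr::map_dfr(seq_len(nrow(contrasts)), function(k) {
    w <- as.numeric(contrasts[k, CONDITIONS])
    used <- w != 0
    if (any(n[, used] < 2L)) {
      stop("condition with fewer than 2 replicates in contrast '",
           contrasts$contrast[k], "'", call. = FALSE)
    }
    est <- drop(m %*% w)
    u <- sweep(s2, 2L, w^2, `*`) / n # c_i^2 s2_i / n_i
    se2 <- rowSums(u)
    df <- switch(df_method,
      satterthwaite = se2^2 / rowSums(u^2 / (n - 1L)),
      residual = rowSums(n[, used, drop = FALSE] - 1L)
    )
    tt <- est / sqrt(se2)
    tibble::tibble(
      region_id = wide$region_id,
      contrast = contrasts$contrast[k],
      estimate = est,
      se = sqrt(se2),
      df = df,
      t = tt,
      p_raw = 2 * pt(-abs(tt), df)
    )
  })
}

#' Benjamini-Hochberg adjustment over the pooled test family
#'
#' Step-up adjusted p-values for the full family of exon-by-contrast
#' tests considered simultaneously.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
adjust_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Fit the exon-level differential-expression model
#'
#' Runs [fit_group_stats()] and [test_contrasts()] over all regions,
#' then applies the Benjamini-Hochberg correction over the pooled
#' region-by-contrast family (all contrasts "considered simultaneously";
#' set `fdr_pool = "per_contrast"` to adjust each contrast separately).
#' Significance is reported at two tiers: the primary FDR threshold
#' (default `<= 0.2`, chosen liberal to limit type II error) and a strict
#' tier (`< 0.05`).
#'
#' @param expr ln-RPKM tibble, typically restricted to the analyzable
#'   regions of [filter_regions()].
#' @param design Sample design tibble.
#' @param contrasts Contrast tibble (default [default_contrasts()]).
#' @param fdr_pool `"pooled"` (default) or `"per_contrast"`.
#' @param fdr_primary Primary significance threshold on adjusted p
#'   (default 0.2, inclusive).
#' @param fdr_strict Strict threshold (default 0.05, exclusive).
#' @param variance_floor Passed to [fit_group_stats()].
#' @param df_method Passed to [test_contrasts()].
#' @return An object of class `exon_de`: a list with `results` (tibble
#'   adding `p_fdr`, `significant`, `significant_strict`), `group_stats`,
#'   `contrasts` and `config`. Use [tidy()] / [glance()] / [autoplot()].
#' @export
run_exon_de <- function(expr, design, contrasts = default_contrasts(),
                        fdr_pool = c("pooled", "per_contrast"),
                        fdr_primary = 0.2, fdr_strict = 0.05,
                        variance_floor = 1e-8,
                        df_method = c("satterthwaite", "residual")) {
  fdr_pool <- match.arg(fdr_pool)
  df_method <- match.arg(df_method)
  stopifnot(0 < fdr_strict, fdr_strict <= fdr_primary, fdr_primary < 1)
  gs <- fit_group_stats(expr, design, variance_floor)
  res <- test_contrasts(gs, contrasts, df_method)
  res <- if (fdr_pool == "pooled") {
    dplyr::mutate(res, p_fdr = adjust_fdr(.data$p_raw))
  } else {
    res |>
      dplyr::group_by(.data$contrast) |>
      dplyr::mutate(p_fdr = adjust_fdr(.data$p_raw)) |>
      dplyr::ungroup()
  }
  res <- dplyr::mutate(
    res,
    significant = .data$p_fdr <= fdr_primary,
    significant_strict = .data$p_fdr < fdr_strict
  )
  structure(
    list(
      results = res,
      group_stats = gs,
      contrasts = contrasts,
      config = list(
        fdr_pool = fdr_pool, fdr_primary = fdr_primary,
        fdr_strict = fdr_strict, variance_floor = variance_floor,
        df_method = df_method, offset = attr(expr, "offset")
      )
    ),
    class = "exon_de"
  )
}

#' @export
print.exon_de <- function(x, ...) {
  g <- glance(x)
  cat("Exon-level heteroscedastic contrast fit\n")
  cat("  regions:", g$n_regions, " contrasts:", g$n_contrasts,
      " tests:", g$n_tests, "\n")
  cat(sprintf("  significant at FDR <= %.2g: %d (strict < %.2g: %d)\n",
              x$config$fdr_primary, g$n_significant,
              x$config$fdr_strict, g$n_significant_strict))
  invisible(x)
}

#' @rdname run_exon_de
#' @param x An `exon_de` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.exon_de <- function(x, ...) {
  x$results
}

#' @rdname run_exon_de
#' @exportS3Method generics::glance
glance.exon_de <- function(x, ...) {
  tibble::tibble(
    n_regions = dplyr::n_distinct(x$results$region_id),
    n_contrasts = nrow(x$contrasts),
    n_tests = nrow(x$results),
    n_significant = sum(x$results$significant),
    n_significant_strict = sum(x$results$significant_strict),
    fdr_primary = x$config$fdr_primary,
    fdr_strict = x$config$fdr_strict,
    fdr_pool = x$config$fdr_pool,
    df_method = x$config$df_method
  )
}
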