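# Independent oracles used across the suite. Each reimplements the checked
# quantity by a different route than the package (enumeration, brute force,
# or an established stats function) and must stay that way.

# Welch two-sample t-test via stats::t.test (independent of test_contrasts).
oracle_welch <- function(x, y) {
  fit <- stats::t.test(x, y, var.equal = FALSE)
  list(estimate = mean(x) - mean(y),
       t = unname(fit$statistic),
       df = unname(fit$parameter),
       p = fit$p.value)
}

# Brute-force Benjamini-Hochberg step-up: p_(k) * m / k, cumulative
# minimum from the largest rank down, mapped back to input order.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  for (k in (m - 1):1) if (m > 1) adj[k] <- min(adj[k], adj[k + 1])
  pmin(adj, 1)[order(ord)]
}

# Two-tail Fisher exact p by naive enumeration with lchoose arithmetic.
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1)
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  pr <- exp(logp)
  obs <- pr[support == a]
  min(sum(pr[pr <= obs * (1 + 1e-7)]), 1)
}

# Union of exon base pairs per gene, by materialising the bp set.
oracle_gene_bp <- function(starts, ends) {
  length(unique(unlist(mapply(function(s, e) seq(s, e - 1L), starts, ends,
                              SIMPLIFY = FALSE))))
}

# Expression tibble from a region x sample matrix.
expr_tibble <- function(mat, design, offset = 0.001) {
  out <- dplyr::bind_cols(
    tibble::tibble(region_id = rownames(mat) %||%
                     paste0("r", seq_len(nrow(mat)))),
    tibble::as_tibble(mat, .name_repair = ~design$sample_id)
  )
  attr(out, "offset") <- offset
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gaussian ln-expression draws for the four conditions at given means/SDs.
draw_expr_matrix <- function(n_regions, design,
                             means = c(MI = 0, FI = 0, MT = 0, FT = 0),
                             sds = c(MI = 0.2, FI = 0.25,
                                     MT = 0.3, FT = 0.35)) {
  mat <- sapply(seq_len(nrow(design)), function(j) {
    cc <- design$condition[j]
    rnorm(n_regions, means[cc], sds[cc])
  })
  matrix(mat, nrow = n_regions,
         dimnames = list(paste0("r", seq_len(n_regions)),
                         design$sample_id))
}
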