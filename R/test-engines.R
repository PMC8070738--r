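# Vectorized row-wise two-group tests used by the per-gene DEG caller.
# Thousands of genes are tested per run, so the Brown-Forsythe gate, the
# one-way ANOVA and the Kruskal-Wallis statistic are computed directly from
# group sums rather than through per-gene model-fitting calls.  The test
# suite checks each engine against car::leveneTest, stats::oneway.test /
# aov and stats::kruskal.test on random inputs.

# F statistic and p for a one-way ANOVA with two groups, by row.
# Returns p = NA when both group variances are zero and the means are equal
# (nothing to test); p = 0 when within-variance is zero but means differ.
row_anova2 <- function(x, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2); n <- n1 + n2
  m1 <- rowMeans(x[, idx1, drop = FALSE])
  m2 <- rowMeans(x[, idx2, drop = FALSE])
  m <- (n1 * m1 + n2 * m2) / n
  ss_between <- n1 * (m1 - m)^2 + n2 * (m2 - m)^2
  ss_within <- rowSums((x[, idx1, drop = FALSE] - m1)^2) +
    rowSums((x[, idx2, drop = FALSE] - m2)^2)
  f <- (ss_between / 1) / (ss_within / (n - 2))
  p <- pf(f, 1, n - 2, lower.tail = FALSE)
  # constant rows: sums of squares at rounding-noise level carry no signal
  tol <- n * (1e-8 * (abs(m) + 1))^2
  zero_w <- ss_within <= tol
  zero_b <- ss_between <= tol
  p[zero_w & !zero_b] <- 0
  p[zero_w & zero_b] <- NA_real_
  list(statistic = f, p = p)
}

# Brown-Forsythe (median-centred Levene) p-value by row, two groups.
# Rows whose absolute deviations are constant overall carry no spread
# information; they are reported as p = 1 (treated as homoscedastic).
row_levene_bf <- function(x, idx1, idx2) {
  z <- x
  z[, idx1] <- abs(x[, idx1, drop = FALSE] -
                     row_medians(x[, idx1, drop = FALSE]))
  z[, idx2] <- abs(x[, idx2, drop = FALSE] -
                     row_medians(x[, idx2, drop = FALSE]))
  res <- row_anova2(z, idx1, idx2)
  p <- res$p
  p[is.na(p)] <- 1
  p
}

row_medians <- function(x) {
  apply(x, 1, median)
}

# Kruskal-Wallis by row for two groups.  For tie-free rows with total
# sample size <= exact_max the p-value is computed by exhaustive
# enumeration of all assignments of ranks to group 1 (the exact conditional
# null); otherwise the chi-square approximation with the standard tie
# correction is used.  `method` records which route each row took.
row_kruskal2 <- function(x, idx1, idx2, exact_max = 10L) {
  n1 <- length(idx1); n2 <- length(idx2); n <- n1 + n2
  ranks <- t(apply(x[, c(idx1, idx2), drop = FALSE], 1, rank))
  r1 <- rowSums(ranks[, seq_len(n1), drop = FALSE])
  # H from the rank sum of group 1 (two-group identity)
  h_of_r1 <- function(rs) {
    12 / (n * (n + 1)) *
      (rs^2 / n1 + (n * (n + 1) / 2 - rs)^2 / n2) - 3 * (n + 1)
  }
  h <- h_of_r1(r1)
  # tie correction
  tie_term <- apply(ranks, 1, function(r) {
    t <- table(r)
    sum(t^3 - t)
  })
  has_ties <- tie_term > 0
  correction <- 1 - tie_term / (n^3 - n)
  h_corr <- ifelse(correction > 0, h / correction, NA_real_)
  p <- pchisq(h_corr, df = 1, lower.tail = FALSE)
  method <- rep("chisq", nrow(x))
  all_tied <- correction <= 0
  p[all_tied] <- NA_real_

  exact_rows <- !has_ties & n <= exact_max
  if (any(exact_rows)) {
    h_null <- kw_exact_null(n1, n2)
    p_exact <- vapply(h[exact_rows],
                      function(hv) mean(h_null >= hv - 1e-9), numeric(1))
    p[exact_rows] <- p_exact
    h_corr[exact_rows] <- h[exact_rows]
    method[exact_rows] <- "exact"
  }
  method[all_tied] <- "degenerate"
  list(statistic = h_corr, p = p, method = method)
}

# Null distribution of the two-group Kruskal-Wallis H over all C(n, n1)
# assignments of the tie-free ranks 1..n to group 1.  Memoised per (n1, n2).
kw_exact_null <- local({
  cache <- new.env(parent = emptyenv())
  function(n1, n2) {
    key <- paste(n1, n2)
    if (!is.null(cache[[key]])) return(cache[[key]])
    n <- n1 + n2
    subsets <- combn(n, n1)
    rs <- colSums(matrix(seq_len(n)[subsets], nrow = n1))
    h <- 12 / (n * (n + 1)) *
      (rs^2 / n1 + (n * (n + 1) / 2 - rs)^2 / n2) - 3 * (n + 1)
    cache[[key]] <- h
    h
  }
})
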