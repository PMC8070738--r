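# Independent brute-force oracles used across the suite.  Each oracle is
# deliberately written by a different route than the implementation it
# checks (enumeration, direct summation, from-scratch arithmetic).

# Hypergeometric tails by direct summation of the pmf via choose().
hyper_tail_oracle <- function(N, K, n, k) {
  kk <- max(0, K + n - N):min(K, n)
  pmf <- choose(K, kk) * choose(N - K, n - kk) / choose(N, n)
  list(over = sum(pmf[kk >= k]), under = sum(pmf[kk <= k]),
       point = if (k %in% kk) pmf[kk == k] else 0)
}

# Complete-linkage agglomeration by exhaustive pairwise-max search;
# returns the ordered merge heights.
complete_linkage_heights_oracle <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best_h <- Inf; best <- c(NA, NA)
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best_h - 1e-12) {
          best_h <- h; best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Balanced two-way ANOVA sums of squares from the textbook decomposition.
anova2_ss_oracle <- function(y, a, b) {
  a <- as.character(a); b <- as.character(b)
  grand <- mean(y)
  ss_a <- sum(tapply(y, a, function(v) length(v)) *
                (tapply(y, a, mean) - grand)^2)
  ss_b <- sum(tapply(y, b, function(v) length(v)) *
                (tapply(y, b, mean) - grand)^2)
  cell <- paste(a, b)
  cell_mean <- tapply(y, cell, mean)[cell]
  a_mean <- tapply(y, a, mean)[a]
  b_mean <- tapply(y, b, mean)[b]
  ss_ab <- sum((cell_mean - a_mean - b_mean + grand)^2)
  ss_e <- sum((y - cell_mean)^2)
  c(strain = ss_a, must = ss_b, interaction = ss_ab, residuals = ss_e)
}

# Exact two-sided signed-rank p by enumeration of all 2^n sign patterns.
signed_rank_p_oracle <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  p <- 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))
  min(1, p)
}

# Exact two-sided rank-sum p by enumeration of all group-1 assignments.
rank_sum_p_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  subsets <- utils::combn(n1 + n2, n1)
  w_all <- apply(subsets, 2, function(ix) sum(r[ix]))
  p <- 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))
  min(1, p)
}

# Exact Kruskal-Wallis p for a 3v3 tie-free sample, enumerating all
# assignments of the six values to group 1 and scoring each with
# stats::kruskal.test (an independent route to the H statistic).
kw_exact_p_oracle <- function(x, y) {
  v <- c(x, y)
  h_obs <- unname(kruskal.test(list(x, y))$statistic)
  subsets <- utils::combn(6, 3)
  h_all <- apply(subsets, 2, function(ix) {
    unname(kruskal.test(list(v[ix], v[-ix]))$statistic)
  })
  mean(h_all >= h_obs - 1e-9)
}

# Minimal two-strain RPKM fixture: one gene per row of `values`, equal
# lengths, so RPKM ordering mirrors the raw values.
make_rpkm_fixture <- function(values_wt, values_mut, gene_ids = NULL) {
  n <- nrow(values_wt)
  gene_ids <- gene_ids %||% sprintf("g%03d", seq_len(n))
  samples <- c("wt_1", "wt_2", "wt_3", "mut_1", "mut_2", "mut_3")
  m <- cbind(values_wt, values_mut)
  tibble::tibble(
    gene_id = rep(gene_ids, times = ncol(m)),
    sample_id = rep(samples, each = n),
    rpkm = as.numeric(m))
}

design_3v3 <- tibble::tibble(
  sample_id = c("wt_1", "wt_2", "wt_3", "mut_1", "mut_2", "mut_3"),
  strain = rep(c("wt", "mut"), each = 3))

`%||%` <- function(a, b) if (is.null(a)) b else a
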