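# RPKM normalization, overlap correction, and the Levene-gated DEG caller.

test_that("RPKM follows the unit-scale formula and handles zeros", {
  # 10 counts on a 1 kb gene in a library of 1e6 reads -> RPKM = 10
  counts <- tibble::tibble(
    gene_id = c("gA", "filler", "gA", "filler"),
    sample_id = c("s1", "s1", "s2", "s2"),
    count = c(10L, 999990L, 0L, 1000000L))
  annot <- tibble::tibble(gene_id = c("gA", "filler"),
                          length_bp = c(1000, 5000))
  r <- rpkm_normalize(counts, annot)
  expect_equal(r$rpkm[r$gene_id == "gA" & r$sample_id == "s1"], 10)
  expect_equal(r$rpkm[r$gene_id == "gA" & r$sample_id == "s2"], 0)
})

test_that("RPKM equals independent per-cell recomputation on a random matrix", {
  withr::with_seed(7, {
    cnt <- matrix(rpois(80, 50), nrow = 20)
  })
  genes <- sprintf("g%02d", 1:20)
  samples <- sprintf("s%d", 1:4)
  lengths <- seq(500, 2400, length.out = 20)
  counts <- tibble::tibble(
    gene_id = rep(genes, times = 4),
    sample_id = rep(samples, each = 20),
    count = as.integer(cnt))
  annot <- tibble::tibble(gene_id = genes, length_bp = lengths)
  r <- rpkm_normalize(counts, annot)
  wide <- as.matrix(tidyr::pivot_wider(r, names_from = sample_id,
                                       values_from = rpkm)[, -1])
  manual <- sweep(sweep(cnt * 1e9, 1, lengths, "/"), 2, colSums(cnt), "/")
  expect_equal(unname(wide), unname(manual))

  # scale invariance: multiplying one sample's counts by k is a no-op
  counts2 <- counts
  counts2$count[counts2$sample_id == "s1"] <-
    counts2$count[counts2$sample_id == "s1"] * 7L
  r2 <- rpkm_normalize(counts2, annot)
  expect_equal(r2$rpkm[r2$sample_id == "s1"], r$rpkm[r$sample_id == "s1"])
})

test_that("zero library size raises an error naming the sample", {
  counts <- tibble::tibble(gene_id = c("g1", "g1"),
                           sample_id = c("ok", "empty"),
                           count = c(5L, 0L))
  annot <- tibble::tibble(gene_id = "g1", length_bp = 100)
  expect_error(rpkm_normalize(counts, annot), "empty")
})

test_that("overlap subtraction replaces naive totals with unique counts", {
  counts <- tibble::tibble(
    gene_id = rep(c("A", "B", "C"), each = 2),
    sample_id = rep(c("s1", "s2"), times = 3),
    count = c(100L, 80L, 150L, 120L, 7L, 9L))
  rc <- tibble::tibble(gene_a = "A", gene_b = "B",
                       sample_id = c("s1", "s2"),
                       a_unique = c(40L, 0L), b_unique = c(90L, 40L),
                       shared = c(60L, 80L))
  out <- subtract_overlap(counts, rc)
  expect_equal(out$count[out$gene_id == "A"], c(40L, 0L))
  expect_equal(out$count[out$gene_id == "B"], c(90L, 40L))
  # untouched genes unchanged
  expect_equal(out$count[out$gene_id == "C"], c(7L, 9L))
  expect_true(all(out$count <= counts$count))

  # shared = 0 leaves the pair at its naive totals
  rc0 <- tibble::tibble(gene_a = "A", gene_b = "B",
                        sample_id = c("s1", "s2"),
                        a_unique = c(100L, 80L), b_unique = c(150L, 120L),
                        shared = c(0L, 0L))
  expect_equal(subtract_overlap(counts, rc0), counts)

  # naive total fully explained by the shared region -> corrected 0
  # (a knocked-out gene masked by its overlapping partner)
  rc_masked <- tibble::tibble(gene_a = "A", gene_b = "B",
                              sample_id = c("s1", "s2"),
                              a_unique = c(0L, 0L), b_unique = c(50L, 40L),
                              shared = c(100L, 80L))
  out2 <- subtract_overlap(counts, rc_masked)
  expect_equal(out2$count[out2$gene_id == "A"], c(0L, 0L))

  # declared pair without region counts is an error
  annot <- tibble::tibble(gene_id = c("A", "B", "C"),
                          overlap_partner = c("B", "A", NA))
  rc_other <- tibble::tibble(gene_a = "C", gene_b = "B",
                             sample_id = "s1", a_unique = 1L,
                             b_unique = 1L, shared = 0L)
  expect_error(subtract_overlap(counts, rc_other, annot),
               "missing region counts")
})

test_that("corrected counts recover the generator's unique-region truth", {
  spec <- count_sim_spec(n_genes = 60, knockout_genes = "g0001",
                         overlap_pair = list(gene_a = "g0001",
                                             gene_b = "g0002",
                                             shared_fraction = 0.5),
                         seed = 21)
  sim <- simulate_counts(spec)
  out <- subtract_overlap(sim$counts, sim$region_counts, sim$annotation)
  got <- dplyr::filter(out, gene_id %in% c("g0001", "g0002"))
  wide <- tidyr::pivot_wider(got, names_from = gene_id,
                             values_from = count)
  merged <- dplyr::inner_join(wide, sim$region_counts, by = "sample_id")
  expect_equal(merged$g0001, merged$a_unique)
  expect_equal(merged$g0002, merged$b_unique)
})

test_that("row-wise test engines agree with the reference implementations", {
  skip_if_not_installed("car")
  withr::with_seed(31, {
    x <- matrix(rnorm(25 * 8, mean = 10), nrow = 25)
    # inject heteroscedastic rows so both gate branches are exercised
    x[1:5, 5:8] <- x[1:5, 5:8] * 6
  })
  idx1 <- 1:4; idx2 <- 5:8
  g <- factor(rep(c("a", "b"), each = 4))
  lev <- esterdeg:::row_levene_bf(x, idx1, idx2)
  anv <- esterdeg:::row_anova2(x, idx1, idx2)
  kw <- esterdeg:::row_kruskal2(x, idx1, idx2, exact_max = 0L)
  for (i in seq_len(nrow(x))) {
    v <- x[i, ]
    expect_equal(lev[i],
                 car::leveneTest(v, g, center = median)$`Pr(>F)`[1],
                 tolerance = 1e-10)
    expect_equal(anv$p[i],
                 summary(aov(v ~ g))[[1]]$`Pr(>F)`[1],
                 tolerance = 1e-10)
    expect_equal(kw$p[i], kruskal.test(v, g)$p.value, tolerance = 1e-10)
  }
})

test_that("ANOVA branch on two groups satisfies F = t^2", {
  withr::with_seed(13, {
    x <- matrix(rnorm(10 * 6, mean = 5), nrow = 10)
  })
  anv <- esterdeg:::row_anova2(x, 1:3, 4:6)
  for (i in 1:10) {
    tt <- t.test(x[i, 1:3], x[i, 4:6], var.equal = TRUE)
    expect_equal(anv$statistic[i], unname(tt$statistic)^2,
                 tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis p on tie-free 3v3 input matches exact enumeration", {
  withr::with_seed(17, {
    for (rep in 1:12) {
      x <- rnorm(3); y <- rnorm(3, mean = rep / 6)
      kw <- esterdeg:::row_kruskal2(matrix(c(x, y), nrow = 1), 1:3, 4:6)
      expect_equal(kw$method, "exact")
      expect_equal(kw$p, kw_exact_p_oracle(x, y), tolerance = 1e-12)
    }
  })
  # the exact 3v3 null has a finite attainable minimum: 2 of the 20
  # assignments are as extreme as a perfect separation
  kw_min <- esterdeg:::row_kruskal2(matrix(1:6, nrow = 1), 1:3, 4:6)
  expect_equal(kw_min$p, 2 / 20)
})

test_that("deg_test assigns classes by the dual criterion and BH ordering", {
  wt <- matrix(c(100, 110, 90,   # strong up gene (x4)
                 100, 105, 95,   # null gene
                 50, 50, 50,     # constant equal in both -> untested
                 200, 210, 190), # strong down gene
               nrow = 4, byrow = TRUE)
  mut <- matrix(c(400, 420, 380,
                  101, 98, 103,
                  50, 50, 50,
                  48, 50, 52),
                nrow = 4, byrow = TRUE)
  rpkm <- make_rpkm_fixture(wt, mut)
  res <- deg_test(rpkm, design_3v3)
  expect_s3_class(res, "deg_result")
  expect_equal(res$deg_class[res$gene_id == "g001"], "up")
  expect_equal(res$deg_class[res$gene_id == "g002"], "ns")
  expect_equal(res$deg_class[res$gene_id == "g003"], "untested")
  expect_equal(res$test_used[res$gene_id == "g003"], "none")
  expect_equal(res$deg_class[res$gene_id == "g004"], "down")
  # log2fc sign and rough magnitude
  expect_gt(res$log2fc[res$gene_id == "g001"], 1.9)
  expect_lt(res$log2fc[res$gene_id == "g004"], -1.9)
  # adjusted p never below raw p
  expect_true(all(res$p_adj >= res$p_raw - 1e-12, na.rm = TRUE))
  # class counts partition the tested genes
  g <- glance(res)
  expect_equal(g$n_up + g$n_down + g$n_ns, g$n_tested)
  # DEG calls satisfy both thresholds
  called <- dplyr::filter(res, deg_class %in% c("up", "down"))
  expect_true(all(called$p_adj < 0.05 & abs(called$log2fc) >= 1))
})

test_that("BH adjustment is monotone in the raw p-values", {
  withr::with_seed(23, {
    wt <- matrix(rnorm(60, 100, 10), ncol = 3)
    mut <- matrix(rnorm(60, 100, 10), ncol = 3)
  })
  res <- deg_test(make_rpkm_fixture(wt, mut), design_3v3)
  ord <- order(res$p_raw)
  expect_true(all(diff(res$p_adj[ord]) >= -1e-12))
})

test_that("genes detected in no sample are excluded before testing", {
  wt <- matrix(c(10, 12, 9, 0, 0, 0), nrow = 2, byrow = TRUE)
  mut <- matrix(c(11, 10, 12, 0, 0, 0), nrow = 2, byrow = TRUE)
  res <- deg_test(make_rpkm_fixture(wt, mut), design_3v3)
  expect_equal(res$gene_id, "g001")
  expect_equal(attr(res, "summary")$n_excluded_undetected, 1)
})

test_that("deg_test validates its design contract", {
  wt <- matrix(rnorm(6, 10), nrow = 2)
  mut <- matrix(rnorm(6, 10), nrow = 2)
  rpkm <- make_rpkm_fixture(wt, mut)
  bad_design <- dplyr::mutate(design_3v3,
                              strain = c("a", "a", "a", "b", "c", "c"))
  expect_error(deg_test(rpkm, bad_design), "exactly two strains")
  expect_error(deg_test(rpkm, design_3v3, reference = "nope"),
               "not a strain label")
  two_rep <- dplyr::slice(design_3v3, c(1, 4))
  expect_error(
    deg_test(dplyr::filter(rpkm, sample_id %in% two_rep$sample_id),
             two_rep), "two replicates")
})

test_that("volcano autoplot builds from a deg result", {
  wt <- matrix(rnorm(30, 100, 5), ncol = 3)
  mut <- matrix(rnorm(30, 100, 5), ncol = 3)
  res <- deg_test(make_rpkm_fixture(wt, mut), design_3v3)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
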