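# Generators: determinism, truth labels, planted-signal construction.

test_that("count simulation is deterministic and labels planted truth", {
  spec <- count_sim_spec(n_genes = 200, n_up = 10, n_down = 5,
                         knockout_genes = c("g0003", "g0007"), seed = 42)
  a <- simulate_counts(spec)
  b <- simulate_counts(spec)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_true(all(a$counts$count >= 0))
  expect_equal(sum(a$truth$class == "up"), 10)
  expect_equal(sum(a$truth$class == "down"), 5)
  expect_setequal(a$truth$gene_id[a$truth$class == "knockout"],
                  c("g0003", "g0007"))

  # no planted effects -> truth table has zero DE labels
  null_spec <- count_sim_spec(n_genes = 50, seed = 1)
  null_sim <- simulate_counts(null_spec)
  expect_true(all(null_sim$truth$class == "ns"))
  expect_true(all(null_sim$truth$true_log2fc == 0))
})

test_that("knockout genes receive near-zero mutant counts", {
  spec <- count_sim_spec(n_genes = 100, knockout_genes = sprintf("g%04d", 1:20),
                         seed = 3)
  sim <- simulate_counts(spec)
  ko_mut <- dplyr::inner_join(
    sim$counts, sim$design, by = "sample_id") |>
    dplyr::filter(gene_id %in% spec$knockout_genes, strain == "mut")
  # Poisson(0.5) residual reads: mean at most ~1
  expect_lt(mean(ko_mut$count), 1)
  ko_wt <- dplyr::inner_join(sim$counts, sim$design, by = "sample_id") |>
    dplyr::filter(gene_id %in% spec$knockout_genes, strain == "wt")
  expect_gt(mean(ko_wt$count), 10)
})

test_that("overlap pair emits region counts whose naive totals double-count", {
  spec <- count_sim_spec(n_genes = 50, knockout_genes = "g0001",
                         overlap_pair = list(gene_a = "g0001",
                                             gene_b = "g0002",
                                             shared_fraction = 0.5),
                         seed = 11)
  sim <- simulate_counts(spec)
  rc <- sim$region_counts
  expect_equal(nrow(rc), 6)
  naive <- tidyr::pivot_wider(
    dplyr::filter(sim$counts, gene_id %in% c("g0001", "g0002")),
    names_from = gene_id, values_from = count)
  merged <- dplyr::inner_join(naive, rc, by = "sample_id")
  expect_equal(merged$g0001, merged$a_unique + merged$shared)
  expect_equal(merged$g0002, merged$b_unique + merged$shared)
  expect_equal(sim$annotation$overlap_partner[1], "g0002")
})

test_that("count spec validation rejects inconsistent settings", {
  expect_error(count_sim_spec(n_genes = 10, n_up = 8, n_down = 8),
               "exceeds")
  expect_error(count_sim_spec(overlap_pair = list(gene_a = "g0001",
                                                  gene_b = "g0001",
                                                  shared_fraction = 0.2)),
               "distinct")
  expect_error(count_sim_spec(overlap_pair = list(gene_a = "g0001",
                                                  gene_b = "g0002",
                                                  shared_fraction = 1.5)),
               "shared_fraction")
  expect_error(
    simulate_counts(count_sim_spec(n_genes = 10,
                                   knockout_genes = "g9999")),
    "unknown gene ids")
})

test_that("planted GO terms are strongly enriched by construction", {
  universe <- sprintf("g%04d", 1:500)
  de <- universe[1:60]
  spec <- go_sim_spec(
    n_terms = 20, term_size_range = c(5, 50),
    planted_enriched_terms = tibble::tibble(
      term_id = "T_planted", size = 40, de_overlap = 30),
    seed = 5)
  annot <- simulate_go_annotation(spec, universe, de)
  expect_identical(annot, simulate_go_annotation(spec, universe, de))
  planted_genes <- annot$gene_id[annot$term_id == "T_planted"]
  tails <- hyper_tail_oracle(N = 500, K = length(planted_genes),
                             n = length(de),
                             k = length(intersect(planted_genes, de)))
  expect_lt(tails$over, 1e-3)
})

test_that("a planted term equal to the DE set attains the minimal tail p", {
  universe <- sprintf("g%03d", 1:40)
  de <- universe[1:10]
  spec <- go_sim_spec(n_terms = 0,
                      planted_enriched_terms = tibble::tibble(
                        term_id = "T_de", size = 10, de_overlap = 10),
                      seed = 2)
  annot <- simulate_go_annotation(spec, universe, de)
  res <- enrich(annot, de, universe = universe)
  # full overlap is the most extreme configuration achievable
  expect_equal(res$k, 10)
  expect_equal(res$p_over, hyper_tail_oracle(40, 10, 10, 10)$over)
})

test_that("random annotation yields ~5% raw-significant terms under the null", {
  universe <- sprintf("g%04d", 1:400)
  de <- universe[1:50]
  fracs <- vapply(1:10, function(s) {
    annot <- simulate_go_annotation(
      go_sim_spec(n_terms = 60, term_size_range = c(10, 80), seed = s),
      universe, de)
    res <- suppressWarnings(enrich(annot, de, universe = universe))
    mean(pmin(res$p_over, res$p_under) < 0.05)
  }, numeric(1))
  # hypergeometric discreteness keeps the attained rate at or below nominal
  expect_lt(mean(fracs), 0.10)
  expect_gt(mean(fracs), 0.005)
})

test_that("PPI simulation emits a symmetric, bounded, blocked edge list", {
  spec <- ppi_sim_spec(n_proteins = 30, block_sizes = c(8, 8), seed = 9)
  edges <- simulate_ppi(spec)
  expect_identical(edges$score, simulate_ppi(spec)$score)
  expect_equal(nrow(edges), choose(30, 2))
  expect_true(all(edges$score >= 0 & edges$score <= 1))
  truth <- attr(edges, "truth")
  within <- dplyr::inner_join(
    dplyr::inner_join(edges, truth, by = c(protein_a = "protein_id")),
    truth, by = c(protein_b = "protein_id"))
  same <- !is.na(within$block.x) & !is.na(within$block.y) &
    within$block.x == within$block.y
  expect_gt(min(within$score[same]), max(within$score[!same]))
  expect_error(ppi_sim_spec(within_block_score_range = c(0.1, 0.3),
                            background_score_range = c(0.2, 0.5)),
               "strictly above")
  expect_error(ppi_sim_spec(n_proteins = 10, block_sizes = c(8, 8)),
               "exceeds")
})

test_that("histone simulation shifts the requested classes and modifications", {
  classes <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:300),
    class = rep(c("up", "down", "ns"), each = 100))
  mods <- histone_modifications()
  expect_length(mods, 8)
  spec <- histone_sim_spec(shift_up = 1, shift_down = -1,
                           shift_mods = mods[1:7], noise_sd = 0.1, seed = 4)
  ratios <- simulate_histone(spec, classes)
  expect_identical(ratios, simulate_histone(spec, classes))
  expect_equal(names(ratios), c("gene_id", mods))
  up_mean <- colMeans(ratios[classes$class == "up", mods])
  ns_mean <- colMeans(ratios[classes$class == "ns", mods])
  expect_true(all((up_mean - ns_mean)[mods[1:7]] > 0.5))
  expect_lt(abs((up_mean - ns_mean)[[mods[8]]]), 0.2)
  expect_error(
    simulate_histone(spec, tibble::tibble(gene_id = "g1", class = "weird")),
    "unknown gene class")
})
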