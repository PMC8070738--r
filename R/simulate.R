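# Synthetic-data generators.  Each generator is seeded, deterministic, and
# emits the truth labels its downstream stage is expected to recover.

#' Specification for a synthetic two-strain RNA-seq count experiment
#'
#' Describes a negative-binomial gene-count simulation comparing a wildtype
#' strain against a deletion mutant: a planted set of up-/downregulated
#' genes, knocked-out genes with near-zero mutant counts, and optionally one
#' pair of overlapping ORFs whose naive per-gene totals double-count the
#' shared region.
#'
#' @param n_genes Number of genes.
#' @param n_replicates_per_strain Biological replicates per strain (default
#'   3, i.e. six libraries in total).
#' @param baseline_mean_log_range Range (natural-log scale) from which
#'   per-gene baseline negative-binomial means are drawn uniformly.
#' @param dispersion Negative-binomial size parameter; larger means less
#'   overdispersion.
#' @param n_up,n_down Numbers of planted up-/downregulated genes.
#' @param effect_log2fc Absolute planted log2 fold change (mutant vs
#'   wildtype), applied with sign `+` for up and `-` for down genes.
#' @param knockout_genes Character vector of gene ids (of the form
#'   `"g0001"`) whose mutant-strain counts are drawn from a Poisson with
#'   mean 0.5 — a handful of stray reads rather than hard zeros.
#' @param overlap_pair Optional `list(gene_a =, gene_b =, shared_fraction =)`
#'   declaring one same-strand overlapping ORF pair; `shared_fraction` is
#'   the fraction of each gene's length lying in the shared region.
#' @param seed Integer seed.
#'
#' @return An object of class `count_sim_spec`.
#' @seealso [simulate_counts()]
#' @export
count_sim_spec <- function(n_genes = 6000,
                           n_replicates_per_strain = 3,
                           baseline_mean_log_range = c(log(20), log(2000)),
                           dispersion = 10,
                           n_up = 0, n_down = 0,
                           effect_log2fc = 2,
                           knockout_genes = character(),
                           overlap_pair = NULL,
                           seed = 1L) {
  n_genes <- assert_count(n_genes, "n_genes")
  n_rep <- assert_count(n_replicates_per_strain, "n_replicates_per_strain")
  assert_scalar_number(dispersion, "dispersion", min = 1e-8)
  n_up <- assert_count(n_up, "n_up", min = 0L)
  n_down <- assert_count(n_down, "n_down", min = 0L)
  assert_scalar_number(effect_log2fc, "effect_log2fc", min = 0)
  if (length(baseline_mean_log_range) != 2L ||
      diff(baseline_mean_log_range) < 0) {
    abort("`baseline_mean_log_range` must be an increasing pair")
  }
  if (n_up + n_down + length(knockout_genes) > n_genes) {
    abort("n_up + n_down + knockouts exceeds n_genes")
  }
  if (!is.null(overlap_pair)) {
    if (!all(c("gene_a", "gene_b", "shared_fraction") %in%
             names(overlap_pair))) {
      abort("`overlap_pair` needs gene_a, gene_b and shared_fraction")
    }
    assert_scalar_number(overlap_pair$shared_fraction, "shared_fraction",
                         min = 0, max = 1)
    if (identical(overlap_pair$gene_a, overlap_pair$gene_b)) {
      abort("overlap pair must name two distinct genes")
    }
  }
  structure(
    list(n_genes = n_genes, n_replicates_per_strain = n_rep,
         baseline_mean_log_range = baseline_mean_log_range,
         dispersion = dispersion, n_up = n_up, n_down = n_down,
         effect_log2fc = effect_log2fc,
         knockout_genes = as.character(knockout_genes),
         overlap_pair = overlap_pair, seed = as.integer(seed)),
    class = "count_sim_spec")
}

#' Simulate a two-strain gene-count experiment with planted truth
#'
#' Draws negative-binomial counts for `n_genes` genes in two strains
#' (`wt` and `mut`), plants up-/downregulated genes at the requested fold
#' change, forces knocked-out genes to near-zero mutant counts, and, when an
#' overlapping ORF pair is declared, emits region-level counts (A-unique,
#' B-unique, shared) alongside naive per-gene totals that double-count the
#' shared region, so the overlap correction has a well-defined input.
#'
#' @param spec A [count_sim_spec()].
#'
#' @return A list of class `count_sim` with elements `counts` (long tibble:
#'   `gene_id`, `sample_id`, `count`; for overlap-pair genes these are the
#'   naive totals), `annotation` (`gene_id`, `length_bp`, `chrom`,
#'   `overlap_partner`, `shared_bp`), `design` (`sample_id`, `strain`),
#'   `truth` (`gene_id`, `class`, `true_log2fc`) and `region_counts`
#'   (`gene_a`, `gene_b`, `sample_id`, `a_unique`, `b_unique`, `shared`,
#'   only for a declared pair).
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "count_sim_spec"))
  with_seed(child_seed(spec$seed, "counts"), {
    n <- spec$n_genes
    n_rep <- spec$n_replicates_per_strain
    gene_ids <- sprintf("g%04d", seq_len(n))
    samples <- c(sprintf("wt_%d", seq_len(n_rep)),
                 sprintf("mut_%d", seq_len(n_rep)))
    strain <- rep(c("wt", "mut"), each = n_rep)

    lengths <- round(runif(n, 400, 4000))
    base_mu <- exp(runif(n, spec$baseline_mean_log_range[1],
                         spec$baseline_mean_log_range[2]))

    class <- rep("ns", n)
    true_lfc <- rep(0, n)
    ko_idx <- match(spec$knockout_genes, gene_ids)
    if (anyNA(ko_idx)) abort("knockout_genes contains unknown gene ids")
    pair_idx <- integer(0)
    if (!is.null(spec$overlap_pair)) {
      pair_idx <- match(c(spec$overlap_pair$gene_a, spec$overlap_pair$gene_b),
                        gene_ids)
      if (anyNA(pair_idx)) abort("overlap pair names unknown gene ids")
    }
    # Plant DE genes outside the knockout and overlap-pair sets.
    free <- setdiff(seq_len(n), c(ko_idx, pair_idx))
    de_idx <- sample(free, spec$n_up + spec$n_down)
    up_idx <- head(de_idx, spec$n_up)
    down_idx <- setdiff(de_idx, up_idx)
    class[up_idx] <- "up"; true_lfc[up_idx] <- spec$effect_log2fc
    class[down_idx] <- "down"; true_lfc[down_idx] <- -spec$effect_log2fc
    class[ko_idx] <- "knockout"

    if (length(pair_idx) == 2L) {
      # the overlapped gene is ordinarily expressed (geometric centre of
      # the baseline range) and its partner strongly expressed (95th
      # percentile), so reads from the shared region dominate the
      # overlapped gene's naive totals — the masking the region-level
      # correction exists to undo
      rng <- spec$baseline_mean_log_range
      base_mu[pair_idx[1]] <- exp(mean(rng))
      base_mu[pair_idx[2]] <- exp(rng[1] + 0.95 * diff(rng))
    }
    mu_wt <- base_mu
    mu_mut <- base_mu * 2^true_lfc

    draw <- function(mu) {
      matrix(rnbinom(n * n_rep, mu = rep(mu, n_rep), size = spec$dispersion),
             nrow = n)
    }
    cnt <- cbind(draw(mu_wt), draw(mu_mut))
    if (length(ko_idx) > 0L) {
      # a handful of stray reads, not hard zeros
      cnt[ko_idx, n_rep + seq_len(n_rep)] <-
        rpois(length(ko_idx) * n_rep, 0.5)
    }

    annotation <- tibble(
      gene_id = gene_ids, length_bp = lengths,
      chrom = sprintf("chr%02d", 1L + (seq_len(n) %% 16L)),
      overlap_partner = NA_character_, shared_bp = NA_integer_)
    region_counts <- NULL

    if (length(pair_idx) == 2L) {
      f <- spec$overlap_pair$shared_fraction
      ia <- pair_idx[1]; ib <- pair_idx[2]
      mu_a <- c(rep(mu_wt[ia], n_rep), rep(mu_mut[ia], n_rep))
      mu_b <- c(rep(mu_wt[ib], n_rep), rep(mu_mut[ib], n_rep))
      if (ia %in% ko_idx) mu_a[n_rep + seq_len(n_rep)] <- 0.5
      if (ib %in% ko_idx) mu_b[n_rep + seq_len(n_rep)] <- 0.5
      a_unique <- rnbinom(2 * n_rep, mu = (1 - f) * mu_a,
                          size = spec$dispersion)
      b_unique <- rnbinom(2 * n_rep, mu = (1 - f) * mu_b,
                          size = spec$dispersion)
      shared <- rnbinom(2 * n_rep, mu = f * (mu_a + mu_b),
                        size = spec$dispersion)
      cnt[ia, ] <- a_unique + shared
      cnt[ib, ] <- b_unique + shared
      shared_bp <- as.integer(round(f * min(lengths[pair_idx])))
      annotation$overlap_partner[pair_idx] <- gene_ids[rev(pair_idx)]
      annotation$shared_bp[pair_idx] <- shared_bp
      region_counts <- tibble(
        gene_a = gene_ids[ia], gene_b = gene_ids[ib],
        sample_id = samples,
        a_unique = as.integer(a_unique),
        b_unique = as.integer(b_unique),
        shared = as.integer(shared))
    }

    counts <- tibble(
      gene_id = rep(gene_ids, times = 2 * n_rep),
      sample_id = rep(samples, each = n),
      count = as.integer(cnt))

    structure(
      list(counts = counts,
           annotation = annotation,
           design = tibble(sample_id = samples, strain = strain),
           truth = tibble(gene_id = gene_ids, class = class,
                          true_log2fc = true_lfc),
           region_counts = region_counts,
           spec = spec),
      class = "count_sim")
  })
}

#' Specification for a synthetic gene-ontology annotation table
#'
#' @param n_terms Number of random (non-planted) terms.
#' @param term_size_range Integer pair: term sizes drawn uniformly.
#' @param planted_enriched_terms Optional tibble/data frame with columns
#'   `term_id`, `size`, `de_overlap` — each planted term contains
#'   `de_overlap` genes drawn from the DE set and `size - de_overlap` from
#'   the remainder of the universe.
#' @param seed Integer seed.
#' @return An object of class `go_sim_spec`.
#' @export
go_sim_spec <- function(n_terms = 50,
                        term_size_range = c(10, 200),
                        planted_enriched_terms = NULL,
                        seed = 1L) {
  n_terms <- assert_count(n_terms, "n_terms", min = 0L)
  if (length(term_size_range) != 2L || diff(term_size_range) < 0) {
    abort("`term_size_range` must be an increasing pair")
  }
  if (!is.null(planted_enriched_terms)) {
    assert_cols(planted_enriched_terms, c("term_id", "size", "de_overlap"),
                "planted_enriched_terms")
    if (any(planted_enriched_terms$de_overlap >
            planted_enriched_terms$size)) {
      abort("planted de_overlap cannot exceed term size")
    }
  }
  structure(list(n_terms = n_terms, term_size_range = term_size_range,
                 planted_enriched_terms = planted_enriched_terms,
                 seed = as.integer(seed)),
            class = "go_sim_spec")
}

#' Simulate a flat gene-to-term annotation table
#'
#' Random terms are uniform draws from the universe; planted terms receive a
#' prescribed overlap with the differentially-expressed set, so that their
#' hypergeometric enrichment is strong by construction.
#'
#' @param spec A [go_sim_spec()].
#' @param universe Character vector of gene ids (nonempty).
#' @param de_set Character vector of DE gene ids (subset of `universe`);
#'   required only when planted terms are declared.
#' @return A tibble (`gene_id`, `term_id`), one row per annotation.
#' @export
simulate_go_annotation <- function(spec, universe, de_set = character()) {
  stopifnot(inherits(spec, "go_sim_spec"))
  if (length(universe) == 0L) abort("`universe` must be nonempty")
  if (!all(de_set %in% universe)) abort("`de_set` must be within `universe`")
  if (spec$n_terms > 0L &&
      max(spec$term_size_range) > length(universe)) {
    abort("term sizes exceed universe size")
  }
  with_seed(child_seed(spec$seed, "go"), {
    out <- list()
    if (spec$n_terms > 0L) {
      sizes <- round(runif(spec$n_terms, spec$term_size_range[1],
                           spec$term_size_range[2]))
      out <- purrr::map2(sprintf("T%04d", seq_len(spec$n_terms)), sizes,
                         function(id, k) {
                           tibble(gene_id = sample(universe, k), term_id = id)
                         })
    }
    if (!is.null(spec$planted_enriched_terms)) {
      pl <- spec$planted_enriched_terms
      if (any(pl$de_overlap > 0L) && length(de_set) == 0L) {
        abort("planted terms declared but `de_set` is empty")
      }
      non_de <- setdiff(universe, de_set)
      planted <- purrr::pmap(pl, function(term_id, size, de_overlap, ...) {
        genes <- c(sample(de_set, de_overlap),
                   sample(non_de, size - de_overlap))
        tibble(gene_id = genes, term_id = term_id)
      })
      out <- c(out, planted)
    }
    bind_rows(out)
  })
}

#' Specification for a synthetic protein-interaction score matrix
#'
#' @param n_proteins Number of proteins.
#' @param block_sizes Integer vector of planted cluster sizes (sum must not
#'   exceed `n_proteins`).
#' @param within_block_score_range Score range for within-block pairs,
#'   within `[0, 1]` and strictly above the background range so planted
#'   blocks are recoverable.
#' @param background_score_range Score range for all other pairs.
#' @param seed Integer seed.
#' @return An object of class `ppi_sim_spec`.
#' @export
ppi_sim_spec <- function(n_proteins = 60,
                         block_sizes = c(12, 12),
                         within_block_score_range = c(0.8, 0.95),
                         background_score_range = c(0, 0.15),
                         seed = 1L) {
  n_proteins <- assert_count(n_proteins, "n_proteins", min = 2L)
  if (sum(block_sizes) > n_proteins) {
    abort("sum(block_sizes) exceeds n_proteins")
  }
  for (r in list(within_block_score_range, background_score_range)) {
    if (length(r) != 2L || diff(r) < 0 || r[1] < 0 || r[2] > 1) {
      abort("score ranges must be increasing pairs within [0, 1]")
    }
  }
  if (within_block_score_range[1] <= background_score_range[2]) {
    abort("within-block scores must lie strictly above the background range")
  }
  structure(list(n_proteins = n_proteins,
                 block_sizes = as.integer(block_sizes),
                 within_block_score_range = within_block_score_range,
                 background_score_range = background_score_range,
                 seed = as.integer(seed)),
            class = "ppi_sim_spec")
}

#' Simulate a blocked protein-interaction score edge list
#'
#' @param spec A [ppi_sim_spec()].
#' @return A tibble (`protein_a`, `protein_b`, `score`) covering every
#'   unordered protein pair, with an attribute `truth` mapping each protein
#'   to its planted block (`NA` for background proteins).
#' @export
simulate_ppi <- function(spec) {
  stopifnot(inherits(spec, "ppi_sim_spec"))
  with_seed(child_seed(spec$seed, "ppi"), {
    n <- spec$n_proteins
    ids <- sprintf("P%04d", seq_len(n))
    block <- rep(NA_integer_, n)
    at <- 1L
    for (b in seq_along(spec$block_sizes)) {
      block[at:(at + spec$block_sizes[b] - 1L)] <- b
      at <- at + spec$block_sizes[b]
    }
    pairs <- combn(n, 2)
    same <- !is.na(block[pairs[1, ]]) & !is.na(block[pairs[2, ]]) &
      block[pairs[1, ]] == block[pairs[2, ]]
    score <- numeric(ncol(pairs))
    score[same] <- runif(sum(same), spec$within_block_score_range[1],
                         spec$within_block_score_range[2])
    score[!same] <- runif(sum(!same), spec$background_score_range[1],
                          spec$background_score_range[2])
    edges <- tibble(protein_a = ids[pairs[1, ]],
                    protein_b = ids[pairs[2, ]],
                    score = score)
    attr(edges, "truth") <- tibble(protein_id = ids, block = block)
    edges
  })
}

#' Specification for synthetic histone-modification ratio profiles
#'
#' Emulates a per-gene table of nucleosome co-immunoprecipitation ratios for
#' the canonical eight modifications (three acetylations, five
#' methylations), with location shifts applied to up-/downregulated genes.
#'
#' @param modifications Character vector of modification names (default the
#'   canonical eight).
#' @param shift_up,shift_down Location shifts (in ratio units) added to the
#'   profiles of up-/downregulated genes on `shift_mods`.
#' @param shift_mods Modifications receiving the shift (default: all).
#' @param baseline Baseline mean ratio for all genes.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return An object of class `histone_sim_spec`.
#' @export
histone_sim_spec <- function(modifications = histone_modifications(),
                             shift_up = 0, shift_down = 0,
                             shift_mods = modifications,
                             baseline = 1, noise_sd = 0.3,
                             seed = 1L) {
  if (length(modifications) == 0L || anyDuplicated(modifications)) {
    abort("`modifications` must be a nonempty set of distinct names")
  }
  if (!all(shift_mods %in% modifications)) {
    abort("`shift_mods` must be a subset of `modifications`")
  }
  assert_scalar_number(noise_sd, "noise_sd", min = 1e-12)
  structure(list(modifications = modifications, shift_up = shift_up,
                 shift_down = shift_down, shift_mods = shift_mods,
                 baseline = baseline, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "histone_sim_spec")
}

#' The canonical eight histone modifications
#'
#' Three acetylations and five methylations, as assayed in genome-wide
#' nucleosome immunoprecipitation datasets.
#' @return A character vector of length 8.
#' @export
histone_modifications <- function() {
  c("H3K9ac", "H3K14ac", "H4ac",
    "H3K4me1", "H3K4me2", "H3K4me3", "H3K36me3", "H3K79me3")
}

#' Simulate per-gene histone-modification ratios
#'
#' @param spec A [histone_sim_spec()].
#' @param gene_classes Tibble (`gene_id`, `class`) partitioning genes into
#'   `up`, `down` and `ns`.
#' @return A wide tibble: `gene_id` plus one column per modification.
#' @export
simulate_histone <- function(spec, gene_classes) {
  stopifnot(inherits(spec, "histone_sim_spec"))
  assert_cols(gene_classes, c("gene_id", "class"), "gene_classes")
  bad <- setdiff(unique(gene_classes$class), c("up", "down", "ns"))
  if (length(bad) > 0L) {
    abort(sprintf("unknown gene class(es): %s", paste(bad, collapse = ", ")))
  }
  with_seed(child_seed(spec$seed, "histone"), {
    n <- nrow(gene_classes)
    m <- length(spec$modifications)
    ratios <- matrix(rnorm(n * m, mean = spec$baseline, sd = spec$noise_sd),
                     nrow = n,
                     dimnames = list(NULL, spec$modifications))
    shift_cols <- spec$modifications %in% spec$shift_mods
    ratios[gene_classes$class == "up", shift_cols] <-
      ratios[gene_classes$class == "up", shift_cols] + spec$shift_up
    ratios[gene_classes$class == "down", shift_cols] <-
      ratios[gene_classes$class == "down", shift_cols] + spec$shift_down
    dplyr::bind_cols(tibble(gene_id = gene_classes$gene_id),
                     as_tibble(ratios))
  })
}
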