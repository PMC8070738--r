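# RPKM normalization, overlapping-ORF count correction, and the
# Levene-gated differential-expression caller.

#' Normalize gene counts to reads per kilobase per million mapped reads
#'
#' `rpkm[g, s] = count[g, s] * 1e9 / (length_bp[g] * total_counts[s])`.
#' Multiplying every count in a sample by a constant leaves that sample's
#' RPKM unchanged.
#'
#' @param counts Long tibble with columns `gene_id`, `sample_id`, `count`
#'   (non-negative).
#' @param annotation Tibble with columns `gene_id`, `length_bp` (> 0) for
#'   every gene present in `counts`.
#' @return A tibble (`gene_id`, `sample_id`, `rpkm`).
#' @examples
#' counts <- tibble::tibble(gene_id = "g1", sample_id = "s1", count = 10L)
#' annot <- tibble::tibble(gene_id = "g1", length_bp = 1000)
#' # with a single gene the library is 10 reads; RPKM = 10 * 1e9 / (1000 * 10)
#' rpkm_normalize(counts, annot)
#' @export
rpkm_normalize <- function(counts, annotation) {
  assert_cols(counts, c("gene_id", "sample_id", "count"), "counts")
  assert_cols(annotation, c("gene_id", "length_bp"), "annotation")
  if (any(counts$count < 0)) abort("counts must be non-negative")
  missing_len <- setdiff(unique(counts$gene_id), annotation$gene_id)
  if (length(missing_len) > 0L) {
    abort(sprintf("no gene length for: %s",
                  paste(head(missing_len, 5), collapse = ", ")))
  }
  if (any(annotation$length_bp <= 0)) abort("gene lengths must be positive")
  totals <- counts %>%
    group_by(.data$sample_id) %>%
    summarise(total = sum(.data$count), .groups = "drop")
  zero <- totals$sample_id[totals$total == 0]
  if (length(zero) > 0L) {
    abort(sprintf("zero library size in sample(s): %s",
                  paste(zero, collapse = ", ")))
  }
  counts %>%
    left_join(select(annotation, "gene_id", "length_bp"), by = "gene_id") %>%
    left_join(totals, by = "sample_id") %>%
    mutate(rpkm = .data$count * 1e9 / (.data$length_bp * .data$total)) %>%
    select("gene_id", "sample_id", "rpkm")
}

#' Correct counts of overlapping ORF pairs using region-level counts
#'
#' When two same-strand genes overlap, naive per-gene totals double-count
#' reads falling in the shared region, which can mask the true expression
#' state of either partner (an apparently expressed gene whose unique
#' region is silent).  Given region-level counts, the corrected count of
#' each partner is its unique-region count.
#'
#' @param counts Long tibble (`gene_id`, `sample_id`, `count`) of naive
#'   totals.
#' @param region_counts Tibble (`gene_a`, `gene_b`, `sample_id`,
#'   `a_unique`, `b_unique`, `shared`), one row per declared pair and
#'   sample.
#' @param annotation Optional annotation tibble with an `overlap_partner`
#'   column; if given, every declared pair must have region counts.
#' @return The corrected counts tibble, same shape as `counts`.
#' @export
subtract_overlap <- function(counts, region_counts, annotation = NULL) {
  assert_cols(counts, c("gene_id", "sample_id", "count"), "counts")
  assert_cols(region_counts,
              c("gene_a", "gene_b", "sample_id", "a_unique", "b_unique",
                "shared"), "region_counts")
  if (!is.null(annotation) && "overlap_partner" %in% names(annotation)) {
    declared <- annotation$gene_id[!is.na(annotation$overlap_partner)]
    covered <- unique(c(region_counts$gene_a, region_counts$gene_b))
    missing <- setdiff(declared, covered)
    if (length(missing) > 0L) {
      abort(sprintf("missing region counts for declared overlap gene(s): %s",
                    paste(missing, collapse = ", ")))
    }
  }
  corrected <- bind_rows(
    region_counts %>%
      select(gene_id = "gene_a", "sample_id", corrected = "a_unique"),
    region_counts %>%
      select(gene_id = "gene_b", "sample_id", corrected = "b_unique"))
  out <- counts %>%
    left_join(corrected, by = c("gene_id", "sample_id")) %>%
    mutate(count = ifelse(is.na(.data$corrected),
                          .data$count, .data$corrected)) %>%
    select("gene_id", "sample_id", "count")
  over <- out %>%
    left_join(counts, by = c("gene_id", "sample_id"),
              suffix = c("", "_naive")) %>%
    filter(.data$count > .data$count_naive)
  if (nrow(over) > 0L) {
    abort("region counts exceed naive totals; inconsistent input")
  }
  out
}

#' Call differentially expressed genes with a Levene-gated test switch
#'
#' For each gene, group variances are compared with a Brown-Forsythe
#' (median-centred Levene) test.  Genes judged homoscedastic are tested
#' with a one-way ANOVA; heteroscedastic genes with a Kruskal-Wallis test
#' (exact enumeration p-values on small tie-free samples, chi-square with
#' tie correction otherwise).  Raw p-values are corrected across all tested
#' genes and a gene is called differentially expressed when it passes both
#' the adjusted-p cutoff and the fold-change cutoff.
#'
#' Fold change is `log2(mean_mut / mean_wt)` computed from mean RPKM with a
#' small pseudo-count added to both means, so fully silenced genes get a
#' large finite negative value.  Genes with zero values in every sample are
#' excluded before testing; genes with zero variance in both groups and
#' equal means are reported as `untested`.
#'
#' @param rpkm Tibble (`gene_id`, `sample_id`, `rpkm`) as from
#'   [rpkm_normalize()].
#' @param design Tibble (`sample_id`, `strain`) with exactly two strains
#'   and at least two replicates each.
#' @param reference Strain label of the wildtype/denominator strain
#'   (default: `"wt"` when present, otherwise the first strain in sorted
#'   order).
#' @param alpha Adjusted-p cutoff for the DEG call.
#' @param fc_threshold Fold-change cutoff on the linear scale (default 2,
#'   i.e. `|log2fc| >= 1`).
#' @param correction `"bh"` (Benjamini-Hochberg, default) or `"holm"`.
#' @param levene_alpha Significance level of the homoscedasticity gate.
#' @param pseudocount Pseudo-count (RPKM units) added to both group means
#'   before the fold-change ratio.
#' @param log_transform If `TRUE` (default), tests act on
#'   `log2(rpkm + log_offset)`; the log transform stabilizes the
#'   mean-variance relationship of RPKM so that genuinely regulated genes
#'   are not shunted to the rank branch by variance heterogeneity alone.
#'   Fold change is computed from raw RPKM either way.
#' @param log_offset Offset (RPKM units) inside the log transform; larger
#'   than the fold-change pseudo-count so that a stray read or two in a
#'   silenced gene does not dominate the log-scale within-group variance.
#' @return A tibble of class `deg_result` with one row per retained gene:
#'   `gene_id`, `rpkm_mean_wt`, `rpkm_mean_mut`, `log2fc`, `test_used`
#'   (`anova`, `kruskal_wallis` or `none`), `p_raw`, `p_adj`, `deg_class`
#'   (`up`, `down`, `ns` or `untested`).  Use [glance()] for the summary
#'   counts.
#' @export
deg_test <- function(rpkm, design, reference = NULL,
                     alpha = 0.05, fc_threshold = 2,
                     correction = c("bh", "holm"),
                     levene_alpha = 0.05, pseudocount = 0.1,
                     log_transform = TRUE, log_offset = 1) {
  assert_cols(rpkm, c("gene_id", "sample_id", "rpkm"), "rpkm")
  assert_cols(design, c("sample_id", "strain"), "design")
  correction <- match.arg(correction)
  assert_scalar_number(alpha, "alpha", min = 0, max = 1)
  assert_scalar_number(fc_threshold, "fc_threshold", min = 1)

  strains <- sort(unique(design$strain))
  if (length(strains) != 2L) abort("design must contain exactly two strains")
  unknown <- setdiff(unique(rpkm$sample_id), design$sample_id)
  if (length(unknown) > 0L) {
    abort(sprintf("sample(s) not in design: %s",
                  paste(unknown, collapse = ", ")))
  }
  reference <- reference %||% (if ("wt" %in% strains) "wt" else strains[1])
  if (!reference %in% strains) abort("`reference` is not a strain label")
  other <- setdiff(strains, reference)

  wide <- rpkm %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "rpkm")
  x <- as.matrix(wide[, -1, drop = FALSE])
  rownames(x) <- wide$gene_id
  strain_of <- setNames(design$strain, design$sample_id)[colnames(x)]
  idx_ref <- which(strain_of == reference)
  idx_mut <- which(strain_of == other)
  if (length(idx_ref) < 2L || length(idx_mut) < 2L) {
    abort("each strain needs at least two replicates")
  }

  # genes detected in no sample are excluded before testing
  detected <- rowSums(x) > 0
  x <- x[detected, , drop = FALSE]

  mean_wt <- rowMeans(x[, idx_ref, drop = FALSE])
  mean_mut <- rowMeans(x[, idx_mut, drop = FALSE])
  log2fc <- log2((mean_mut + pseudocount) / (mean_wt + pseudocount))

  xt <- if (log_transform) log2(x + log_offset) else x

  p_lev <- row_levene_bf(xt, idx_ref, idx_mut)
  anv <- row_anova2(xt, idx_ref, idx_mut)
  kw <- row_kruskal2(xt, idx_ref, idx_mut)

  use_kw <- p_lev < levene_alpha
  p_raw <- ifelse(use_kw, kw$p, anv$p)
  test_used <- ifelse(use_kw, "kruskal_wallis", "anova")
  untested <- is.na(p_raw)
  test_used[untested] <- "none"

  p_adj <- rep(NA_real_, length(p_raw))
  adj_method <- if (correction == "bh") "BH" else "holm"
  p_adj[!untested] <- stats::p.adjust(p_raw[!untested], method = adj_method)

  deg_class <- rep("ns", length(p_raw))
  deg_class[untested] <- "untested"
  sig <- !untested & p_adj < alpha & abs(log2fc) >= log2(fc_threshold)
  deg_class[sig & log2fc > 0] <- "up"
  deg_class[sig & log2fc < 0] <- "down"

  out <- tibble(
    gene_id = rownames(x),
    rpkm_mean_wt = unname(mean_wt),
    rpkm_mean_mut = unname(mean_mut),
    log2fc = unname(log2fc),
    test_used = unname(test_used),
    p_raw = unname(p_raw),
    p_adj = unname(p_adj),
    deg_class = deg_class)

  new_result_tibble(
    out, "deg_result",
    summary = list(n_tested = sum(!untested),
                   n_up = sum(deg_class == "up"),
                   n_down = sum(deg_class == "down"),
                   n_ns = sum(deg_class == "ns"),
                   n_untested = sum(untested),
                   n_excluded_undetected = sum(!detected)),
    params = list(reference = reference, mutant = other, alpha = alpha,
                  fc_threshold = fc_threshold, correction = correction,
                  levene_alpha = levene_alpha, pseudocount = pseudocount,
                  log_transform = log_transform, log_offset = log_offset))
}

#' @method glance deg_result
#' @export
glance.deg_result <- function(x, ...) {
  s <- attr(x, "summary")
  tibble(n_tested = s$n_tested, n_up = s$n_up, n_down = s$n_down,
         n_ns = s$n_ns, n_untested = s$n_untested)
}

#' @method tidy deg_result
#' @export
tidy.deg_result <- function(x, ...) {
  as_tibble(x)
}

#' Volcano plot of a differential-expression result
#'
#' @param object A [deg_test()] result.
#' @param ... Unused.
#' @return A ggplot object: log2 fold change against -log10 adjusted p,
#'   colored by DEG class, with the fold-change and alpha cutoffs drawn.
#' @method autoplot deg_result
#' @export
autoplot.deg_result <- function(object, ...) {
  params <- attr(object, "params")
  df <- as_tibble(object) %>% filter(.data$deg_class != "untested")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(.data$p_adj),
                                   colour = .data$deg_class)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(params$fc_threshold),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(params$alpha),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(up = "#2c7fb8", down = "#d95f0e", ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change (mutant / wildtype)",
                  y = "-log10 adjusted p", colour = NULL)
}
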