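# Hypergeometric term enrichment against a quantified-gene universe.

#' Hypergeometric over/under-representation of annotation terms
#'
#' For each term with `K` genes in the universe of size `N`, and a query
#' set of size `n` overlapping the term in `k` genes, the over- and
#' under-representation tails are `p_over = P(X >= k)` and
#' `p_under = P(X <= k)` with `X ~ Hypergeometric(N, K, n)`.  The smaller
#' tail is adjusted for multiple testing across terms and a direction is
#' assigned when the adjusted value is significant.
#'
#' The annotation is treated as flat (no ontology-graph propagation); the
#' universe defaults to every annotated gene but should normally be set to
#' the quantified-gene set of the experiment.
#'
#' @param annotation Tibble (`gene_id`, `term_id`).
#' @param query Character vector of query gene ids (e.g. upregulated DEGs).
#'   Genes outside the universe are dropped with a warning.
#' @param universe Character vector of gene ids; defaults to all genes in
#'   `annotation`.
#' @param correction `"bh"` (default) or `"holm"`.
#' @param alpha Adjusted-p cutoff for the direction call.
#' @return A tibble of class `enrich_result`: `term_id`, `K` (term size in
#'   universe), `n` (query size), `k` (overlap), `p_over`, `p_under`,
#'   `p_adj`, `direction` (`enriched`, `depleted` or `ns`).
#' @export
enrich <- function(annotation, query, universe = NULL,
                   correction = c("bh", "holm"), alpha = 0.05) {
  assert_cols(annotation, c("gene_id", "term_id"), "annotation")
  correction <- match.arg(correction)
  universe <- unique(universe %||% annotation$gene_id)
  if (length(universe) == 0L) abort("empty universe")
  if (length(query) == 0L) abort("empty query set")
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    warn(sprintf("%d query gene(s) outside the universe were dropped",
                 length(outside)))
    query <- intersect(query, universe)
    if (length(query) == 0L) abort("no query genes inside the universe")
  }
  all_terms <- unique(annotation$term_id)
  annotation <- annotation %>%
    filter(.data$gene_id %in% universe) %>%
    distinct(.data$gene_id, .data$term_id)
  dropped <- setdiff(all_terms, unique(annotation$term_id))
  if (length(dropped) > 0L) {
    warn(sprintf("%d term(s) with no genes in the universe were dropped",
                 length(dropped)))
  }
  ann_split <- split(annotation$gene_id, annotation$term_id)
  if (length(ann_split) == 0L) {
    warn("no terms with genes in the universe")
  }
  nn <- length(query)
  big_n <- length(universe)
  res <- purrr::imap(ann_split, function(genes, term) {
    big_k <- length(genes)
    k <- length(intersect(genes, query))
    tibble(term_id = term, K = big_k, n = nn, k = k,
           p_over = phyper(k - 1, big_k, big_n - big_k, nn,
                           lower.tail = FALSE),
           p_under = phyper(k, big_k, big_n - big_k, nn))
  }) %>% bind_rows()
  p_min <- pmin(res$p_over, res$p_under)
  adj_method <- if (correction == "bh") "BH" else "holm"
  res$p_adj <- stats::p.adjust(pmin(1, p_min), method = adj_method)
  res$direction <- "ns"
  sig <- res$p_adj < alpha
  res$direction[sig & res$p_over <= res$p_under] <- "enriched"
  res$direction[sig & res$p_over > res$p_under] <- "depleted"
  res <- arrange(res, .data$p_adj)
  new_result_tibble(res, "enrich_result",
                    params = list(alpha = alpha, correction = correction,
                                  universe_size = big_n))
}

#' @method glance enrich_result
#' @export
glance.enrich_result <- function(x, ...) {
  tibble(n_terms = nrow(x),
         n_enriched = sum(x$direction == "enriched"),
         n_depleted = sum(x$direction == "depleted"),
         n_significant = sum(x$direction != "ns"))
}

#' @method tidy enrich_result
#' @export
tidy.enrich_result <- function(x, ...) as_tibble(x)

#' Bar plot of the most significant terms of an enrichment result
#'
#' @param object An [enrich()] result.
#' @param n_terms Number of top terms shown.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrich_result
#' @export
autoplot.enrich_result <- function(object, n_terms = 20, ...) {
  df <- as_tibble(object) %>%
    arrange(.data$p_adj) %>%
    head(n_terms) %>%
    mutate(term_id = factor(.data$term_id, levels = rev(.data$term_id)))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_adj),
                                   y = .data$term_id,
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(
      values = c(enriched = "#2c7fb8", depleted = "#d95f0e", ns = "grey60")) +
    ggplot2::labs(x = "-log10 adjusted p", y = NULL, fill = NULL)
}
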