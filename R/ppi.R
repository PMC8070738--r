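# Complete-linkage clustering of protein-interaction confidence scores.

#' Cluster a protein-interaction score matrix and apply retention rules
#'
#' Scores (confidence in a functional interaction, in `[0, 1]`) are turned
#' into distances `d = 1 - score`, clustered by agglomerative hierarchical
#' clustering with complete linkage, and the tree is cut at `cut_height`.
#' Each flat cluster is scored by the mean of all its within-cluster
#' pairwise scores (missing pairs count as 0) and retained when it has more
#' than `min_size` members and a mean score above `min_score`.
#'
#' Edge lists on the 0-1000 integer confidence scale are rescaled to
#' `[0, 1]` automatically when the maximum score exceeds 1.  Pairs absent
#' from the edge list are imputed as score 0.
#'
#' @param edges Tibble (`protein_a`, `protein_b`, `score`).  Duplicated
#'   pairs with conflicting scores are an error.
#' @param cut_height Distance at which the dendrogram is cut (default
#'   0.95).
#' @param min_size Retention rule: cluster size must exceed this (default
#'   10, strictly).
#' @param min_score Retention rule: mean within-cluster score must exceed
#'   this (default 0.4).
#' @return A tibble of class `ppi_clusters`, one row per flat cluster:
#'   `cluster`, `size`, `mean_score`, `retained`.  The membership table is
#'   available via [tidy()] and the `hclust` tree via
#'   `attr(x, "hclust")`.
#' @export
ppi_cluster <- function(edges, cut_height = 0.95,
                        min_size = 10, min_score = 0.4) {
  sm <- ppi_score_matrix(edges)
  if (nrow(sm) < 2L) abort("need at least two proteins")
  assert_scalar_number(cut_height, "cut_height", min = 0, max = 2)
  d <- stats::as.dist(1 - sm)
  hc <- stats::hclust(d, method = "complete")
  membership <- stats::cutree(hc, h = cut_height)
  ids <- rownames(sm)
  per_cluster <- purrr::map(sort(unique(membership)), function(cl) {
    members <- ids[membership == cl]
    ms <- if (length(members) >= 2L) {
      sub <- sm[members, members]
      mean(sub[upper.tri(sub)])
    } else {
      NA_real_
    }
    tibble(cluster = cl, size = length(members), mean_score = ms)
  }) %>% bind_rows()
  per_cluster <- per_cluster %>%
    mutate(retained = .data$size > min_size &
             !is.na(.data$mean_score) & .data$mean_score > min_score)
  new_result_tibble(
    per_cluster, "ppi_clusters",
    membership = tibble(protein_id = ids, cluster = unname(membership)),
    hclust = hc,
    params = list(cut_height = cut_height, min_size = min_size,
                  min_score = min_score))
}

# Build the symmetric [0, 1] score matrix from an edge list; missing pairs
# are 0, the diagonal is a placeholder (self-scores are ignored).
ppi_score_matrix <- function(edges) {
  assert_cols(edges, c("protein_a", "protein_b", "score"), "edges")
  if (any(is.na(edges$score))) abort("scores must not be missing")
  edges <- edges %>% filter(.data$protein_a != .data$protein_b)
  if (nrow(edges) == 0L) {
    abort("need at least two proteins with a scored pair")
  }
  if (max(edges$score) > 1) {
    # STRING-style 0-1000 integer confidence scale
    edges$score <- edges$score / 1000
  }
  if (any(edges$score < 0 | edges$score > 1)) {
    abort("scores must lie in [0, 1] (or the 0-1000 integer scale)")
  }
  key <- ifelse(edges$protein_a < edges$protein_b,
                paste(edges$protein_a, edges$protein_b),
                paste(edges$protein_b, edges$protein_a))
  dup <- duplicated(key)
  if (any(dup)) {
    first <- match(key[dup], key)
    if (any(abs(edges$score[dup] - edges$score[first]) > 1e-12)) {
      abort("conflicting duplicate scores for the same pair (asymmetry)")
    }
    edges <- edges[!dup, ]
  }
  ids <- sort(unique(c(edges$protein_a, edges$protein_b)))
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  ia <- match(edges$protein_a, ids)
  ib <- match(edges$protein_b, ids)
  m[cbind(ia, ib)] <- edges$score
  m[cbind(ib, ia)] <- edges$score
  diag(m) <- 1
  m
}

#' @method glance ppi_clusters
#' @export
glance.ppi_clusters <- function(x, ...) {
  tibble(n_clusters = nrow(x),
         n_retained = sum(x$retained),
         largest = max(x$size),
         mean_retained_score = mean(x$mean_score[x$retained]))
}

#' @method tidy ppi_clusters
#' @export
tidy.ppi_clusters <- function(x, ...) {
  attr(x, "membership") %>%
    left_join(as_tibble(x), by = "cluster")
}

#' Size against mean score for PPI clusters, with retention thresholds
#'
#' @param object A [ppi_cluster()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ppi_clusters
#' @export
autoplot.ppi_clusters <- function(object, ...) {
  params <- attr(object, "params")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$size, y = .data$mean_score,
                               colour = .data$retained)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = params$min_size, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = params$min_score, linetype = "dashed") +
    ggplot2::labs(x = "cluster size", y = "mean within-cluster score",
                  colour = "retained")
}
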