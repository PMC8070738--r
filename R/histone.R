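# Histone-modification enrichment of regulated gene sets.

#' Test histone-modification enrichment of up/down gene sets
#'
#' For each modification and each regulated class (`up`, `down`), the
#' per-gene ratios of the class are compared to those of the
#' non-significant (`ns`) genes with a Kruskal-Wallis rank test (with two
#' groups this is equivalent to a Wilcoxon rank-sum test).  Fold
#' enrichment is the ratio of class mean to `ns` mean.  P-values are
#' corrected with Benjamini-Hochberg across all class-by-modification
#' tests.
#'
#' @param ratios Wide tibble: `gene_id` plus one numeric column per
#'   modification.  Missing ratios are dropped per modification, not per
#'   gene.
#' @param gene_classes Tibble (`gene_id`, `class`) with classes `up`,
#'   `down`, `ns`; the `ns` reference class must be nonempty.
#' @param alpha Adjusted-p cutoff for the enrichment call.
#' @param modifications Modification columns to test (default: every
#'   column of `ratios` except `gene_id`).
#' @return A tibble of class `histone_enrichment`: `gene_class`,
#'   `modification`, `n_class`, `n_ns`, `mean_ratio_class`,
#'   `mean_ratio_ns`, `fold_enrichment`, `p_raw`, `p_adj`, `call`
#'   (`enriched`, `depleted` or `ns`).  [glance()] gives the per-class
#'   enriched/depleted counts (the "x of 8" summary).
#' @export
histone_enrich <- function(ratios, gene_classes, alpha = 0.05,
                           modifications = NULL) {
  assert_cols(ratios, "gene_id", "ratios")
  assert_cols(gene_classes, c("gene_id", "class"), "gene_classes")
  modifications <- modifications %||% setdiff(names(ratios), "gene_id")
  missing_mod <- setdiff(modifications, names(ratios))
  if (length(missing_mod) > 0L) {
    abort(sprintf("modification column(s) absent: %s",
                  paste(missing_mod, collapse = ", ")))
  }
  bad <- setdiff(unique(gene_classes$class), c("up", "down", "ns"))
  if (length(bad) > 0L) {
    abort(sprintf("unknown gene class(es): %s", paste(bad, collapse = ", ")))
  }
  if (!any(gene_classes$class == "ns")) {
    abort("the `ns` reference class is empty")
  }
  long <- ratios %>%
    select(dplyr::all_of(c("gene_id", modifications))) %>%
    tidyr::pivot_longer(-"gene_id", names_to = "modification",
                        values_to = "ratio") %>%
    dplyr::inner_join(gene_classes, by = "gene_id") %>%
    filter(!is.na(.data$ratio))

  classes_present <- intersect(c("up", "down"), unique(long$class))
  grid <- tidyr::expand_grid(gene_class = classes_present,
                             modification = modifications)
  res <- purrr::pmap(grid, function(gene_class, modification) {
    v_class <- long$ratio[long$class == gene_class &
                            long$modification == modification]
    v_ns <- long$ratio[long$class == "ns" &
                         long$modification == modification]
    m_class <- mean(v_class); m_ns <- mean(v_ns)
    p <- if (length(v_class) >= 2L && length(v_ns) >= 2L &&
             (sd(c(v_class, v_ns)) > 0)) {
      kruskal.test(list(v_class, v_ns))$p.value
    } else if (length(v_class) >= 1L && length(v_ns) >= 1L &&
               isTRUE(sd(c(v_class, v_ns)) == 0)) {
      1
    } else {
      NA_real_
    }
    tibble(gene_class = gene_class, modification = modification,
           n_class = length(v_class), n_ns = length(v_ns),
           mean_ratio_class = m_class, mean_ratio_ns = m_ns,
           fold_enrichment = m_class / m_ns, p_raw = p)
  }) %>% bind_rows()

  res$p_adj <- stats::p.adjust(res$p_raw, method = "BH")
  res$call <- "ns"
  sig <- !is.na(res$p_adj) & res$p_adj < alpha
  res$call[sig & res$fold_enrichment > 1] <- "enriched"
  res$call[sig & res$fold_enrichment < 1] <- "depleted"
  new_result_tibble(res, "histone_enrichment",
                    params = list(alpha = alpha,
                                  modifications = modifications))
}

#' @method glance histone_enrichment
#' @export
glance.histone_enrichment <- function(x, ...) {
  as_tibble(x) %>%
    group_by(.data$gene_class) %>%
    summarise(n_modifications = n(),
              n_enriched = sum(.data$call == "enriched"),
              n_depleted = sum(.data$call == "depleted"),
              .groups = "drop")
}

#' @method tidy histone_enrichment
#' @export
tidy.histone_enrichment <- function(x, ...) as_tibble(x)

#' Fold-enrichment bars per modification and gene class
#'
#' @param object A [histone_enrich()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot histone_enrichment
#' @export
autoplot.histone_enrichment <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$modification,
                               y = .data$fold_enrichment,
                               fill = .data$call)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$gene_class)) +
    ggplot2::scale_fill_manual(
      values = c(enriched = "#2c7fb8", depleted = "#d95f0e", ns = "grey60")) +
    ggplot2::labs(x = NULL, y = "fold enrichment vs ns genes", fill = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
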