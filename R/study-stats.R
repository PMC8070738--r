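# Metabolite-comparison and sensory statistics: control normalization,
# Kruskal-Wallis omnibus with rank-based LSD post hoc, two-way ANOVA with
# Tukey HSD, the triangular-test binomial law, and Wilcoxon descriptor
# comparisons.

#' Normalize measurements by the mean of a control group
#'
#' Divides every value by the mean of the control group's values, so the
#' control group's relative mean is 1.  With a `by` grouping (e.g. per
#' compound), normalization is done within each group.
#'
#' @param data A data frame.
#' @param value Name of the numeric value column.
#' @param group Name of the grouping column containing `control`.
#' @param control Label of the control level.
#' @param by Optional character vector of columns (e.g. `"compound"`)
#'   within which to normalize separately.
#' @return The input tibble with an added `relative` column.
#' @export
normalize_by_control <- function(data, value = "value", group = "strain",
                                 control, by = NULL) {
  assert_cols(data, c(value, group, by), "data")
  if (!control %in% data[[group]]) {
    abort(sprintf("control level '%s' absent from `%s`", control, group))
  }
  data <- as_tibble(data)
  data <- if (is.null(by)) mutate(data, .grp = "all") else
    mutate(data, .grp = do.call(paste, data[by]))
  ctrl_means <- data %>%
    filter(.data[[group]] == control) %>%
    group_by(.data$.grp) %>%
    summarise(.ctrl_mean = mean(.data[[value]]), .groups = "drop")
  bad <- ctrl_means$.grp[ctrl_means$.ctrl_mean == 0 |
                           is.na(ctrl_means$.ctrl_mean)]
  if (length(bad) > 0L) {
    abort(sprintf("zero or missing control mean for: %s",
                  paste(bad, collapse = ", ")))
  }
  missing_grp <- setdiff(unique(data$.grp), ctrl_means$.grp)
  if (length(missing_grp) > 0L) {
    abort(sprintf("no control replicates for: %s",
                  paste(missing_grp, collapse = ", ")))
  }
  data %>%
    left_join(ctrl_means, by = ".grp") %>%
    mutate(relative = .data[[value]] / .data$.ctrl_mean) %>%
    select(-".grp", -".ctrl_mean")
}

#' Kruskal-Wallis omnibus with rank-based LSD comparisons to a control
#'
#' An omnibus Kruskal-Wallis test across all groups, followed by pairwise
#' Fisher-LSD-style comparisons of mean ranks against the control group:
#' the difference of mean ranks is referred to a t distribution with
#' `N - k` degrees of freedom using the rank variance deflated by the
#' omnibus statistic, and p-values are corrected with Benjamini-Hochberg
#' across comparisons.
#'
#' @param data A data frame.
#' @param value,group Column names of the numeric values and group labels.
#' @param control Label of the control group.
#' @param alpha Significance level for the flags (default 0.01).
#' @return A tibble of class `kw_lsd`, one row per non-control group:
#'   `group`, `n`, `mean_rank`, `rank_diff` (vs control), `p_raw`,
#'   `p_adj`, `significant`.  The omnibus test is in
#'   `attr(x, "omnibus")` and in [glance()].
#' @export
kw_lsd <- function(data, value = "value", group = "strain", control,
                   alpha = 0.01) {
  assert_cols(data, c(value, group), "data")
  v <- data[[value]]
  g <- as.character(data[[group]])
  if (!control %in% g) abort(sprintf("control '%s' not found", control))
  groups <- unique(g)
  if (length(groups) < 2L) abort("need at least two groups")
  sizes <- table(g)
  if (any(sizes < 2L)) abort("every group needs at least two replicates")

  if (sd(v) == 0) {
    # degenerate: constant data carry no ordering information
    omnibus <- list(statistic = 0, p_value = 1)
    h <- 0
  } else {
    kt <- kruskal.test(v, factor(g))
    omnibus <- list(statistic = unname(kt$statistic),
                    p_value = kt$p.value)
    h <- unname(kt$statistic)
  }
  n_tot <- length(v)
  k <- length(groups)
  r <- rank(v)
  mean_ranks <- tapply(r, g, mean)
  s2 <- var(r)
  others <- setdiff(groups, control)
  res <- purrr::map(others, function(gr) {
    diff <- mean_ranks[[gr]] - mean_ranks[[control]]
    se2 <- s2 * ((n_tot - 1 - h) / (n_tot - k)) *
      (1 / sizes[[gr]] + 1 / sizes[[control]])
    tstat <- if (se2 > 0) diff / sqrt(se2) else 0
    p <- if (se2 > 0) 2 * pt(abs(tstat), df = n_tot - k,
                             lower.tail = FALSE) else 1
    tibble(group = gr, n = as.integer(sizes[[gr]]),
           mean_rank = mean_ranks[[gr]], rank_diff = diff, p_raw = p)
  }) %>% bind_rows()
  res$p_adj <- stats::p.adjust(res$p_raw, method = "BH")
  res$significant <- res$p_adj < alpha & omnibus$p_value < alpha
  new_result_tibble(res, "kw_lsd", omnibus = omnibus,
                    params = list(control = control, alpha = alpha))
}

#' @method glance kw_lsd
#' @export
glance.kw_lsd <- function(x, ...) {
  om <- attr(x, "omnibus")
  tibble(statistic = om$statistic, p_value = om$p_value,
         n_groups_flagged = sum(x$significant))
}

#' @method tidy kw_lsd
#' @export
tidy.kw_lsd <- function(x, ...) as_tibble(x)

#' Two-way ANOVA (strain x must) with Tukey HSD post hoc
#'
#' Fits `value ~ strain * must` and tests the two main effects and their
#' interaction; Tukey honest-significant-difference comparisons are
#' computed for each significant effect.
#'
#' @param data A data frame.
#' @param value,strain,must Column names.
#' @param alpha Per-effect significance level (default 0.001).
#' @return A tibble of class `anova2_hsd`, one row per effect: `term`,
#'   `df`, `sumsq`, `meansq`, `statistic`, `p_value`, `significant`
#'   (all-`NA` statistics on constant data are reported with
#'   `significant = NA`, i.e. untestable).  HSD tables for significant
#'   effects are in `attr(x, "hsd")`.
#' @export
anova2_hsd <- function(data, value = "value", strain = "strain",
                       must = "must", alpha = 0.001) {
  assert_cols(data, c(value, strain, must), "data")
  df <- tibble(value = data[[value]],
               strain = factor(data[[strain]]),
               must = factor(data[[must]]))
  if (nlevels(df$strain) < 2L || nlevels(df$must) < 2L) {
    abort("both factors need at least two levels")
  }
  cells <- table(df$strain, df$must)
  if (any(cells == 0L)) {
    abort("empty strain x must cell(s) with interaction requested")
  }
  fit <- aov(value ~ strain * must, data = df)
  an <- summary(fit)[[1]]
  terms <- trimws(rownames(an))
  res <- tibble(term = terms, df = an$Df, sumsq = an$`Sum Sq`,
                meansq = an$`Mean Sq`,
                statistic = an$`F value`, p_value = an$`Pr(>F)`) %>%
    filter(.data$term != "Residuals")
  resid_ms <- an$`Mean Sq`[terms == "Residuals"]
  if (sd(df$value) == 0 || !is.finite(resid_ms) ||
      all(is.na(res$statistic))) {
    res$significant <- NA
    return(new_result_tibble(res, "anova2_hsd", hsd = list(),
                             params = list(alpha = alpha),
                             note = "untestable: no variance"))
  }
  res$significant <- !is.na(res$p_value) & res$p_value < alpha
  hsd <- list()
  which_hsd <- intersect(res$term[res$significant],
                         c("strain", "must", "strain:must"))
  if (length(which_hsd) > 0L) {
    th <- TukeyHSD(fit, which = which_hsd)
    hsd <- purrr::map(th, function(m) {
      as_tibble(m, rownames = "comparison") %>%
        rename(diff = "diff", lwr = "lwr", upr = "upr",
               p_adj = "p adj")
    })
  }
  new_result_tibble(res, "anova2_hsd", hsd = hsd,
                    params = list(alpha = alpha), note = NULL)
}

#' @method glance anova2_hsd
#' @export
glance.anova2_hsd <- function(x, ...) {
  tibble(n_effects = nrow(x),
         n_significant = sum(x$significant, na.rm = TRUE),
         untestable = all(is.na(x$significant)))
}

#' @method tidy anova2_hsd
#' @export
tidy.anova2_hsd <- function(x, ...) as_tibble(x)

#' Exact one-sided binomial probability for triangular discrimination tests
#'
#' In a triangular (forced-choice among three, two identical) sensory
#' test the probability of a correct answer by chance is 1/3.  The
#' p-value is the exact upper tail `P(X >= n_correct)` for
#' `X ~ Binomial(n_trials, 1/3)`, computed by direct summation.
#'
#' @param n_correct Number of correct identifications (vectorized).
#' @param n_trials Number of trials (judges times presentations).
#' @return A tibble: `n_trials`, `n_correct`, `prop_correct`, `p_value`.
#' @export
triangular_test <- function(n_correct, n_trials) {
  if (any(n_correct < 0) || any(n_trials < 1) ||
      any(n_correct > n_trials)) {
    abort("need 0 <= n_correct <= n_trials")
  }
  p <- purrr::map2_dbl(n_correct, n_trials, function(k, n) {
    sum(dbinom(seq(k, n), n, 1 / 3))
  })
  tibble(n_trials = as.integer(n_trials),
         n_correct = as.integer(n_correct),
         prop_correct = n_correct / n_trials, p_value = p)
}

#' Per-descriptor Wilcoxon comparison of two wines
#'
#' For each aroma descriptor, the intensity ratings of the two wines are
#' compared with a Wilcoxon test — paired signed-rank by default (each
#' judge rated both wines; zero differences are dropped, the standard
#' convention), or unpaired rank-sum with `paired = FALSE`.  Exact
#' p-values are used for small samples without ties.
#'
#' @param data Data frame with columns `judge`, `wine`, `descriptor`,
#'   `intensity` (names configurable).
#' @param judge,wine,descriptor,intensity Column names.
#' @param alpha Significance level (default 0.05).
#' @param paired Paired signed-rank (default) or unpaired rank-sum.
#' @return A tibble of class `descriptor_wilcoxon`: `descriptor`, `n`,
#'   `statistic`, `p_value`, `significant`.  Descriptors with identical
#'   ratings throughout (all differences zero) are reported with
#'   `p_value = 1` and `significant = FALSE`.
#' @export
descriptor_wilcoxon <- function(data, judge = "judge", wine = "wine",
                                descriptor = "descriptor",
                                intensity = "intensity",
                                alpha = 0.05, paired = TRUE) {
  assert_cols(data, c(judge, wine, descriptor, intensity), "data")
  wines <- unique(data[[wine]])
  if (length(wines) != 2L) abort("need exactly two wines")
  res <- purrr::map(unique(data[[descriptor]]), function(d) {
    sub <- data[data[[descriptor]] == d, ]
    x <- sub[sub[[wine]] == wines[1], ]
    y <- sub[sub[[wine]] == wines[2], ]
    if (paired) {
      jx <- x[[judge]]; jy <- y[[judge]]
      if (!setequal(jx, jy) || anyDuplicated(jx) || anyDuplicated(jy)) {
        abort(sprintf("paired mode: judge sets differ for '%s'", d))
      }
      xv <- x[[intensity]][order(jx)]
      yv <- y[[intensity]][order(jy)]
      n_eff <- sum(xv != yv)
      if (n_eff == 0L) {
        return(tibble(descriptor = d, n = length(xv), statistic = NA_real_,
                      p_value = 1, significant = FALSE))
      }
      wt <- suppressWarnings(wilcox.test(xv, yv, paired = TRUE))
    } else {
      wt <- suppressWarnings(wilcox.test(x[[intensity]], y[[intensity]]))
      n_eff <- nrow(x) + nrow(y)
    }
    tibble(descriptor = d, n = if (paired) length(x[[intensity]]) else n_eff,
           statistic = unname(wt$statistic), p_value = wt$p.value,
           significant = wt$p.value < alpha)
  }) %>% bind_rows()
  new_result_tibble(res, "descriptor_wilcoxon",
                    params = list(alpha = alpha, paired = paired,
                                  wines = wines))
}

#' @method tidy descriptor_wilcoxon
#' @export
tidy.descriptor_wilcoxon <- function(x, ...) as_tibble(x)

#' @method glance descriptor_wilcoxon
#' @export
glance.descriptor_wilcoxon <- function(x, ...) {
  tibble(n_descriptors = nrow(x), n_significant = sum(x$significant))
}
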