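# Multi-locus meiotic segregation: analytic expectations, seeded
# simulation with genotype-dependent spore viability, and the chi-square
# deficit test for double-deletion carrier frequencies.

#' Describe a diploid genotype over unlinked deletion loci
#'
#' @param x Either a named character vector (`c(ATF1 = "wt/del", ...)`) or
#'   a tibble with columns `locus` and `state`; states must be one of
#'   `"wt/wt"`, `"wt/del"`, `"del/del"`.  Loci are modeled as unlinked
#'   (located on different chromosomes), so spores segregate
#'   independently across loci.
#' @return A tibble of class `diploid_genotype` (`locus`, `state`,
#'   `p_del`: the probability that a spore carries the deletion —
#'   1, 1/2 or 0).
#' @examples
#' # heterozygous at five esterase loci: a fully deleted spore is 1/32
#' g <- diploid_genotype(c(ATF1 = "wt/del", ATF2 = "wt/del",
#'                         EEB1 = "wt/del", EHT1 = "wt/del",
#'                         MGL2 = "wt/del"))
#' expected_spore_frequency(g, g$locus)
#' @export
diploid_genotype <- function(x) {
  if (is.character(x) && !is.null(names(x))) {
    x <- tibble(locus = names(x), state = unname(x))
  }
  assert_cols(x, c("locus", "state"), "x")
  if (nrow(x) < 1L) abort("a genotype needs at least one locus")
  if (anyDuplicated(x$locus)) abort("duplicate locus")
  bad <- setdiff(unique(x$state), c("wt/wt", "wt/del", "del/del"))
  if (length(bad) > 0L) {
    abort(sprintf("unknown allele state(s): %s", paste(bad, collapse = ", ")))
  }
  out <- tibble(locus = x$locus, state = x$state,
                p_del = unname(c("wt/wt" = 0, "wt/del" = 0.5,
                                 "del/del" = 1)[x$state]))
  class(out) <- c("diploid_genotype", class(out))
  out
}

#' Expected frequency of spores deleted at a required set of loci
#'
#' Product over the required loci of the per-locus probability that a
#' spore carries the deletion (1 for `del/del`, 1/2 for `wt/del`, 0 for
#' `wt/wt`), assuming independent segregation of unlinked loci.
#'
#' @param genotype A [diploid_genotype()].
#' @param required_deleted Character vector of loci that must all be
#'   deleted in the spore.
#' @return A single probability.
#' @export
expected_spore_frequency <- function(genotype, required_deleted) {
  stopifnot(inherits(genotype, "diploid_genotype"))
  unknown <- setdiff(required_deleted, genotype$locus)
  if (length(unknown) > 0L) {
    abort(sprintf("unknown locus: %s", paste(unknown, collapse = ", ")))
  }
  prod(genotype$p_del[match(required_deleted, genotype$locus)])
}

#' Expected double-deletion carrier frequency for every locus pair
#'
#' @param genotype A [diploid_genotype()] with at least two loci.
#' @return A tibble (`locus_a`, `locus_b`, `expected_freq`), one row per
#'   unordered pair, with `expected_freq` the product of the two
#'   single-locus carrier probabilities.
#' @export
pair_frequencies <- function(genotype) {
  stopifnot(inherits(genotype, "diploid_genotype"))
  if (nrow(genotype) < 2L) abort("need at least two loci")
  pairs <- combn(nrow(genotype), 2)
  tibble(locus_a = genotype$locus[pairs[1, ]],
         locus_b = genotype$locus[pairs[2, ]],
         expected_freq = genotype$p_del[pairs[1, ]] *
           genotype$p_del[pairs[2, ]])
}

#' Define a genotype-dependent spore viability model
#'
#' Each rule names a set of loci and a survival probability; a spore
#' matches a rule when it carries the deletion at every locus of the rule.
#' Rules are checked in order and the first match wins; spores matching no
#' rule survive with `default_survival`.
#'
#' @param rules A list of `list(loci = <character>, survival = <prob>)`
#'   entries.
#' @param default_survival Survival probability for spores matching no
#'   rule (default 1).
#' @return An object of class `viability_model`.
#' @examples
#' # quintuple-deletion lethality
#' viability_model(list(list(loci = c("ATF1", "ATF2", "EEB1", "EHT1",
#'                                    "MGL2"), survival = 0)))
#' @export
viability_model <- function(rules = list(), default_survival = 1) {
  assert_scalar_number(default_survival, "default_survival", 0, 1)
  for (r in rules) {
    if (!is.list(r) || !all(c("loci", "survival") %in% names(r))) {
      abort("each rule must be list(loci =, survival =)")
    }
    assert_scalar_number(r$survival, "survival", 0, 1)
    if (length(r$loci) == 0L) abort("a rule must name at least one locus")
  }
  structure(list(rules = rules, default_survival = default_survival),
            class = "viability_model")
}

#' Simulate meiotic spores from a diploid with genotype-dependent viability
#'
#' In `tetrad` mode every heterozygous locus segregates exactly 2:2 within
#' each four-spore tetrad, independently across loci; in `random_spore`
#' mode each spore's genotype is drawn independently.  Viability is then
#' applied per spore via the [viability_model()]; germination rate and
#' carrier statistics are computed on the viable spores.
#'
#' @param genotype A [diploid_genotype()].
#' @param n_tetrads Number of tetrads dissected (4 spores each).
#' @param model A [viability_model()] (default: every spore survives).
#' @param mode `"tetrad"` or `"random_spore"`.
#' @param seed Optional integer seed.
#' @return A list of class `spore_sample`: `n_dissected`, `n_viable`,
#'   `germination_rate`, `haplotypes` (one row per distinct haplotype of
#'   the viable spores, logical deletion columns per locus plus `n` and
#'   `freq`), `deletion_counts` (viable spores by number of deleted loci)
#'   and `pair_carriers` (`locus_a`, `locus_b`, `carriers`, `freq`,
#'   `expected_freq`).
#' @export
simulate_spores <- function(genotype, n_tetrads, model = viability_model(),
                            mode = c("tetrad", "random_spore"),
                            seed = NULL) {
  stopifnot(inherits(genotype, "diploid_genotype"),
            inherits(model, "viability_model"))
  mode <- match.arg(mode)
  n_tetrads <- assert_count(n_tetrads, "n_tetrads")
  n_spores <- 4L * n_tetrads
  loci <- genotype$locus
  with_seed(if (is.null(seed)) NULL else child_seed(seed, "meiosis"), {
    del <- matrix(FALSE, n_spores, length(loci),
                  dimnames = list(NULL, loci))
    two_of_four <- combn(4L, 2L)
    for (j in seq_along(loci)) {
      p <- genotype$p_del[j]
      if (p == 1) {
        del[, j] <- TRUE
      } else if (p == 0.5) {
        if (mode == "tetrad") {
          # exactly 2 of the 4 spores of each tetrad carry the deletion
          pick <- sample.int(6L, n_tetrads, replace = TRUE)
          offsets <- two_of_four[, pick]
          rows <- as.vector(offsets) + rep((seq_len(n_tetrads) - 1L) * 4L,
                                           each = 2L)
          del[rows, j] <- TRUE
        } else {
          del[, j] <- runif(n_spores) < 0.5
        }
      }
    }
    survival <- rep(model$default_survival, n_spores)
    assigned <- rep(FALSE, n_spores)
    for (r in model$rules) {
      unknown <- setdiff(r$loci, loci)
      if (length(unknown) > 0L) {
        abort(sprintf("viability rule names unknown locus: %s",
                      paste(unknown, collapse = ", ")))
      }
      hit <- rowSums(del[, r$loci, drop = FALSE]) == length(r$loci)
      survival[hit & !assigned] <- r$survival
      assigned <- assigned | hit
    }
    viable <- runif(n_spores) < survival

    vdel <- del[viable, , drop = FALSE]
    hap <- as_tibble(vdel) %>%
      count(dplyr::across(dplyr::everything()), name = "n") %>%
      mutate(freq = .data$n / sum(.data$n))
    dc <- tibble(n_deleted = rowSums(vdel)) %>%
      count(.data$n_deleted, name = "n")
    pf <- if (nrow(genotype) >= 2L) {
      pair_frequencies(genotype)
    } else {
      tibble(locus_a = character(), locus_b = character(),
             expected_freq = numeric())
    }
    carriers <- purrr::map2_int(pf$locus_a, pf$locus_b, function(a, b) {
      sum(vdel[, a] & vdel[, b])
    })
    structure(
      list(n_dissected = n_spores,
           n_viable = sum(viable),
           germination_rate = sum(viable) / n_spores,
           haplotypes = hap,
           deletion_counts = dc,
           pair_carriers = pf %>%
             mutate(carriers = carriers,
                    freq = carriers / sum(viable)) %>%
             select("locus_a", "locus_b", "carriers", "freq",
                    expected_freq = "expected_freq"),
           mode = mode,
           del = del,
           viable = viable),
      class = "spore_sample")
  })
}

#' @method glance spore_sample
#' @export
glance.spore_sample <- function(x, ...) {
  tibble(n_dissected = x$n_dissected, n_viable = x$n_viable,
         germination_rate = x$germination_rate, mode = x$mode)
}

#' @method tidy spore_sample
#' @export
tidy.spore_sample <- function(x, ...) x$haplotypes

#' @export
print.spore_sample <- function(x, ...) {
  cat(sprintf(
    "spore sample (%s mode): %d dissected, %d viable (germination %.1f%%)\n",
    x$mode, x$n_dissected, x$n_viable, 100 * x$germination_rate))
  print(x$pair_carriers)
  invisible(x)
}

#' Chi-square deficit test for double-deletion carriers
#'
#' For each locus pair, the observed number of viable spores carrying both
#' deletions is compared to the expected carrier frequency with a 1-df
#' goodness-of-fit test on the carrier/non-carrier split.  A depleted pair
#' (observed far below expected) signals a deleterious genetic
#' interaction between the two deletions.
#'
#' When the expected frequency is exactly 0 or 1 while the opposite count
#' is nonzero, the chi-square statistic is undefined; an exact binomial
#' test is used instead and flagged in the `exact` column.
#'
#' @param observed Tibble (`locus_a`, `locus_b`, `carriers`) of observed
#'   double-deletion carrier counts among viable spores (e.g.
#'   `x$pair_carriers` from [simulate_spores()]).
#' @param n_viable Number of viable spores genotyped.
#' @param expected_freqs Tibble (`locus_a`, `locus_b`, `expected_freq`)
#'   as from [pair_frequencies()].
#' @return A tibble: per pair, `carriers`, `expected_carriers`,
#'   `statistic`, `p_value`, `deficit` (observed below expected) and
#'   `exact`.
#' @export
chi_square_pair_deficit <- function(observed, n_viable, expected_freqs) {
  assert_cols(observed, c("locus_a", "locus_b", "carriers"), "observed")
  assert_cols(expected_freqs, c("locus_a", "locus_b", "expected_freq"),
              "expected_freqs")
  n_viable <- assert_count(n_viable, "n_viable")
  df <- observed %>%
    left_join(expected_freqs, by = c("locus_a", "locus_b"))
  if (anyNA(df$expected_freq)) {
    abort("expected frequency missing for some pair")
  }
  res <- purrr::pmap(df, function(locus_a, locus_b, carriers,
                                  expected_freq, ...) {
    o <- c(carriers, n_viable - carriers)
    e <- n_viable * c(expected_freq, 1 - expected_freq)
    if (any(e == 0)) {
      mismatched <- o[e == 0]
      if (all(mismatched == 0)) {
        stat <- 0; p <- 1; exact <- FALSE
      } else {
        stat <- NA_real_
        p <- stats::binom.test(carriers, n_viable,
                               p = expected_freq)$p.value
        exact <- TRUE
      }
    } else {
      stat <- sum((o - e)^2 / e)
      p <- pchisq(stat, df = 1, lower.tail = FALSE)
      exact <- FALSE
    }
    tibble(locus_a = locus_a, locus_b = locus_b,
           carriers = carriers, expected_carriers = e[1],
           statistic = stat, p_value = p,
           deficit = carriers < e[1], exact = exact)
  }) %>% bind_rows()
  res
}
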