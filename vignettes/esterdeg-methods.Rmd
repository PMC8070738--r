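---
title: "Methods: differential expression and meiotic genetics of esterase-gene deletions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential expression and meiotic genetics of esterase-gene deletions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esterdeg)
library(dplyr)
```

# Scope

`esterdeg` implements the computational analysis used in functional-genetics
studies of wine-yeast esterase deletions, where a multiply deleted strain
(for the alcohol acetyl transferases Atf1p/Atf2p, the ethanol
acyl transferases Eeb1p/Eht1p, and the monoacylglycerol lipase Mgl2p) is
compared to its isogenic parent at three levels:

1. **Transcriptome** — RPKM-normalized gene counts, correction of
   overlapping ORFs, differential-expression calling with a Levene-gated
   parametric/rank test switch, then GO hypergeometric enrichment,
   clustering of the protein–protein-interaction (PPI) confidence-score
   matrix, and histone-modification enrichment of the regulated gene sets.
2. **Meiotic genetics** — analytic segregation expectations for
   multi-locus heterozygous diploids, seeded spore simulation with
   genotype-dependent viability, and a chi-square deficit test for
   double-deletion carriers (the signature of a deleterious interaction
   such as the one between *ATF1* and *MGL2* deletions).
3. **Metabolites and sensory data** — control normalization,
   Kruskal–Wallis with a rank-based LSD post hoc, two-way ANOVA with
   Tukey HSD, the exact triangular-test binomial law, and Wilcoxon
   descriptor comparisons.

A seeded synthetic-data generator produces every input with the
statistical structure each stage assumes, so the whole pipeline is
testable offline; real data in the same tabular formats drop in directly.

# The differential-expression model

## Normalization

Counts are normalized to reads per kilobase per million mapped reads:

$$\mathrm{RPKM}_{gs} = \frac{c_{gs} \cdot 10^9}{L_g \, N_s},$$

with $c_{gs}$ the read count of gene $g$ in sample $s$, $L_g$ the gene
length in bp and $N_s$ the library size. RPKM is scale-invariant per
sample, which the tests verify directly.

## Overlapping ORFs

When two same-strand genes overlap, reads from the shared span are
counted for both, and a silenced gene can appear expressed purely through
its partner's reads. Given region-level counts (A-unique, B-unique,
shared), `subtract_overlap()` replaces each partner's naive total by its
unique-region count. The generator emits both the region-level truth and
the double-counting naive totals, so the correction is testable: in the
bundled scenario the masked knockout is called `ns` before correction and
`down` after it.

## The Levene-gated test switch

Per gene, group variances are first compared with a Brown–Forsythe test
(Levene's test with median centring; the median-centred variant is robust
to the heavy tails of count-derived data). Genes judged homoscedastic at
`levene_alpha = 0.05` are tested with a one-way ANOVA, the rest with a
Kruskal–Wallis rank test. Raw p-values are corrected by
Benjamini–Hochberg (Holm–Bonferroni is available via `correction =
"holm"`, since both conventions circulate for the enrichment step), and a
gene is a DEG when `p_adj < alpha` **and** the fold change exceeds
`fc_threshold` (default twofold).

Two numerical decisions matter here:

* **Test scale.** Tests act on `log2(RPKM + 1)` by default. On the raw
  RPKM scale the standard deviation of an overdispersed count grows
  with its mean, so a genuine fold change *itself* produces
  heteroscedasticity and strong effects would be shunted to the rank
  branch — where a 3v3 comparison can never reach significance (below).
  The log transform stabilizes the mean–variance coupling so the gate
  measures distributional misbehaviour, not effect size. Fold changes
  are always computed from raw mean RPKM with a pseudo-count of 0.1 on
  both means, giving silenced genes a large, finite negative `log2fc`.
  `log_transform = FALSE` restores raw-scale testing.
* **Exact small-sample Kruskal–Wallis.** For tie-free samples of total
  size at most 10, the Kruskal–Wallis p-value is computed by exhaustive
  enumeration of rank assignments (the exact conditional null); the
  chi-square approximation with tie correction is used otherwise. With
  three replicates per strain there are $\binom{6}{3} = 20$ assignments
  and the smallest attainable p-value is $2/20 = 0.1$: a heteroscedastic
  gene cannot be declared differentially expressed from 3v3 replicates
  by the rank branch alone. This is a real property of the design, not a
  software limitation, and the calibration tests account for it.

Genes with zero counts in every sample are excluded before testing
(mirroring the "commonly detected genes" universe); genes with zero
variance and equal means in both groups are reported as `untested`.

# Enrichment stages

## GO hypergeometric tests

For a term with $K$ genes in a universe of $N$ quantified genes and a
query of $n$ DEGs overlapping it in $k$,
$p_\mathrm{over} = P(X \ge k)$ and $p_\mathrm{under} = P(X \le k)$ for
$X \sim \mathrm{Hypergeometric}(N, K, n)$, computed exactly. The smaller
tail is corrected across terms and the direction (enriched/depleted)
assigned when significant. The annotation is flat — no ontology-graph
propagation — matching analyses that consume a gene-association file
directly. The test suite checks every $(N \le 15, K, n, k)$ configuration
against full enumeration of the hypergeometric mass function.

## PPI score clustering

Confidence scores $s \in [0,1]$ (0–1000 integer scores are rescaled)
become distances $d = 1 - s$, the minimal monotone transform for a
bounded similarity. Agglomerative clustering with **complete linkage**
follows the field's convention for score matrices; the dendrogram is cut
at an explicit `cut_height` (default 0.95) rather than "visually", so
results are reproducible. Flat clusters are scored by the mean of all
within-cluster pairwise scores and retained when size > 10 **and** mean
score > 0.4 — the boundary is strict, so a 10-member cluster is reported
but never retained. Merge heights are validated against a brute-force
complete-linkage oracle on small matrices.

## Histone-modification enrichment

For each of the canonical eight modifications (H3K9ac, H3K14ac, H4ac,
H3K4me1/2/3, H3K36me3, H3K79me3) and each regulated class, the per-gene
ratios are compared to the non-significant genes with a Kruskal–Wallis
test (two groups: equivalent to a rank-sum test, kept as KW for fidelity
to the upstream convention). Benjamini–Hochberg runs across all
16 class-by-modification tests — the widest defensible family. Fold
enrichment is the ratio of class means; `glance()` reports the
"$x$ of 8 enriched" summary.

# Meiotic genetics

Loci are modeled as unlinked (the deletions sit on different
chromosomes). A spore inherits a deletion with probability 1, 1/2 or 0
for `del/del`, `wt/del`, `wt/wt` parents, independently across loci, so
the expected frequency of a spore deleted at a required locus set is the
product of the per-locus probabilities: 1/32 for a five-locus
heterozygote, 1/8 when two of the five loci are already homozygous
deleted. `simulate_spores()` offers two modes:

* **tetrad** — each heterozygous locus segregates exactly 2:2 within
  each four-spore tetrad (first-division fidelity), independently across
  loci;
* **random_spore** — each spore drawn independently.

Both have identical marginal haplotype distributions; the tetrad mode
additionally satisfies the 2:2 invariant exactly, which the tests check.
Viability is applied per spore through an ordered rule list
(`viability_model()`): the first rule whose locus set is fully deleted in
the spore determines its survival probability. A uniform-survival draw is
made for every spore regardless of rules, so a model whose rules all say
"survive" reproduces the neutral model exactly under the same seed.
Viability acts at germination (spores), matching how inviable progeny are
observed in tetrad dissection; prezygotic incompatibility is a property
of a cross, not of a spore, and is out of scope for the spore simulator.

The deficit test frames each locus pair as a carrier/non-carrier
goodness-of-fit against the product-rule expectation (1 df). When the
expected frequency is degenerate (0 or 1) with discordant observations,
an exact binomial test is substituted and flagged.

# Metabolite and sensory statistics

* `normalize_by_control()` divides by the control-strain mean, per
  compound; it is idempotent on normalized data.
* `kw_lsd()` runs the omnibus Kruskal–Wallis test, then compares each
  group's mean rank to the control with the LSD-style statistic
  $t = (\bar R_i - \bar R_c)\big/\sqrt{S^2\tfrac{N-1-H}{N-k}
  (\tfrac1{n_i}+\tfrac1{n_c})}$ on $N - k$ df, BH-corrected; flags
  require the omnibus test to be significant too (the "protected" LSD).
  Constant data yield an omnibus p of 1 by convention.
* `anova2_hsd()` fits `value ~ strain * must` and reports per-effect F
  tests (default `alpha = 0.001`) with Tukey HSD intervals for
  significant effects; all-constant responses are reported untestable
  rather than significant. Balanced-design sums of squares are verified
  against an explicit arithmetic decomposition in the tests.
* `triangular_test()` is the exact one-sided binomial tail at chance
  1/3 — one-sided because the forced-choice discrimination alternative
  is directional.
* `descriptor_wilcoxon()` defaults to the paired signed-rank test (each
  judge rates both wines) with exact small-sample p-values; zero
  differences are dropped (the standard convention), and a descriptor
  with all-zero differences is reported `p = 1`, not significant.
  `paired = FALSE` gives the rank-sum variant.

# The synthetic-data generator

`simulate_counts()` draws negative-binomial counts — the standard
overdispersed RNA-seq model — parameterized by mean and size
(`dispersion`), with per-gene baselines log-uniform over a configurable
range (default 20–2000 expected reads, spanning ordinary yeast
expression), two strains with a configurable number of replicates
(default 3, i.e. six libraries), planted up/down genes at a fixed
`log2fc`, knockouts whose mutant counts are Poisson(0.5) ("a few stray
reads", not hard zeros), and optionally one overlapping ORF pair emitted
as region-level counts plus double-counting naive totals. The overlapped
gene's baseline is pinned to the geometric centre of the range and its
partner to the 95th percentile: the masking phenomenon requires the
partner's shared-region reads to dominate the overlapped gene's naive
totals, which a random draw does not guarantee.

`simulate_go_annotation()` plants terms with a prescribed DE-set overlap
(random terms otherwise); `simulate_ppi()` builds blocked score matrices
with within-block scores strictly above background; `simulate_histone()`
shifts the ratio distributions of regulated genes on a chosen subset of
modifications. Every generator expands one global seed into a
per-generator child seed by fixed offsets, so a single integer reproduces
a whole run, and each generator is byte-identical under a fixed seed.

What the generator does **not** emulate: read-level errors and mapping
ambiguity, GC/length biases inside a gene, correlated gene programs
(counts are independent across genes given their means), a realistic GO
DAG, and score noise structured like a real interaction database.
Passing the bundled scenario therefore demonstrates that the *pipeline
logic* recovers planted structure under its stated assumptions — not
that those assumptions hold for any particular real dataset.

# Problem sizes and calibration

The bundled end-to-end scenario uses 2000 genes, 3 replicates per
strain, NB size 50 ("low dispersion": coefficient of variation about
15 %), 120 up / 15 down planted genes at |log2fc| = 2 (the strong
up-bias seen in esterase-deletion mutants), four knockouts, one
overlapping pair with half its length shared, PPI blocks of 12, 12 and
10 proteins among 70, and a +0.3 ratio shift on seven of the eight
histone modifications. Calibration repeats null simulations over 50
seeds: the raw p < 0.05 fraction stays near 5 % and the median DEG count
is 0, while planted effects are recovered with recall above 0.9 and
direction accuracy 1. These sizes keep a complete run near half a minute
while leaving all rates well-estimated.

# Known limitations

* With three replicates per strain the rank branch cannot reach
  p < 0.1, so heteroscedastic genes are effectively only testable
  parametrically at this design size; more replicates relax this.
* BH correction is applied within each analysis family independently;
  cross-stage error control is not attempted.
* The PPI stage consumes precomputed confidence scores; it does not
  query an interaction database.
* `pair_frequencies()` reports all unordered locus pairs of one diploid;
  pooling conventions across several hybrids (e.g. counting distinct
  pairs across two crosses) are left to the caller.

# A worked example

```{r example}
run <- run_pipeline(pipeline_config(seed = 1))
run
glance(run$deg)
glance(run$histone)

g <- diploid_genotype(c(ATF1 = "wt/del", ATF2 = "wt/del",
                        EEB1 = "wt/del", EHT1 = "wt/del",
                        MGL2 = "wt/del"))
expected_spore_frequency(g, g$locus)
spores <- simulate_spores(g, n_tetrads = 2000, seed = 1)
glance(spores)
chi_square_pair_deficit(spores$pair_carriers, spores$n_viable,
                        pair_frequencies(g))
```
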