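---
title: "Threshold-free enrichment landscapes: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-free enrichment landscapes: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goscape)
```

## Motivation

Over-representation analysis of Gene Ontology terms conventionally
starts from a hard differential-expression (DE) cutoff — adjusted
p ≤ 0.05 and fold change > 1.5 is the classic rule — and tests each
term against the resulting list. With the small replicate numbers
typical of in-vivo transcriptomics (three biological replicates per
group), that cutoff is close to arbitrary: the ordering of genes by
evidence is informative long before any gene clears a
multiple-testing threshold. goscape therefore treats the cutoff
itself as the swept variable. Every term is scored along the whole
significance range, and the analyst sees *where* each biological
process peaks rather than whether it survived one particular list.

## The enrichment model

Let the universe be the `N` genes present in both the ranked DE table
and the annotation (annotation-restricted background). For a term
with `K` member genes in the universe and the top-`n` genes of the
ranking, the overlap `k` is referred to the hypergeometric
distribution, and the term's p-value at step `n` is the exact
one-sided over-representation tail `P(X >= k)`,
`X ~ Hypergeometric(N, K, n)`. One-sided over-representation is the
standard choice when the question is which processes are enriched
among regulated genes; depletion is not scored.

The step grid is rank-based: multiples of `step_size` (default 25
genes) up to the last universe gene with raw p ≤ `max_alpha`
(default 0.5), that endpoint always included. Rank steps remain
well-defined under tied p-values, where a p-value grid would not be;
sweeping beyond p = 0.5 would only add selections dominated by
noise. Both parameters are configurable, as is a restriction of the
sweep to up- or down-regulated genes (`direction`), useful when the
biology of interest has a known sign — the motivating application
was a down-regulated proteoglycan.

Within each step, p-values are Benjamini–Hochberg adjusted **across
terms** (column-wise in the term × step matrix). A term's summary
score is its minimum adjusted p over the sweep together with the
smallest step attaining it and the enrichment fold `(k/n)/(K/N)`
there. The minimum over steps is *not* further adjusted across steps
— the steps are strongly dependent (nested selections), a
Bonferroni-type correction across them would be severely
conservative, and no exact null distribution of the minimum is
available without permutation. The score is therefore labelled
exploratory in all outputs and is meant for ranking terms, not for
error-rate statements. The per-step adjusted values, which do carry
the usual BH interpretation, are retained in the landscape matrix
and its TSV export.

Terms with fewer than `min_term_size` genes in the universe
(default 3) are excluded: their tails take so few values that a
single gene flips them between extremes.

### Reading the output

`select_top_terms()` orders terms by best adjusted p (ties: smaller
step, then term id). `gene_representation()` counts, for each gene,
how many selected terms contain it — the genes that recur across the
peak processes. The heatmap cell for gene *g* and term *t* is
`-log10` of *t*'s best adjusted p where *g* is annotated to *t*, and
0 otherwise, so each gene is displayed at the maximum significance
level its processes reach. An alternative cell definition (the step
index at which the peak occurs) was considered and rejected as the
default because it mixes units across columns; the landscape TSV
retains the full matrix for readers who want it.

## The DE stage

The count-based DE stage is deliberately simple and fully
replaceable. Size factors are plain median-of-ratios: for sample *j*,
the median over zero-free genes of `K_gj / geomean_g`. (The
log-space variant, which takes a geometric rather than arithmetic
mean of the two middle ratios at even gene counts, differs in the
fourth decimal; the arithmetic median is used here.) The log2 fold
change is the log-ratio of treated to control means of normalized
counts, with a 0.5 pseudocount added to both means only when one of
them is zero, so exact ratios are preserved for positive data. The
p-value is Welch's two-sample t on `log2(normalized + 1)`, computed
vectorised over genes. BH adjustment is applied over all tested
genes, with no independent filtering.

This stage stands in for a negative-binomial GLM: it ranks genes
well but is underpowered relative to NB inference at n = 3 + 3.
Two consequences are documented rather than hidden:

* **Null calibration.** Welch's test is conservative at three
  observations per group: under *ideal* normal data the fraction of
  raw p < 0.05 is ≈ 0.034, not 0.05, because the Welch–Satterthwaite
  degrees of freedom are themselves estimated from two-observation
  variances. The pipeline's null simulations reproduce exactly this
  rate (≈ 0.034), i.e. the count layer adds essentially no further
  distortion. The test is valid (never anti-conservative), which is
  what the test suite asserts.
* **Hard selection has little power.** At 3 + 3 replicates and
  dispersion 0.1, a 2.64-fold effect almost never reaches
  padj ≤ 0.05 among 2,000 genes, even though it typically ranks in
  the top decile by raw p. This is precisely the regime the
  threshold-free sweep addresses, and the simulated benchmark shows
  it: the planted terms are recovered perfectly by the landscape
  while the fixed-threshold list is usually empty.

Because real studies will prefer a dedicated NB fit, every
downstream stage accepts an external DE table (`read_de_table()`,
or `--de-table` on the command line) with the same columns.

## The synthetic-data generator

The generator emulates a two-group whole-retina experiment:
two groups of `n_samples_per_group = 3` biological replicates,
gene-level integer counts
`K_gj ~ NB(mu = s_j * q_g * 2^(beta_g * x_j), var = mu + phi mu^2)`.
Defaults, chosen once as realistic study conditions:

| parameter | default | rationale |
|---|---|---|
| `n_genes` | 2000 | desk-scale stand-in for an expressed transcriptome |
| `baseline_mean_log_range` | log10 in [1, 4] | expressed genes, mean counts 10–10,000 |
| `dispersion` (phi) | 0.1 | typical bulk RNA-seq biological dispersion |
| `n_de_genes` | 150 | 7.5% regulated genes |
| `de_log2fc_magnitude` | 1.5 | clearly regulated but not caricatural (2.8-fold) |
| `focal_gene_factor` | 2.64 | the decorin-like planted effect, down in treated |
| `n_terms`, `term_size_range` | 200, [10, 30] | GO-slim-like term granularity |
| `n_planted_terms`, `planted_overlap_fraction` | 5, 0.8 | strongly enriched processes |
| size factors `s_j` | log2-uniform [−0.2, 0.2] | library-size variation that makes normalization necessary but benign |

The focal gene is planted *down* in the treated group
(`beta = −log2(2.64) ≈ −1.40`); other DE genes get ±1.5 with random
sign. For every planted term, at least
`ceiling(0.8 × size)` members are DE, the remaining DE budget is
spread over random genes. One global seed expands into fixed
per-stage child seeds (`seed * 1009 + {101, 211, 307} mod 2^31−1`
for annotation, truth and counts), so each stage is reproducible in
isolation and identical configurations are bit-identical end to end.

What the generator does **not** emulate: GC/length biases, batch
effects, gene–gene correlation, the GO DAG (terms are independent
uniform gene sets; no parent-term propagation), and read-level
artefacts. Passing the planted-recovery benchmarks therefore shows
the machinery is correct and well-calibrated on clean NB data, not
that it is robust to every artefact of real libraries.

## Numerical and degenerate-input choices

* Hypergeometric tails use the log-space upper-tail of `phyper`;
  `k = 0` returns exactly 1. Tails match full-support enumeration to
  1e−12 over all configurations with N ≤ 12.
* Welch with zero variance in both groups (constant counts): p is 1
  when the group means are equal and 0 otherwise; a t-scale does not
  exist there, and these are the limits of the test as variances
  shrink.
* Ranking is total and deterministic: raw p, then larger |log2fc|,
  then lexicographic gene id.
* BH inputs outside [0, 1] and inconsistent contingency counts are
  domain errors, not silent clamps.
* An empty annotation, an empty universe, or no term of at least
  `min_term_size` genes abort the landscape with typed errors.
* If no gene is zero-free, median-of-ratios normalization is
  infeasible and the DE stage refuses to guess.

## Problem sizes used in the test suite

The suite exercises the study conditions at desk scale: 50
simulations for the fold-change recovery benchmark (2,000 genes each),
20 for planted-term recovery, 50 null simulations for calibration and
per-step false-discovery-proportion checks, and exhaustive oracle
enumerations for the hypergeometric (N ≤ 12) and BH (1,000 random
vectors) primitives. The full suite runs in well under a minute on a
single CPU.

## Known limitations

* The best-over-steps term score has no closed-form error-rate
  guarantee; treat it as a ranking device (a permutation null would
  be the natural extension).
* The Welch stand-in ranks but does not power-match NB inference;
  for publication-grade DE lists, import a DESeq2/edgeR table.
* Annotation is flat: a gene set per term, no ontology structure,
  no evidence-code weighting.
* Two groups only; no covariates, pairing or multi-factor designs.
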