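---
title: "Methods: circulating miRNA signatures and interactome disease modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circulating miRNA signatures and interactome disease modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind each pipeline stage, the
default parameters and why they were chosen, what the synthetic-data generator
does and does not emulate, and the numerical decisions that are not forced by
the methods themselves.

## Data model

The unit of data is a `ct_matrix`: a features × samples matrix of qPCR
quantification cycles (Cq), a per-cell nondetect mask, an optional
instrument QC-failure mask (taken from the platform, never recomputed), and
per-sample metadata (`group`, `vitd`, `arm`). Cq is a log2-like scale where
one cycle less means roughly twice the template abundance, so all
fold-change arithmetic uses `FC = 2^(mean Cq_control − mean Cq_case)` and
differential testing operates on the negated matrix (higher = more
abundant).

## Quality control

1. **Detection filter.** Cells with Cq ≥ 30 (default `ct_threshold`) or a
   raised instrument QC flag are masked as nondetects. The ≥ convention
   means a reading exactly at the cutoff is not trusted. The filter is
   idempotent and never alters retained values.
2. **Haemolysis assessment.** ΔCq = mean Cq(miR-23a) − mean Cq(miR-451a)
   per sample, replicate wells averaged after name normalization.
   ΔCq > 5 flags possible haemolysis, > 7 high risk; both are excluded.
   A nondetected reference makes the sample `indeterminate` (reported, not
   excluded): an unmeasurable score is not evidence of haemolysis.
3. **Missingness filter.** Features nondetected in strictly more than 20%
   of the remaining samples are dropped (strict inequality: exactly 20% is
   acceptable by convention).
4. **Quantile normalization.** Computed on detected cells only. The
   reference distribution is the mean order statistic across samples;
   samples with unequal detected counts are mapped through interpolation of
   the reference at their own quantile grid. Masked cells keep their
   (meaningless) stored values and stay masked.

The order — normalize, then impute — was an open choice. Normalizing first
means imputation operates on samples already on a common scale, so the
low-rank model does not have to spend components on per-sample shifts; the
cost is that the reference distribution is estimated from incomplete
columns. With ≤ 20% missingness per feature the incomplete-column bias is
small, which tipped the decision.

## Imputation

Nondetects that survive the missingness filter are filled by variational
Bayesian PCA with automatic relevance determination: samples are
observations, features variables; the E-step is grouped by missingness
pattern; the noise precision is capped at 1e12 to keep the near-noiseless
limit finite; components whose loading norms collapse are pruned by the ARD
prior (`alpha_j = d / ||w_j||^2`). Default latent dimension is 5 — enough
for a couple of batch-like factors plus phenotype structure at study scale,
small enough to stay well-posed with tens of samples. Observed cells are
never modified.

## Surrogate-variable adjustment

Hidden heterogeneity (batch, haemolysis residue, cellular contamination) is
estimated with surrogate-variable analysis (`sva`, Buja–Eyuboglu "be"
selection of the count). All *known* covariates — case status, the
intervention arm, and the vitamin-D phenotype — are protected in the model
so surrogate variables cannot absorb them; this matters concretely: in
simulation, leaving vitamin-D unprotected lets SVA swallow the entire
vitamin-D contrast at some seeds. Adjustment then subtracts only the
surrogate-variable and arm components (`remove_unwanted_variation`, with
`keep` for modeled-but-not-subtracted covariates), leaving both phenotype
contrasts intact in expectation.

## Rank-product differential expression

For each direction, a feature's statistic is the geometric mean of its
fold-change ranks across case–control pairings (one case vs one control).
All pairings are used up to `max_comparisons = 50`, beyond which a
seed-determined subsample is taken: the statistic stabilizes well before 50
pairings and cost grows linearly.

The null distribution is obtained by permuting sample labels and recomputing
the rank products **over the same pairing structure**. This preserves the
correlation between pairings that share a sample; an iid uniform-rank null
(each comparison ranked independently) ignores that correlation and is
anti-conservative — in a pure-null simulation (200 features, 20 vs 20) it
roughly doubles the false-positive fraction at the pfp < 0.05 rule, while
the label-permutation null is calibrated. The percentage of false prediction
(pfp) at a feature is the expected number of null rank products at least as
extreme divided by the feature's rank, made monotone by the step-up rule
along each direction's ordering and clipped to [0, 1]. A 1e-9 tolerance in
the null count makes ties between observed and null values (the observed
labeling recurs among permutations) count deterministically.

Features with `min(pfp_up, pfp_down) < 0.05` are called, each in its
better direction (single-call rule; ties broken by |log2 FC|). Two
signatures intersect on normalized miRNA names (case-insensitive, species
prefix stripped, arm suffixes preserved).

## Disease module

The interactome is read from a STRING-dialect TSV; combined scores on the
0–1000 integer scale are detected and rescaled; edges with score strictly
\> 0.4 (medium confidence) are kept; symmetric duplicates keep the maximum
score. The disease gene set is mapped case-insensitively, its induced
largest connected component (LCC) is the observable module, and two nulls
are computed over random node sets of the same size:

- **interaction enrichment**: observed induced edges vs the null mean, with
  `empirical_p = (1 + #{null ≥ obs}) / (n_random + 1)` — the add-one form
  keeps p away from an impossible zero;
- **coherence**: the mean shortest-path length ⟨L⟩ among module pairs,
  measured **on the full network** and averaged over finite pairs only
  (disconnected pairs carry no distance information; dropping them is the
  conservative convention, and the same rule applies to the null sets so
  the comparison is like for like). `z = (⟨L⟩ − mean_null) / sd_null`;
  z < −1.65 (one-sided 5%) calls the module topologically coherent.

Null node sets are uniform by default; a degree-binned null
(`degree_matched_null`) is available because hub-rich modules can look
coherent under a uniform null purely through degree. Centrality (degree,
betweenness normalized by (n−1)(n−2)/2) is computed on the induced module
subgraph by default — hubs *of the module* — with `scope = "network"`
available when global bottlenecks are wanted instead.

## Consensus miRNA targets

Per-source target tables (ranks, or scores converted to per-miRNA
descending-score ranks) are merged per (miRNA, gene) pair. The consensus
score is the geometric mean of the ranks **over the sources that contain
the pair**, and only pairs supported by ≥ 2 sources are kept. Averaging
over present sources (rather than imputing a worst rank for absent ones)
avoids penalizing pairs merely because a source has narrow coverage; the
≥ 2-source rule then guards against single-source artifacts. Ordering is by
score, then by support count, then lexicographically — fully deterministic.
Signature miRNAs lacking an arm suffix match both arms with a warning.
Consensus targets are intersected with the module, counted with
multiplicity (`total`) and uniquely (`unique`), flagged for LCC membership,
and the targeted LCC genes' largest connected subgraph is reported with its
hubs.

## Enrichment

Annotation sets (GMT) are tested by the upper-tail hypergeometric
probability of the observed overlap within the interactome universe,
BH-adjusted across sets; sets outside [3, 2000] members after universe
restriction are skipped. Binary gene attributes (e.g. tissue expression)
are summarized by the query fraction carrying the attribute with a
one-sided hypergeometric p-value against the universe prevalence.

## Synthetic-data generator

`generate_ct_dataset` emulates the *structure* of an early-pregnancy
circulating-miRNA case-control study: per-feature baselines U(22, 36),
planted case and vitamin-D shifts (shared subset included; vitamin-D
insufficiency more prevalent among cases, so the contrasts are confounded
by design, as in real cohorts), hidden Gaussian sample factors with
N(0, 0.5) loadings, abundance-dependent nondetects (logistic in the
underlying Cq, midpoint 31, plateau 0.6), and a few haemolysed samples
(miR-451a shifted −5 Cq). The two haemolysis reference assays share one
factor-loading vector (a sample-wide shift cancels in a within-sample
difference) and get tighter well noise (sd ≤ 0.3), reflecting how abundant
reference assays quantify. Study-scale defaults (754 × 157, 47 cases,
1.0-Cq effects, noise sd 1.0) were fixed a priori as deliberately hard
study conditions.

It does **not** emulate: amplification-efficiency differences between
assays, plate layouts or within-plate spatial effects, true biological
correlation structure between miRNAs beyond the planted factors, or
count-based measurement noise. Companion generators produce a planted-module
interactome, per-source target tables with planted top-ranked targets plus
decoys, and annotation sets with one designated module-matching set.

## Numerical conventions

All randomness flows through `withr::with_seed`; the pipeline derives stage
seeds as master seed + 1 … + 5 so stages are independently reproducible.
Geometric means are computed in log space. Full-network distances are
precomputed as a dense matrix when the network has ≤ 4000 nodes (the
crossover where memory, not time, starts to dominate) and recomputed
per-set otherwise. Empirical p-values use the add-one convention. Rank ties
use midranks throughout.
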