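---
title: "Methods: stratified DIA proteomics with cell type deconvolution"
author: "proteostrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratified DIA proteomics with cell type deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

proteostrat implements a complete analysis chain for fraction-resolved,
label-free DIA (data-independent acquisition) proteomics of stratified
disease cohorts — the kind of design used to contrast genetic
frontotemporal dementia subtypes against non-demented controls (NDC) in
post-mortem brain tissue. This vignette explains each stage's model, its
assumptions, the tunable parameters, and the design decisions taken where
the methodology left room.

## Quantification model

The raw input is a long table of peptide measurements: one peak area and
one identification quality value per (peptide, sample, gel fraction). Four
stages turn this into a protein-by-sample abundance matrix.

**Quality-value filtering** (`filter_peptides`). A measurement is trusted
when its quality value is at most `qcut` (default `1e-3`). A (peptide,
fraction) stratum is kept when at least a `presence` share (default 0.5)
of samples pass the cut — over all samples in `"global"` mode, or within
at least one of the two conditions in `"pairwise"` mode, which is the mode
used ahead of a two-group comparison because it retains
condition-specific peptides (e.g. proteins absent in controls). The
threshold is inclusive: 1 passing sample out of 2 counts as 50%. Failing
measurements inside a retained stratum become missing values rather than
being imputed.

**Normalization** (`normalize_cyclic_loess`). Fast cyclic loess via
limma: on each of 3 iterations every sample column is loess-adjusted
(span 0.7, local linear) against the row-mean reference on the M-A plane.
Normalization runs at the peptide-fraction level *before* fraction
summation (a `normalize_stage = "post_rollup"` switch applies it at the
peptide level after summation instead). Missing entries are ignored in
the fit and stay missing.

**Rollup** (`rollup_fractions`, `rollup_proteins`). Peptide abundance is
the linear-scale sum of its top 2 fractions; protein abundance the sum of
its top 5 peptides. "Top" is decided once per feature by the mean linear
abundance across all samples, not per sample — per-sample re-selection
would confound abundance with missingness. Ties break by feature id so
results are reproducible. Within a selected set, a missing value
contributes 0 to the sum; a feature missing everywhere in a sample stays
missing. Peptides mapping to several proteins abort by default
(`shared = "error"`), with `"drop"` and `"assign_all"` policies available.

**Replicates** (`collapse_replicates`, `replicate_cov`). Technical
replicates are averaged (linear scale) into one column per biological
subject before any group comparison; testing replicate columns as samples
would pseudo-replicate the design. Reproducibility is summarized as the
median over proteins of the within-replicate-group CoV (SD/mean).

## Differential expression: SAM with permutation FDR

Testing runs on log2 protein abundances. For protein $i$ the SAM relative
difference is

$$d_i = \frac{\bar{x}_{2i} - \bar{x}_{1i}}{s_i + s_0}, \qquad
s_i = \sqrt{\left(\tfrac{1}{n_1}+\tfrac{1}{n_2}\right)
\frac{\sum_1 (x-\bar{x}_1)^2 + \sum_2 (x-\bar{x}_2)^2}{n_1+n_2-2}},$$

with the exchangeability factor $s_0$ chosen by the Tusher search:
candidates are the 0, 5, ..., 100 percentiles of the $s_i$, and the winner
minimizes the coefficient of variation of the median absolute deviation of
$d$ computed within windows of $s$-quantiles (100 windows when at least
500 features are tested, 20 above 100 features, quartiles below). A fixed
`s0` can be supplied instead. Group moments are pairwise-complete;
proteins with fewer than two observations in a group are reported as
untested rather than assigned $q = 1$.

Significance comes from balanced label permutations (default 1000):
exhaustive enumeration whenever the number of distinct assignments is at
most `n_perm` (a 3 vs 3 design has exactly $\binom{6}{3} = 20$), otherwise
a seeded uniform draw of distinct assignments without replacement. The
same $s_0$ is reused for every permutation. The p-value of protein $i$ is
the share of the pooled null $|d|$ (across proteins and permutations) at
least $|d_i|$; the q-value at threshold $|d_i|$ is

$$q_i = \hat{\pi}_0 \cdot
\frac{\mathrm{median}_b\,\#\{|d^{(b)}| \ge |d_i|\}}{\#\{|d| \ge |d_i|\}},$$

clipped to $[0,1]$ and made monotone non-increasing in $|d|$.
$\hat\pi_0$ is the share of observed $d$ inside the interquartile range of
the pooled null, divided by 0.5 and capped at 1. Comparisons against the
threshold use a $10^{-9}$ relative epsilon so that assignments whose $|d|$
ties the observed one mathematically (the complement assignment always
does) count as ties regardless of floating-point noise. Fold changes are
ratios of linear group means (disease over reference; a `log_mean` switch
exponentiates the difference of mean logs instead), and significant
proteins split into higher (ratio above 1) and lower expressed sets.

## Cell type enrichment

A labelled single-cell (or single-nucleus) expression reference provides
**specificity**: after per-cell library normalization and per-type
averaging, `specificity[g, t]` is the share of gene $g$'s summed type
means attributable to type $t$; rows sum to 1. Cells labelled `unknown`
are excluded.

**EWCE bootstrap** (`ewce_bootstrap`). The statistic for a protein list is
the sum of its specificity values per cell type. `n_boot` (default 20000)
random lists of the same length are drawn uniformly without replacement
from the background — all quantified proteins — and
$p = (\#\{\text{bootstrap} \ge \text{observed}\} + 1)/(n_\text{boot}+1)$,
so zero is never reported; floor results are labelled `< 1/n_boot`. Fold
enrichment is observed over bootstrap mean, the z-score is in bootstrap
SDs, and BH adjustment runs across cell types. Random lists are
length-matched but not expression-matched by default (an optional
`level_match` mode matches expression-level deciles using the reference's
average expression).

**Highly-enriched classification** (`classify_highly_enriched`). A
protein is assigned the unique cell type with specificity at or above 0.5;
optionally the excitatory and inhibitory columns are first summed into a
`neuron` column (post-merge ties go to the larger value, then column
order).

**Composition-change diagnostic** (`ndc_variation_sd`,
`composition_check`). To ask whether cell-type-linked expression shifts
could simply reflect altered cell proportions, control samples are split
into balanced halves (exhaustively when feasible, otherwise 100 seeded
random splits), per-protein log2 ratios of half-means are pooled into one
SD, and each cell type's highly-enriched protein set is summarized by the
fraction of disease-vs-control fold changes inside the ±2 SD band plus
the fraction of significant proteins outside it. A regulated set sits
outside the band; composition drift alone stays largely inside.

## Overrepresentation analysis

`hypergeometric_enrichment` restricts each gene set to the background
(all quantified proteins), discards terms with fewer than 5 members
there, and computes the upper-tail hypergeometric probability of the
observed overlap, BH-adjusted per ontology namespace. The multiple-testing
method is deliberately plain BH — reproducible and the same correction the
EWCE stage uses — rather than any web-server-specific scheme.
`best_per_parent` implements hierarchical filtering literally: a
significant term survives if, under at least one parent, it has the
smallest p-value among that parent's significant children (ties: larger
overlap, then smaller id); significant parentless terms always survive.
`partition_by_subtree` assigns genes to every requested subtree (root plus
descendants) that annotates them — the generic form of a pre-/postsynaptic
location split — with multi-assignment allowed. GMT and a minimal OBO
subset (`id`, `name`, `namespace`, `is_a`) are the exchange formats; the
OBO reader rejects cyclic graphs.

## Cross-cohort comparison

`overlap_de` restricts two differential profiles to their jointly
quantified proteins before any counting, splits them into shared and
cohort-distinct significant sets at the same q threshold, and counts
direction concordance as fold changes on the same side of 1 (the q
threshold only — nominal-p-only proteins count as distinct).
`effect_size_scatter` pairs SAM $d$ values and reports the share of
proteins with the stronger effect in the first cohort, ties at half
weight.

## The synthetic cohort generator

Every stage is validated on simulated data with planted ground truth
(`simulate_dia_cohort`, `simulate_sc_reference`, `simulate_ontology`).
The cohort model is log-normal on the log2 scale: each measurement's
latent value is protein base (N(18, 2)) + peptide offset (N(0, 1.5)) +
fraction offset (N(0, 1)) + the planted group effect
(±`de_log2fc` for differential proteins in the disease group) +
per-subject scale bias + N(0, `noise_sd`) noise, and the peak area is 2
to that power. Quality values are a two-point mixture (pass `1e-4`, fail
`1e-2`): the pass probability follows a logistic curve in the latent
abundance around `missingness_midpoint`, so dropout is
abundance-dependent, and failed identifications still carry a (noisier)
peak area — the quality filter, not record absence, removes them.
Technical replicates share everything except measurement noise.
Cell-type-linked differential proteins take the reference's marker-gene
identifiers; remaining proteins take the other reference genes in random
order, so unlinked markers enter the cohort as null proteins.

Calibration was fixed once: `noise_sd = 0.5` log2 units reproduces a
median technical-replicate protein CoV near 0.13, the reproducibility
reported for replicate DIA measurements of brain tissue, and is the only
distributional anchor available; `sample_scale_sd = 0.25` represents
residual between-run scale bias (acquisition software has already applied
a total-peak-area normalization to exported data), which the cyclic loess
stage removes; `missingness_midpoint = 14` puts identification failures
about 1.4 SD below typical abundance. The single-cell reference draws
negative-binomial counts (size 2) with each marker gene's mean elevated
`marker_enrichment`-fold in its own type, giving the closed-form expected
specificity `enrichment / (enrichment + n_types - 1)`.

What the generator does **not** emulate: chromatography and spectra,
retention-time drift, charge states, shared-peptide ambiguity beyond an
optional flag, correlated peptide interference, or batch structure. A
passing test suite therefore demonstrates the statistics and bookkeeping
are right under the stated generative model, not that any biological
conclusion transfers to a particular real cohort.

## A documented artifact: normalization under heavy differential expression

When a large share of the proteome is planted as strongly differential
(the shipped cohort plants roughly 23% of proteins at ±2 log2, echoing
the proportions such studies report), global M-A normalization leaks
signal into null proteins. The mechanism is intensity migration:
up-regulated rows gain mean intensity and concentrate at high A,
down-regulated rows at low A; the loess fit absorbs these locally
imbalanced effects into each disease sample's correction curve, imposing
an intensity-dependent, group-aligned shift on null features — which the
top-k rollup then samples at its high-intensity end. Because the shift is
aligned with the true labels, label permutations cannot reproduce it, and
the cohort-level observed FDR inflates well beyond the nominal q
threshold even though sensitivity stays near 1. On protein matrices
simulated without a normalization stage the same SAM implementation
controls FDR tightly (null q<0.05 rate below 0.01 across 200 global-null
simulations; observed FDR ~0.05 under balanced 4-fold effects), which
localizes the artifact to the normalization-rollup interaction, not the
test. Any pipeline that cyclic-loess-normalizes data with abundant
strong, direction-imbalanced regulation shares this behaviour; the
`scripts/acceptance.R` report therefore carries both the cohort-level and
the matrix-level error rates.

## Numerical and degenerate-input conventions

All-missing features are dropped with a warning before normalization; a
single-sample matrix normalizes to itself. Zero-variance proteins are
handled by $s_0 > 0$; if every protein is constant, $d = 0$ and $q = 1$
throughout. Empty target lists yield empty enrichment results rather than
errors; a bootstrap with target equal to background degenerates to fold 1
and p near 1. Every random stage takes an explicit seed, the pipeline
driver (`run_pipeline`) derives per-stage seeds from one root seed, and
rerunning with the same configuration is byte-identical (verified via the
written manifest's MD5 checksums).

## Problem sizes used in validation

The test suite and the acceptance script run entirely on synthetic data:
cohorts of 300-800 proteins with 8-11 subjects per group, 200 global-null
simulations of 100 proteins at 8 vs 8 with 1000 permutations, 500-list
bootstrap calibrations, and enumeration oracles on instances small enough
to enumerate exhaustively (3 vs 3 permutations, backgrounds of at most 30
genes, subset spaces up to a few thousand). These sizes were chosen to
make Monte-Carlo error small relative to the tolerances being asserted.
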