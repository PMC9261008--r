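# proteostrat

Stratified differential proteomics with cell type deconvolution.

`proteostrat` is an R package for analysing fraction-resolved, label-free
DIA (data-independent acquisition) proteomics of stratified disease
cohorts — for example, contrasting genetic dementia subtypes against
non-demented controls (NDC) in post-mortem brain tissue, where bulk
protein signatures mix contributions from astrocytes, neurons,
oligodendrocytes, microglia and vasculature. It is aimed at proteomics
and neurodegeneration researchers who need the full chain from exported
peptide quantification tables to cell-type-resolved differential
signatures, with every stage testable on simulated data carrying planted
ground truth.

The pipeline:

1. **Quantification** — quality-value filtering of (peptide, fraction)
   strata (q ≤ 10⁻³ in ≥ 50% of samples of a condition), fast cyclic
   loess normalization (3 iterations, via limma), rollup by summing the
   top 2 fractions per peptide and the top 5 peptides per protein, and
   technical-replicate CoV.
2. **Differential expression** — SAM moderated t-statistics
   d = (x̄₂ − x̄₁)/(s + s₀) with the Tusher s₀ search, 1000 balanced
   label permutations (exhaustive when possible), pooled-null p-values
   and FDR q-values with a π₀ estimate; discovery at q < 0.05, split into
   higher and lower expressed proteins.
3. **Cell type enrichment** — gene × cell-type specificity from a
   labelled single-cell reference, EWCE: the summed specificity of a
   protein list versus 20,000 length-matched random lists, BH-corrected;
   classification of highly enriched proteins (specificity ≥ 0.5, with
   optional excitatory+inhibitory merging); and a composition-change
   diagnostic comparing fold changes to ±2 SD of control-vs-control
   variation.
4. **Overrepresentation** — hypergeometric enrichment of gene sets
   (≥ 5 proteins in the background) with BH adjustment per namespace,
   "best-per-parent" reduction on an ontology DAG, and subtree
   partitions (e.g. pre-/postsynaptic style splits).
5. **Cohort comparison** — joint quantified sets, shared and distinct
   differential proteins, direction concordance, paired effect sizes.
6. **Simulation** — a generator for peptide-level DIA cohorts
   (log-normal intensities, 1–8 peptides per protein, 4 fractions,
   abundance-dependent missingness through quality values, per-sample
   scale bias, technical replicates, cell-type-linked planted effects),
   labelled single-cell references with planted markers, and ontology
   fixtures with nested gene sets.

## Worked example

Simulate a 8 vs 8 cohort with 10 astrocyte-linked up-regulated proteins
plus 10% generic differential proteins, quantify, test, and ask which
cell type carries the signal:

```r
library(proteostrat)

ref <- simulate_sc_reference(n_cells_per_type = 40, n_genes = 400,
                             n_marker_per_type = 12, marker_enrichment = 20,
                             seed = 42)
cfg <- sim_config(n_samples_per_group = c(NDC = 8, FTD = 8), n_proteins = 200,
                  de_fraction = 0.1,
                  celltype_link = list(astrocyte = list(n = 10, direction = 1)),
                  seed = 43)
cohort <- simulate_dia_cohort(cfg, reference_truth = ref$truth)

quant <- quantify_proteins(cohort$peptides, cohort$metadata, cohort$map,
                           mode = "pairwise")
subj <- collapse_replicates(quant$proteins, cohort$metadata)
de <- run_de(subj$matrix, factor(subj$metadata$group, c("NDC", "FTD")),
             alpha = 0.05, n_perm = 1000, seed = 44)
cat("significant:", sum(de$table$significant),
    "| higher:", length(de$higher), "| lower:", length(de$lower), "\n")
#> significant: 62 | higher: 22 | lower: 40

spec <- compute_specificity(ref$counts, ref$labels)
bg <- intersect(rownames(subj$matrix), rownames(spec))
ew <- ewce_bootstrap(intersect(de$higher, bg), bg, spec,
                     n_boot = 20000, seed = 45)
ew[order(ew$p), c("cell_type", "fold", "z", "p_label", "p_adj")][1:3, ]
#>   cell_type  fold      z p_label   p_adj
#>   astrocyte 2.647  8.018 < 5e-05 0.00035
#>  excitatory 0.938 -0.441   0.598 1.00000
#>  inhibitory 0.887 -0.810  0.7881 1.00000
```

The higher-expressed set is 2.6-fold more astrocyte-specific than random
lists of the same size (8 bootstrap SDs above the mean; the bootstrap p
is below the 1/20000 floor, BH-adjusted 0.00035) — exactly the planted
astrocyte link — while the neuronal cell types sit at fold ≈ 1, i.e.
chance level. The top of `de$table` recovers the planted 4-fold effects
as fold changes near 3.5 with q-values at the permutation floor.

## The analysis workflow

`analysis/01_simulate_cohort.R` through `analysis/06_cohort_comparison.R`
run a complete narrated study on synthetic data — simulation,
quantification, differential expression, cell-type enrichment with the
composition diagnostic, overrepresentation with best-per-parent
filtering, and a two-cohort comparison — writing tables under `results/`.
Run them in order from the repository root:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

The vignette (`vignettes/proteostrat-methods.Rmd`) documents the models,
parameter choices, calibrations, and known limitations — including why
cohort-level observed FDR inflates when a large share of the proteome is
planted as strongly differential (an intensity-migration artifact of
global M-A normalization that any such pipeline shares), while the test
statistics themselves control FDR tightly on matrices that bypass
normalization.

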