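#!/usr/bin/env Rscript
# Cross-cohort comparison: simulate a second disease cohort sharing part of
# the planted signal (an AD-like contrast), run the same quantification and
# DE stages, then compute the joint quantified set, shared and distinct
# differential proteins, direction concordance, and paired effect sizes.

suppressMessages(library(proteostrat))
out <- "results"
dat <- "results/data"

sc_truth <- read_tsv_table(file.path(dat, "sc_truth.tsv"))
cfg_b <- sim_config(
  n_samples_per_group = c(NDC = 10, AD = 10),
  n_proteins = 300,
  de_fraction = 0.15, de_log2fc = 2,
  celltype_link = list(astrocyte = list(n = 12, direction = 1),
                       excitatory = list(n = 12, direction = -1)),
  seed = 3031L
)
cohort_b <- simulate_dia_cohort(cfg_b, reference_truth = sc_truth)
quant_b <- quantify_proteins(cohort_b$peptides, cohort_b$metadata,
                             cohort_b$map, mode = "pairwise")
col_b <- collapse_replicates(quant_b$proteins, cohort_b$metadata)
de_b <- run_de(col_b$matrix,
               factor(col_b$metadata$group, levels = c("NDC", "AD")),
               alpha = 0.05, n_perm = 1000, seed = 31)

x_a <- read_abundance_matrix(file.path(out, "protein_abundance_subjects.tsv"))
de_a_tab <- read_tsv_table(file.path(out, "de_results.tsv"))
a <- cohort_de("FTD", rownames(x_a), de_a_tab)
b <- cohort_de("AD", rownames(col_b$matrix), de_b)

ov <- overlap_de(a, b, alpha = 0.05)
message(sprintf("joint quantified: %d; shared DE: %d; distinct FTD: %d; distinct AD: %d",
                length(ov$joint), length(ov$shared),
                length(ov$distinct_a), length(ov$distinct_b)))
message(sprintf("direction concordance among shared: %d/%d (%.0f%%)",
                ov$concordant, length(ov$shared),
                100 * ov$concordant / max(1, length(ov$shared))))

es <- effect_size_scatter(a, b, ov$shared)
message(sprintf("share of shared proteins with stronger effect in FTD: %.2f",
                es$prop_stronger_a))

write_tsv_table(data.frame(protein = ov$shared), file.path(out, "shared_de.tsv"))
write_tsv_table(data.frame(protein = ov$distinct_a),
                file.path(out, "distinct_ftd.tsv"))
write_tsv_table(es$pairs, file.path(out, "effect_size_pairs.tsv"))
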