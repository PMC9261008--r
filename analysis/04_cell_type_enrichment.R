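#!/usr/bin/env Rscript
# Cell-type deconvolution of the differential signatures: specificity from
# the single-cell reference, EWCE bootstrap enrichment of the higher and
# lower expressed protein sets, highly-enriched protein classification, and
# the composition-change diagnostic against control-vs-control variation.

suppressMessages(library(proteostrat))
out <- "results"
dat <- "results/data"

counts <- t(read_abundance_matrix(file.path(dat, "sc_counts.tsv")))
labels_df <- read_tsv_table(file.path(dat, "sc_labels.tsv"))
labels <- labels_df$label[match(rownames(counts), labels_df$cell)]
spec <- compute_specificity(counts, labels)
write_abundance_matrix(spec, file.path(out, "specificity.tsv"))

x <- read_abundance_matrix(file.path(out, "protein_abundance_subjects.tsv"))
meta <- read_tsv_table(file.path(out, "subject_metadata.tsv"))
de_tab <- read_tsv_table(file.path(out, "de_results.tsv"))
background <- intersect(rownames(x), rownames(spec))
message(sprintf("EWCE background: %d of %d quantified proteins in reference",
                length(background), nrow(x)))

for (side in c("higher", "lower")) {
  target <- intersect(read_gene_list(file.path(out, paste0("de_", side, ".txt"))),
                      background)
  if (length(target) < 5) {
    message("skipping ", side, ": fewer than 5 mappable proteins")
    next
  }
  res <- ewce_bootstrap(target, background, spec, n_boot = 20000,
                        seed = if (side == "higher") 21 else 22)
  write_tsv_table(res, file.path(out, paste0("ewce_", side, ".tsv")))
  top <- res[order(res$p), ][1, ]
  message(sprintf("%s expressed (n = %d): top cell type %s, fold %.2f, p %s",
                  side, length(target), top$cell_type, top$fold, top$p_label))
}

assignments <- classify_highly_enriched(spec, rownames(x), threshold = 0.5,
                                        merge_neurons = TRUE)
message(sprintf("highly enriched (specificity >= 0.5): %d proteins",
                sum(!is.na(assignments))))

ndc_samples <- meta$sample_id[meta$group == "NDC"]
ndc <- ndc_variation_sd(x, ndc_samples, n_splits = 100, seed = 23)
message(sprintf("NDC-vs-NDC fold-change SD: %.3f (band +/- %.3f)",
                ndc$sd, 2 * ndc$sd))
chk <- composition_check(de_tab, assignments, ndc$sd)
write_tsv_table(chk$summary, file.path(out, "composition_summary.tsv"))
write_tsv_table(chk$points, file.path(out, "composition_points.tsv"))
print(chk$summary)
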