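#!/usr/bin/env Rscript
# Simulate the study inputs: a labelled single-cell reference, a
# two-condition fraction-resolved DIA peptide cohort with planted
# differential proteins linked to cell types, and an ontology fixture.
# Outputs go to results/data/.

suppressMessages(library(proteostrat))
seed <- 2024L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("simulating single-cell reference (7 cortical cell types)")
ref <- simulate_sc_reference(n_cells_per_type = 40, n_genes = 500,
                             n_marker_per_type = 15, marker_enrichment = 20,
                             seed = seed)
write_tsv_table(data.frame(cell = rownames(ref$counts), label = ref$labels),
                file.path(out, "sc_labels.tsv"))
write_abundance_matrix(t(ref$counts), file.path(out, "sc_counts.tsv"))
write_tsv_table(ref$truth, file.path(out, "sc_truth.tsv"))

message("simulating DIA cohort: 11 NDC vs 8 FTD subjects, 2 technical replicates")
cfg <- sim_config(
  n_samples_per_group = c(NDC = 11, FTD = 8),
  n_proteins = 300,
  de_fraction = 0.15, de_log2fc = 2,
  celltype_link = list(astrocyte = list(n = 12, direction = 1),
                       excitatory = list(n = 12, direction = -1)),
  n_tech_replicates = 2,
  seed = seed + 1L
)
cohort <- simulate_dia_cohort(cfg, reference_truth = ref$truth)
write_peptide_table(cohort$peptides, file.path(out, "peptides.tsv"))
write_tsv_table(cohort$metadata, file.path(out, "metadata.tsv"))
write_tsv_table(cohort$map, file.path(out, "peptide_protein_map.tsv"))
write_ground_truth(cohort$truth, file.path(out, "ground_truth.json"))

message("simulating ontology fixture (40 terms, depth 3)")
onto <- simulate_ontology(n_terms = 40, max_depth = 3, n_genes = 500,
                          seed = seed + 2L)
write_obo(onto, file.path(out, "ontology.obo"))
sets <- onto$sets
attr(sets, "description") <- stats::setNames(onto$terms$name,
                                             onto$terms$term_id)
write_gmt(sets, file.path(out, "gene_sets.gmt"))

n_de <- sum(cohort$truth$proteins$is_de)
message(sprintf("done: %d peptide records, %d proteins (%d differential)",
                nrow(cohort$peptides), cfg$n_proteins, n_de))
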