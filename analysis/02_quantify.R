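#!/usr/bin/env Rscript
# Peptide-to-protein quantification: quality-value filtering (pairwise
# mode), fast cyclic loess normalization, top-2-fraction and top-5-peptide
# rollup, and technical-replicate reproducibility.

suppressMessages(library(proteostrat))
dat <- "results/data"
out <- "results"

peptides <- read_peptide_table(file.path(dat, "peptides.tsv"))
metadata <- read_tsv_table(file.path(dat, "metadata.tsv"),
                           required = c("sample_id", "group", "subject"))
map <- read_tsv_table(file.path(dat, "peptide_protein_map.tsv"),
                      required = c("peptide_id", "protein_id"))

quant <- quantify_proteins(peptides, metadata, map, mode = "pairwise",
                           qcut = 1e-3, presence = 0.5,
                           k_fractions = 2, k_peptides = 5,
                           loess_iterations = 3)
message(sprintf("retained %d of %d peptide records after quality filtering",
                nrow(quant$filtered), nrow(peptides)))
message(sprintf("quantified %d proteins across %d samples",
                nrow(quant$proteins), ncol(quant$proteins)))

cov <- suppressWarnings(
  replicate_cov(quant$proteins, split(metadata$sample_id, metadata$subject)))
message(sprintf("median technical-replicate CoV: %.3f", cov$median_cov))

collapsed <- collapse_replicates(quant$proteins, metadata)
write_abundance_matrix(quant$proteins, file.path(out, "protein_abundance.tsv"))
write_abundance_matrix(collapsed$matrix,
                       file.path(out, "protein_abundance_subjects.tsv"))
write_tsv_table(collapsed$metadata, file.path(out, "subject_metadata.tsv"))
write_tsv_table(data.frame(protein = names(cov$per_protein),
                           cov = cov$per_protein),
                file.path(out, "replicate_cov.tsv"))
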