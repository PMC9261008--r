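#!/usr/bin/env Rscript
# Gene-set overrepresentation of the differential proteins: hypergeometric
# enrichment against the quantified background (terms with >= 5 proteins),
# BH adjustment, best-per-parent reduction on the ontology DAG, and a
# subtree partition of the significant proteins.

suppressMessages(library(proteostrat))
out <- "results"
dat <- "results/data"

onto <- read_obo(file.path(dat, "ontology.obo"))
sets <- read_gmt(file.path(dat, "gene_sets.gmt"))
x <- read_abundance_matrix(file.path(out, "protein_abundance_subjects.tsv"))
de_tab <- read_tsv_table(file.path(out, "de_results.tsv"))

background <- rownames(x)
ns <- stats::setNames(onto$terms$namespace, onto$terms$term_id)
sc_truth <- read_tsv_table(file.path(dat, "sc_truth.tsv"))
marked <- sc_truth[!is.na(sc_truth$marker_type) & sc_truth$marker_type != "", ]
marker_sets <- split(marked$gene, marked$marker_type)

# higher and lower expressed sets are tested separately, mirroring the
# direction-split differential signatures
for (side in c("higher", "lower")) {
  target <- intersect(read_gene_list(file.path(out, paste0("de_", side, ".txt"))),
                      background)
  message(sprintf("-- %s expressed: %d proteins against background of %d",
                  side, length(target), length(background)))

  res <- hypergeometric_enrichment(target, background, sets, min_size = 5,
                                   namespaces = ns)
  write_tsv_table(res, file.path(out, paste0("enrichment_", side, ".tsv")))
  bpp <- best_per_parent(res, onto$edges, alpha = 0.05)
  message(sprintf("   random-ontology terms: %d tested, %d significant, %d best-per-parent",
                  nrow(res), sum(res$p_adj < 0.05), nrow(bpp)))

  # cell-type marker sets carry genuine planted enrichment (the linked
  # differential proteins are marker genes), unlike the random ontology
  res_mk <- hypergeometric_enrichment(target, background, marker_sets,
                                      min_size = 5)
  write_tsv_table(res_mk, file.path(out, paste0("enrichment_marker_", side, ".tsv")))
  top_mk <- res_mk[res_mk$p_adj < 0.05, ]
  message(sprintf("   marker sets: %s",
                  if (nrow(top_mk) > 0)
                    paste(sprintf("%s (overlap %d/%d, adj p %.2g)",
                                  top_mk$term_id, top_mk$overlap, top_mk$size,
                                  top_mk$p_adj), collapse = "; ")
                  else "none significant"))
}

# partition by the root's immediate children, standing in for a
# pre/post-synaptic style location split
all_de <- intersect(de_tab$protein[de_tab$significant == TRUE |
                                     de_tab$significant == "TRUE"],
                    background)
roots <- unique(onto$edges$child[onto$edges$parent == onto$terms$term_id[1]])
if (length(roots) >= 2) {
  part <- partition_by_subtree(all_de, onto$edges, sets, roots[1:2])
  message(sprintf("subtree partition of %d DE proteins: %s; unannotated %d",
                  length(all_de),
                  paste(sprintf("%s=%d", names(part$counts), part$counts),
                        collapse = ", "),
                  length(part$unannotated)))
}
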