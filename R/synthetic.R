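#' Simulation configuration for a synthetic DIA cohort
#'
#' Bundles and validates all parameters of the peptide-level cohort
#' simulator. Defaults describe a two-group brain-tissue study measured in
#' four gel fractions with one to eight peptides per protein.
#'
#' @param n_samples_per_group Samples per condition. Either a single count
#'   (both groups equal) or a named integer vector of length 2 giving the
#'   group labels and sizes, e.g. `c(NDC = 11, FTD = 8)`.
#' @param n_proteins Number of simulated proteins.
#' @param peptides_per_protein_range Integer interval (length 2) from which
#'   each protein's peptide count is drawn uniformly. Must lie in [1, 50].
#' @param n_fractions Number of gel fractions per sample.
#' @param de_fraction Proportion of proteins planted as differentially
#'   expressed (in addition to any proteins requested via `celltype_link`).
#' @param de_log2fc Planted log2 effect size for differential proteins.
#' @param celltype_link Optional named list mapping a cell-type name to
#'   `list(n = <count>, direction = +1 | -1)`. That many differential
#'   proteins are linked to the cell type with the given direction; their
#'   protein identifiers reuse the cell type's marker genes when
#'   `reference_truth` is supplied to [simulate_dia_cohort()].
#' @param sample_scale_sd SD (log2 units) of the per-sample scale bias
#'   (residual bias left after acquisition-level total-area normalization;
#'   cyclic loess removes it downstream).
#' @param noise_sd SD (log2 units) of per-measurement noise. The default
#'   0.5 is calibrated so that the protein-level coefficient of variation
#'   between technical replicates comes out near 0.13 after rollup, the
#'   reproducibility typical of DIA brain-tissue cohorts.
#' @param missingness_midpoint Latent log2 abundance at which the retention
#'   probability (quality value passing the 1e-3 cut) is 0.5. `-Inf` retains
#'   everything, `Inf` fails everything. The default 14 sits about 1.4 SD
#'   below the typical latent abundance, so identification failures
#'   concentrate in the low-abundance tail.
#' @param missingness_slope Scale (log2 units) of the logistic retention
#'   curve; larger values flatten the abundance dependence.
#' @param n_tech_replicates Technical replicates per biological sample;
#'   replicates share every effect except measurement noise.
#' @param shared_peptide_fraction Proportion of peptides additionally mapped
#'   to a second protein, to exercise shared-peptide policies. Default 0
#'   (every peptide maps to exactly one protein).
#' @param seed Random seed; a fixed seed gives identical output.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples_per_group = c(NDC = 10, FTD = 10),
                       n_proteins = 200,
                       peptides_per_protein_range = c(1L, 8L),
                       n_fractions = 4L,
                       de_fraction = 0.1,
                       de_log2fc = 2,
                       celltype_link = NULL,
                       sample_scale_sd = 0.25,
                       noise_sd = 0.5,
                       missingness_midpoint = 14,
                       missingness_slope = 1,
                       n_tech_replicates = 1L,
                       shared_peptide_fraction = 0,
                       seed = 1L) {
  if (length(n_samples_per_group) == 1L) {
    n_samples_per_group <- c(NDC = n_samples_per_group, FTD = n_samples_per_group)
  }
  if (length(n_samples_per_group) != 2L || is.null(names(n_samples_per_group))) {
    stop("n_samples_per_group must be a single count or a named length-2 vector")
  }
  stopifnot(
    all(n_samples_per_group >= 1), n_proteins >= 1, n_fractions >= 1,
    n_tech_replicates >= 1,
    length(peptides_per_protein_range) == 2L,
    peptides_per_protein_range[1] >= 1, peptides_per_protein_range[2] <= 50,
    peptides_per_protein_range[1] <= peptides_per_protein_range[2],
    de_fraction >= 0, de_fraction <= 1,
    sample_scale_sd >= 0, noise_sd >= 0, missingness_slope > 0,
    shared_peptide_fraction >= 0, shared_peptide_fraction < 1
  )
  if (!is.null(celltype_link)) {
    if (is.null(names(celltype_link)) || any(names(celltype_link) == "")) {
      stop("celltype_link must be a named list")
    }
    for (lk in celltype_link) {
      if (!all(c("n", "direction") %in% names(lk)) || !lk$direction %in% c(-1, 1)) {
        stop("each celltype_link entry needs fields n and direction (+1/-1)")
      }
    }
  }
  structure(list(
    n_samples_per_group = n_samples_per_group,
    n_proteins = as.integer(n_proteins),
    peptides_per_protein_range = as.integer(peptides_per_protein_range),
    n_fractions = as.integer(n_fractions),
    de_fraction = de_fraction,
    de_log2fc = de_log2fc,
    celltype_link = celltype_link,
    sample_scale_sd = sample_scale_sd,
    noise_sd = noise_sd,
    missingness_midpoint = missingness_midpoint,
    missingness_slope = missingness_slope,
    n_tech_replicates = as.integer(n_tech_replicates),
    shared_peptide_fraction = shared_peptide_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a labelled single-cell expression reference
#'
#' Draws a cell-by-gene count matrix from a negative-binomial model with
#' planted marker genes: a marker gene's mean expression in its own cell
#' type is `marker_enrichment` times its mean in every other type. After
#' per-cell normalization and type averaging, a marker's specificity for its
#' type is therefore close to `enrichment / (enrichment + n_types - 1)`.
#'
#' @param cell_types Character vector of cell-type names (>= 2).
#' @param n_cells_per_type Cells simulated per type.
#' @param n_genes Total genes; marker sets are disjoint and drawn from the
#'   front of the gene list.
#' @param n_marker_per_type Planted marker genes per cell type.
#' @param marker_enrichment Mean fold elevation of a marker in its own type.
#' @param nb_size Negative-binomial size (dispersion) parameter.
#' @param base_mean_log_sd SD of the log-normal distribution of per-gene
#'   baseline means.
#' @param seed Random seed.
#'
#' @return A list with `counts` (cell x gene integer matrix), `labels`
#'   (character vector, one per cell) and `truth` (data.frame with columns
#'   `gene`, `marker_type`, `enrichment`; `marker_type` is `NA` for
#'   non-markers).
#' @export
simulate_sc_reference <- function(cell_types = c("astrocyte", "endothelial",
                                                 "excitatory", "inhibitory",
                                                 "microglia", "oligodendrocyte",
                                                 "OPC"),
                                  n_cells_per_type = 50L,
                                  n_genes = 500L,
                                  n_marker_per_type = 10L,
                                  marker_enrichment = 20,
                                  nb_size = 2,
                                  base_mean_log_sd = 0.5,
                                  seed = 1L) {
  n_types <- length(cell_types)
  if (n_types < 2L) stop("at least 2 cell types are required")
  if (n_types * n_marker_per_type > n_genes) {
    stop("marker sets exceed n_genes: reduce n_marker_per_type or add genes")
  }
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  labels <- rep(cell_types, each = n_cells_per_type)
  n_cells <- length(labels)

  base_mean <- exp(stats::rnorm(n_genes, mean = log(5), sd = base_mean_log_sd))
  # mu[g, t]: per-type mean; markers elevated in their own type
  mu <- matrix(base_mean, nrow = n_genes, ncol = n_types)
  marker_type <- rep(NA_character_, n_genes)
  if (n_marker_per_type > 0) {
    for (t in seq_len(n_types)) {
      idx <- ((t - 1L) * n_marker_per_type + 1L):(t * n_marker_per_type)
      mu[idx, t] <- mu[idx, t] * marker_enrichment
      marker_type[idx] <- cell_types[t]
    }
  }
  counts <- matrix(0L, nrow = n_cells, ncol = n_genes,
                   dimnames = list(sprintf("cell%05d", seq_len(n_cells)), genes))
  for (t in seq_len(n_types)) {
    rows <- which(labels == cell_types[t])
    counts[rows, ] <- matrix(
      stats::rnbinom(length(rows) * n_genes, mu = rep(mu[, t], each = length(rows)),
                     size = nb_size),
      nrow = length(rows)
    )
  }
  truth <- data.frame(gene = genes, marker_type = marker_type,
                      enrichment = ifelse(is.na(marker_type), 1, marker_enrichment),
                      stringsAsFactors = FALSE)
  list(counts = counts, labels = labels, truth = truth)
}

#' Simulate a fraction-resolved DIA peptide cohort with planted ground truth
#'
#' Generates long-format peptide quantification records mimicking a
#' two-condition gel-fractionated DIA experiment. Each measurement's linear
#' peak area is `2 ^ latent` with
#' `latent = protein base + peptide offset + fraction offset +
#' group effect + sample scale bias + noise`; the group effect equals
#' `direction * de_log2fc` for planted differential proteins in the second
#' (disease) condition. Quality values are a two-point mixture: a
#' measurement passes (qvalue 1e-4) with logistic probability increasing in
#' the latent abundance around `missingness_midpoint`, otherwise it fails
#' (qvalue 1e-2) and carries a noisier peak area, so the quality filter (not
#' record absence) removes it. Technical replicates share every effect
#' except measurement noise.
#'
#' @param config A [sim_config()] object.
#' @param reference_truth Optional `truth` data.frame from
#'   [simulate_sc_reference()]; when given, proteins linked to a cell type
#'   via `config$celltype_link` are named after that type's marker genes so
#'   cohort and reference identifiers align.
#'
#' @return A list with elements `peptides` (data.frame: `peptide_id`,
#'   `sample_id`, `fraction`, `peak_area`, `qvalue`), `metadata` (data.frame:
#'   `sample_id`, `group`, `subject`, `replicate`), `map` (data.frame:
#'   `peptide_id`, `protein_id`) and `truth` (list with `proteins` and
#'   `samples` data.frames recording all planted parameters).
#' @export
simulate_dia_cohort <- function(config, reference_truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  groups <- names(config$n_samples_per_group)
  n_prot <- config$n_proteins

  protein_ids <- sprintf("P%04d", seq_len(n_prot))
  cell_type <- rep(NA_character_, n_prot)
  direction <- rep(0L, n_prot)
  is_de <- rep(FALSE, n_prot)

  # cell-type-linked DE proteins occupy the front of the protein list
  cursor <- 0L
  if (!is.null(config$celltype_link)) {
    for (ct in names(config$celltype_link)) {
      lk <- config$celltype_link[[ct]]
      idx <- cursor + seq_len(lk$n)
      if (max(idx) > n_prot) stop("celltype_link requests more proteins than n_proteins")
      cell_type[idx] <- ct
      direction[idx] <- as.integer(lk$direction)
      is_de[idx] <- TRUE
      if (!is.null(reference_truth)) {
        markers <- reference_truth$gene[!is.na(reference_truth$marker_type) &
                                          reference_truth$marker_type == ct]
        if (length(markers) < lk$n) {
          stop(sprintf("reference has only %d markers for cell type '%s'",
                       length(markers), ct))
        }
        protein_ids[idx] <- markers[seq_len(lk$n)]
      }
      cursor <- cursor + lk$n
    }
  }
  if (!is.null(reference_truth)) {
    # remaining proteins take unused reference gene ids (in random order,
    # so markers of unlinked cell types enter the cohort as null proteins)
    # and the quantified set overlaps the single-cell reference
    unused <- setdiff(reference_truth$gene, protein_ids)
    unused <- sample(unused)
    rest <- setdiff(seq_len(n_prot), seq_len(cursor))
    n_take <- min(length(rest), length(unused))
    protein_ids[rest[seq_len(n_take)]] <- unused[seq_len(n_take)]
  }
  n_extra_de <- round(config$de_fraction * n_prot)
  if (n_extra_de > 0) {
    pool <- which(!is_de)
    extra <- if (length(pool) > 1) {
      sort(sample(pool, min(n_extra_de, length(pool))))
    } else pool
    is_de[extra] <- TRUE
    direction[extra] <- rep_len(c(1L, -1L), length(extra))
  }

  # sample layout: biological subjects x technical replicates
  subj <- unlist(lapply(groups, function(g) {
    sprintf("%s%02d", g, seq_len(config$n_samples_per_group[[g]]))
  }))
  subj_group <- rep(groups, times = config$n_samples_per_group)
  reps <- config$n_tech_replicates
  metadata <- data.frame(
    sample_id = as.vector(t(outer(subj, seq_len(reps),
                                  function(s, r) sprintf("%s_r%d", s, r)))),
    group = rep(subj_group, each = reps),
    subject = rep(subj, each = reps),
    replicate = rep(seq_len(reps), times = length(subj)),
    stringsAsFactors = FALSE
  )
  n_subj <- length(subj)
  n_samp <- nrow(metadata)
  scale_bias <- stats::rnorm(n_subj, 0, config$sample_scale_sd)

  # peptide layout
  rng <- config$peptides_per_protein_range
  n_pep_per_prot <- sample.int(rng[2] - rng[1] + 1L, n_prot, replace = TRUE) +
    rng[1] - 1L
  pep_protein_idx <- rep(seq_len(n_prot), times = n_pep_per_prot)
  n_pep <- length(pep_protein_idx)
  peptide_ids <- sprintf("pep%05d", seq_len(n_pep))
  map <- data.frame(peptide_id = peptide_ids,
                    protein_id = protein_ids[pep_protein_idx],
                    stringsAsFactors = FALSE)
  if (config$shared_peptide_fraction > 0 && n_prot > 1) {
    n_shared <- max(1L, round(config$shared_peptide_fraction * n_pep))
    shared <- sample.int(n_pep, n_shared)
    second <- vapply(pep_protein_idx[shared], function(p) {
      sample(setdiff(seq_len(n_prot), p), 1L)
    }, integer(1))
    map <- rbind(map, data.frame(peptide_id = peptide_ids[shared],
                                 protein_id = protein_ids[second],
                                 stringsAsFactors = FALSE))
  }

  protein_base <- stats::rnorm(n_prot, 18, 2)
  peptide_offset <- stats::rnorm(n_pep, 0, 1.5)
  fraction_offset <- matrix(stats::rnorm(n_pep * config$n_fractions, 0, 1),
                            nrow = n_pep)

  # latent log2 abundance for every (peptide, fraction, sample) cell
  n_frac <- config$n_fractions
  rec_pep <- rep(seq_len(n_pep), each = n_frac * n_samp)
  rec_frac <- rep(rep(seq_len(n_frac), each = n_samp), times = n_pep)
  rec_samp <- rep(seq_len(n_samp), times = n_pep * n_frac)
  rec_subj <- match(metadata$subject[rec_samp], subj)
  rec_group2 <- metadata$group[rec_samp] == groups[2]

  latent <- protein_base[pep_protein_idx[rec_pep]] +
    peptide_offset[rec_pep] +
    fraction_offset[cbind(rec_pep, rec_frac)] +
    ifelse(rec_group2, direction[pep_protein_idx[rec_pep]] * config$de_log2fc, 0) +
    scale_bias[rec_subj]
  noise <- stats::rnorm(length(latent), 0, config$noise_sd)

  if (is.infinite(config$missingness_midpoint)) {
    p_retain <- if (config$missingness_midpoint > 0) 0 else 1
  } else {
    p_retain <- stats::plogis((latent - config$missingness_midpoint) /
                                config$missingness_slope)
  }
  pass <- stats::runif(length(latent)) < p_retain
  qvalue <- ifelse(pass, 1e-4, 1e-2)
  # failed identifications keep a peak area, but a noisier one
  extra_noise <- ifelse(pass, 0, stats::rnorm(length(latent), 0, 1))
  peak_area <- 2 ^ (latent + noise + extra_noise)

  peptides <- data.frame(
    peptide_id = peptide_ids[rec_pep],
    sample_id = metadata$sample_id[rec_samp],
    fraction = rec_frac,
    peak_area = peak_area,
    qvalue = qvalue,
    stringsAsFactors = FALSE
  )
  truth <- list(
    proteins = data.frame(protein_id = protein_ids, is_de = is_de,
                          direction = direction,
                          log2fc = ifelse(is_de, direction * config$de_log2fc, 0),
                          cell_type = cell_type, stringsAsFactors = FALSE),
    samples = data.frame(sample_id = metadata$sample_id,
                         group = metadata$group,
                         scale_bias = scale_bias[match(metadata$subject, subj)],
                         stringsAsFactors = FALSE)
  )
  list(peptides = peptides, metadata = metadata, map = map, truth = truth)
}

#' Simulate a rooted ontology DAG with nested gene sets
#'
#' Builds a random rooted directed acyclic graph of annotation terms in
#' which every child term's gene set is a subset of the union of its
#' parents' gene sets, mirroring the annotation-propagation property of
#' curated ontologies. Term sizes span values below and above the usual
#' minimum-size filter of 5.
#'
#' @param n_terms Number of terms (>= 3), including the root.
#' @param max_depth Maximum depth below the root; `1` gives a star graph.
#' @param n_genes Size of the gene universe annotated at the root.
#' @param seed Random seed.
#'
#' @return A list with `terms` (data.frame: `term_id`, `name`, `namespace`),
#'   `edges` (data.frame: `parent`, `child`), and `sets` (named list of
#'   gene-symbol vectors, one per term).
#' @export
simulate_ontology <- function(n_terms = 30L, max_depth = 3L,
                              n_genes = 200L, seed = 1L) {
  if (n_terms < 3L) stop("n_terms must be >= 3")
  stopifnot(max_depth >= 1L)
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  term_ids <- sprintf("T:%04d", seq_len(n_terms))
  depth <- c(0L, sample.int(max_depth, n_terms - 1L, replace = TRUE))
  sets <- vector("list", n_terms)
  names(sets) <- term_ids
  sets[[1L]] <- genes
  edges_parent <- character(0)
  edges_child <- character(0)
  for (i in 2:n_terms) {
    candidates <- which(depth < depth[i] & seq_len(n_terms) < i)
    if (length(candidates) == 0L) candidates <- 1L
    n_par <- min(length(candidates), sample.int(2L, 1L))
    parents <- if (length(candidates) == 1L) candidates else
      sample(candidates, n_par)
    pool <- unique(unlist(sets[parents]))
    # sizes deliberately span the min-size filter boundary
    size <- min(length(pool), sample.int(max(2L, length(pool) %/% 2L), 1L) + 1L)
    sets[[i]] <- sort(sample(pool, size))
    edges_parent <- c(edges_parent, term_ids[parents])
    edges_child <- c(edges_child, rep(term_ids[i], length(parents)))
  }
  list(
    terms = data.frame(term_id = term_ids,
                       name = paste("term", seq_len(n_terms)),
                       namespace = "BP", stringsAsFactors = FALSE),
    edges = data.frame(parent = edges_parent, child = edges_child,
                       stringsAsFactors = FALSE),
    sets = sets
  )
}
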