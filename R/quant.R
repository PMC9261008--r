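#' Quality-value filtering of fraction-resolved peptide measurements
#'
#' Applies the presence filter per (peptide, fraction) stratum. A stratum is
#' retained when the share of samples whose measurement passes the quality
#' cut (`qvalue <= qcut`) reaches `presence`; samples without any record for
#' the stratum count as failing. In `"global"` mode the share is taken over
#' all samples; in `"pairwise"` mode the stratum is kept when the share
#' within at least one of the two conditions reaches `presence`. Inside a
#' retained stratum, measurements that fail the cut are removed (treated as
#' missing downstream).
#'
#' @param table Peptide table: data.frame with columns `peptide_id`,
#'   `sample_id`, `fraction`, `peak_area`, `qvalue`.
#' @param metadata Sample metadata with columns `sample_id` and the
#'   condition column named by `condition`.
#' @param mode `"global"` or `"pairwise"`. Pairwise requires exactly two
#'   conditions.
#' @param qcut Quality-value cut-off (default 1e-3).
#' @param presence Required share of passing samples (inclusive; default
#'   0.5).
#' @param condition Name of the metadata column holding condition labels.
#'
#' @return The filtered peptide table (same columns, subset of rows).
#' @export
filter_peptides <- function(table, metadata, mode = c("pairwise", "global"),
                            qcut = 1e-3, presence = 0.5, condition = "group") {
  mode <- match.arg(mode)
  stopifnot(all(c("peptide_id", "sample_id", "fraction", "peak_area", "qvalue")
                %in% names(table)))
  if (!condition %in% names(metadata)) {
    stop(sprintf("metadata lacks condition column '%s'", condition))
  }
  unknown <- setdiff(unique(table$sample_id), metadata$sample_id)
  if (length(unknown) > 0) {
    stop(sprintf("samples in table but not in metadata: %s",
                 paste(utils::head(unknown, 5), collapse = ", ")))
  }
  conds <- unique(metadata[[condition]])
  if (length(conds) == 0) stop("metadata defines zero conditions")
  if (mode == "pairwise" && length(conds) != 2) {
    stop("pairwise mode requires exactly two conditions")
  }
  stratum <- paste0(table$peptide_id, "::", table$fraction)
  pass <- table$qvalue <= qcut
  cond_of <- metadata[[condition]][match(table$sample_id, metadata$sample_id)]

  if (mode == "global") {
    agg <- rowsum(as.numeric(pass), stratum)
    keep_stratum <- stats::setNames(agg[, 1] / nrow(metadata) >= presence,
                                    rownames(agg))
  } else {
    ind <- vapply(conds, function(cc) as.numeric(pass & cond_of == cc),
                  numeric(nrow(table)))
    agg <- rowsum(ind, stratum)
    n_cond <- vapply(conds, function(cc) sum(metadata[[condition]] == cc),
                     numeric(1))
    shares <- sweep(agg, 2, n_cond, "/")
    keep_stratum <- stats::setNames(apply(shares >= presence, 1, any),
                                    rownames(agg))
  }
  keep <- keep_stratum[stratum] & pass
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a (peptide, fraction) x sample abundance matrix
#'
#' Spreads a long peptide table into a rectangular matrix whose rows are
#' `peptide_id` / `fraction` combinations and whose columns are samples.
#' Absent measurements become `NA`.
#'
#' @param table A (typically filtered) peptide table.
#' @param samples Optional character vector fixing the column order;
#'   defaults to the sorted samples present in the table.
#' @param log2 Return log2 peak areas (default) or linear values.
#'
#' @return A numeric matrix with rownames `"<peptide_id>::<fraction>"`.
#' @export
fraction_matrix <- function(table, samples = NULL, log2 = TRUE) {
  if (is.null(samples)) samples <- sort(unique(table$sample_id))
  rows <- paste0(table$peptide_id, "::", table$fraction)
  urows <- sort(unique(rows))
  m <- matrix(NA_real_, nrow = length(urows), ncol = length(samples),
              dimnames = list(urows, samples))
  m[cbind(match(rows, urows), match(table$sample_id, samples))] <- table$peak_area
  if (log2) m <- base::log2(m)
  m
}

#' Fast cyclic loess normalization of a log2 abundance matrix
#'
#' Removes intensity-dependent between-sample bias: on each pass every
#' sample column is loess-adjusted against the row-mean reference column
#' (M = sample - reference against A = (sample + reference) / 2, fitted M
#' subtracted). Missing entries are ignored during fitting and remain
#' missing. The fit itself is delegated to
#' [limma::normalizeCyclicLoess()] with `method = "fast"`.
#'
#' @param x Log2-scale matrix, features x samples.
#' @param iterations Number of cyclic passes (default 3).
#' @param span Loess smoothing span (default 0.7).
#'
#' @return The normalized matrix, log2 scale, same dimnames and NA mask.
#' @export
normalize_cyclic_loess <- function(x, iterations = 3, span = 0.7) {
  stopifnot(is.matrix(x))
  if (ncol(x) < 2) {
    warning("single-sample matrix: normalization is the identity")
    return(x)
  }
  all_missing <- rowSums(!is.na(x)) == 0
  if (any(all_missing)) {
    warning(sprintf("dropping %d all-missing rows", sum(all_missing)))
    x <- x[!all_missing, , drop = FALSE]
  }
  out <- limma::normalizeCyclicLoess(x, span = span, iterations = iterations,
                                     method = "fast")
  dimnames(out) <- dimnames(x)
  out
}

# shared top-k sum rollup: rows of `x` (linear scale) are grouped by
# `groups`; within each group the k rows with highest cross-sample mean are
# selected once, then summed per sample with NA contributing 0.  A group
# whose selected rows are all NA in a sample stays NA there.  Ties in the
# mean are broken by row name for determinism.
topk_rollup <- function(x, groups, k, selection = c("global", "per_sample")) {
  selection <- match.arg(selection)
  stopifnot(is.matrix(x), length(groups) == nrow(x))
  split_idx <- split(seq_len(nrow(x)), groups)
  out <- matrix(NA_real_, nrow = length(split_idx), ncol = ncol(x),
                dimnames = list(names(split_idx), colnames(x)))
  for (i in seq_along(split_idx)) {
    rows <- split_idx[[i]]
    sub <- x[rows, , drop = FALSE]
    if (selection == "global") {
      means <- rowMeans(sub, na.rm = TRUE)
      means[is.nan(means)] <- -Inf
      ord <- order(-means, rownames(sub))
      sel <- sub[ord[seq_len(min(k, nrow(sub)))], , drop = FALSE]
      vals <- colSums(sel, na.rm = TRUE)
      vals[colSums(!is.na(sel)) == 0] <- NA_real_
    } else {
      vals <- apply(sub, 2, function(col) {
        obs <- col[!is.na(col)]
        if (length(obs) == 0) return(NA_real_)
        sum(sort(obs, decreasing = TRUE)[seq_len(min(k, length(obs)))])
      })
    }
    out[i, ] <- vals
  }
  out
}

#' Roll fractions up to peptide abundances
#'
#' For each peptide, selects the `k` fractions with the highest mean linear
#' abundance across samples (one global choice per peptide) and sums their
#' linear values per sample. A selected-but-missing fraction contributes 0;
#' a peptide with every selected fraction missing in a sample is missing
#' there. Peptides with no retained fractions are absent from the output.
#'
#' @param x Matrix from [fraction_matrix()] with rownames
#'   `"<peptide_id>::<fraction>"`; log2 scale by default.
#' @param k Number of top fractions to sum (default 2).
#' @param input_scale `"log2"` (default) or `"linear"`.
#' @param selection `"global"` (one fraction choice per peptide, default) or
#'   `"per_sample"` (top-k re-selected within each sample).
#'
#' @return Peptide x sample matrix of linear abundances.
#' @export
rollup_fractions <- function(x, k = 2, input_scale = c("log2", "linear"),
                             selection = c("global", "per_sample")) {
  input_scale <- match.arg(input_scale)
  lin <- if (input_scale == "log2") 2 ^ x else x
  peptide <- sub("::[^:]*$", "", rownames(lin))
  topk_rollup(lin, peptide, k, selection = match.arg(selection))
}

#' Roll peptides up to protein abundances
#'
#' For each protein, selects the `k` peptides with the highest mean linear
#' abundance across samples and sums their linear values per sample
#' (missing selected values contribute 0; all-missing stays missing).
#'
#' @param x Peptide x sample matrix of linear abundances.
#' @param map data.frame with columns `peptide_id`, `protein_id`. Every row
#'   of `x` must be mapped.
#' @param k Number of top peptides to sum (default 5).
#' @param shared `"error"` (default: a peptide mapped to several proteins
#'   aborts), `"drop"` (shared peptides are removed) or `"assign_all"`
#'   (shared peptides count towards every mapped protein).
#' @param selection Passed to the top-k rule; see [rollup_fractions()].
#'
#' @return Protein x sample matrix of linear abundances.
#' @export
rollup_proteins <- function(x, map, k = 5,
                            shared = c("error", "drop", "assign_all"),
                            selection = c("global", "per_sample")) {
  shared <- match.arg(shared)
  stopifnot(all(c("peptide_id", "protein_id") %in% names(map)))
  unmapped <- setdiff(rownames(x), map$peptide_id)
  if (length(unmapped) > 0) {
    stop(sprintf("unmapped peptides: %s",
                 paste(utils::head(unmapped, 5), collapse = ", ")))
  }
  map <- unique(map[map$peptide_id %in% rownames(x), c("peptide_id", "protein_id")])
  n_prot <- table(map$peptide_id)
  shared_peps <- names(n_prot)[n_prot > 1]
  if (length(shared_peps) > 0) {
    if (shared == "error") {
      stop(sprintf("%d peptides map to multiple proteins (e.g. %s); set shared = 'drop' or 'assign_all'",
                   length(shared_peps), shared_peps[1]))
    }
    if (shared == "drop") {
      map <- map[!map$peptide_id %in% shared_peps, , drop = FALSE]
    }
  }
  if (nrow(map) == 0) stop("no mapped peptides left after shared-peptide policy")
  xx <- x[map$peptide_id, , drop = FALSE]
  topk_rollup(xx, map$protein_id, k, selection = match.arg(selection))
}

#' Average technical replicates into subject-level columns
#'
#' Collapses a sample-level abundance matrix to one column per biological
#' subject by averaging the linear abundances of its technical replicates
#' (ignoring missing values; a subject with every replicate missing stays
#' missing). Differential testing must run on subject-level columns —
#' treating replicates as samples pseudo-replicates the design.
#'
#' @param x Feature x sample matrix, linear scale.
#' @param metadata data.frame with `sample_id`, `subject` and `group`.
#'
#' @return A list with `matrix` (feature x subject) and `metadata` (one row
#'   per subject: `sample_id` = subject id, `group`).
#' @export
collapse_replicates <- function(x, metadata, subject = "subject") {
  stopifnot(all(c("sample_id", subject, "group") %in% names(metadata)))
  metadata <- metadata[match(colnames(x), metadata$sample_id), , drop = FALSE]
  subjects <- unique(metadata[[subject]])
  out <- vapply(subjects, function(s) {
    cols <- x[, metadata[[subject]] == s, drop = FALSE]
    v <- rowMeans(cols, na.rm = TRUE)
    v[rowSums(!is.na(cols)) == 0] <- NA_real_
    v
  }, numeric(nrow(x)))
  out <- matrix(out, nrow = nrow(x),
                dimnames = list(rownames(x), subjects))
  meta <- data.frame(sample_id = subjects,
                     group = metadata$group[match(subjects,
                                                  metadata[[subject]])],
                     stringsAsFactors = FALSE)
  list(matrix = out, metadata = meta)
}

#' Replicate coefficient of variation per protein
#'
#' Within each technical-replicate group, computes CoV = SD / mean of the
#' linear abundances of a protein, then averages over groups; the summary is
#' the median CoV over proteins.
#'
#' @param x Protein x sample matrix, linear scale.
#' @param replicate_groups Named list: group name -> character vector of
#'   sample ids (columns of `x`). Groups of size 1 are skipped with a
#'   warning.
#'
#' @return A list with `per_protein` (named numeric vector of mean CoV per
#'   protein) and `median_cov` (scalar).
#' @export
replicate_cov <- function(x, replicate_groups) {
  sizes <- lengths(replicate_groups)
  if (any(sizes < 2)) {
    warning(sprintf("skipping %d replicate groups of size 1", sum(sizes < 2)))
    replicate_groups <- replicate_groups[sizes >= 2]
  }
  if (length(replicate_groups) == 0) stop("no replicate groups with >= 2 samples")
  covs <- vapply(replicate_groups, function(samps) {
    sub <- x[, samps, drop = FALSE]
    m <- rowMeans(sub, na.rm = TRUE)
    s <- apply(sub, 1, stats::sd, na.rm = TRUE)
    ok <- rowSums(!is.na(sub)) >= 2 & m != 0
    ifelse(ok, s / m, NA_real_)
  }, numeric(nrow(x)))
  covs <- matrix(covs, nrow = nrow(x))
  per_protein <- rowMeans(covs, na.rm = TRUE)
  per_protein[is.nan(per_protein)] <- NA_real_
  names(per_protein) <- rownames(x)
  list(per_protein = per_protein,
       median_cov = stats::median(per_protein, na.rm = TRUE))
}

#' Full peptide-to-protein quantification
#'
#' Convenience wrapper chaining the quantification stages: quality-value
#' filtering, fast cyclic loess normalization of log2 peptide-fraction
#' values, top-k fraction rollup to peptides and top-k peptide rollup to
#' proteins.
#'
#' @inheritParams filter_peptides
#' @param map Peptide-to-protein map.
#' @param k_fractions,k_peptides Top-k parameters of the two rollups.
#' @param loess_iterations,loess_span Cyclic loess parameters.
#' @param normalize_stage `"pre_rollup"` (default: peptide-fraction level
#'   normalization before fraction summation) or `"post_rollup"` (after).
#' @param selection Top-k selection rule, see [rollup_fractions()].
#' @param shared Shared-peptide policy, see [rollup_proteins()].
#'
#' @return A list with `proteins` (protein x sample linear matrix),
#'   `peptides` (peptide x sample linear matrix) and `filtered` (the
#'   filtered peptide table).
#' @export
quantify_proteins <- function(table, metadata, map,
                              mode = c("pairwise", "global"),
                              qcut = 1e-3, presence = 0.5,
                              condition = "group",
                              k_fractions = 2, k_peptides = 5,
                              loess_iterations = 3, loess_span = 0.7,
                              normalize_stage = c("pre_rollup", "post_rollup"),
                              selection = c("global", "per_sample"),
                              shared = c("error", "drop", "assign_all")) {
  normalize_stage <- match.arg(normalize_stage)
  selection <- match.arg(selection)
  filtered <- filter_peptides(table, metadata, mode = match.arg(mode),
                              qcut = qcut, presence = presence,
                              condition = condition)
  fm <- fraction_matrix(filtered, samples = metadata$sample_id, log2 = TRUE)
  if (normalize_stage == "pre_rollup") {
    fm <- normalize_cyclic_loess(fm, iterations = loess_iterations,
                                 span = loess_span)
    pep <- rollup_fractions(fm, k = k_fractions, selection = selection)
  } else {
    pep <- rollup_fractions(fm, k = k_fractions, selection = selection)
    pep_log <- normalize_cyclic_loess(base::log2(pep),
                                      iterations = loess_iterations,
                                      span = loess_span)
    pep <- 2 ^ pep_log
    pep[is.na(pep_log)] <- NA_real_
  }
  prot <- rollup_proteins(pep, map, k = k_peptides,
                          shared = match.arg(shared), selection = selection)
  list(proteins = prot, peptides = pep, filtered = filtered)
}
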