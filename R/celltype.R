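#' Gene-by-cell-type specificity matrix from a labelled single-cell reference
#'
#' Normalizes each cell to its library size, averages the normalized
#' expression per cell type, and converts the type means into proportions:
#' `specificity[g, t] = mean_t(g) / sum_t mean_t(g)`. Rows therefore sum to
#' one, and a gene expressed in a single type has specificity 1 there.
#'
#' @param counts Cell x gene matrix (raw counts or normalized expression).
#' @param labels Character/factor vector of cell-type labels, one per cell.
#' @param exclude_labels Labels removed before computing specificity
#'   (default `"unknown"`). Types left with zero cells are dropped with a
#'   warning.
#'
#' @return Gene x cell-type specificity matrix. Genes with zero total
#'   expression are excluded. The per-gene mean normalized expression
#'   (averaged over types) is attached as attribute `"avg_expr"` for
#'   expression-level-matched bootstrapping.
#' @export
compute_specificity <- function(counts, labels, exclude_labels = "unknown") {
  stopifnot(is.matrix(counts), length(labels) == nrow(counts))
  keep <- !(labels %in% exclude_labels)
  counts <- counts[keep, , drop = FALSE]
  labels <- as.character(labels[keep])
  types <- sort(unique(labels))
  if (length(types) < 2) stop("need at least 2 cell types after exclusion")
  lib <- rowSums(counts)
  if (any(lib == 0)) {
    counts <- counts[lib > 0, , drop = FALSE]
    labels <- labels[lib > 0]
    lib <- lib[lib > 0]
  }
  norm <- counts / lib
  type_mean <- vapply(types, function(t) {
    colMeans(norm[labels == t, , drop = FALSE])
  }, numeric(ncol(counts)))
  total <- rowSums(type_mean)
  nz <- total > 0
  if (any(!nz)) {
    warning(sprintf("excluding %d genes with zero total expression", sum(!nz)))
  }
  spec <- type_mean[nz, , drop = FALSE] / total[nz]
  attr(spec, "avg_expr") <- rowMeans(type_mean[nz, , drop = FALSE])
  spec
}

#' Expression-weighted cell type enrichment by bootstrap
#'
#' Tests whether a target gene list is more specific to each cell type than
#' length-matched random lists drawn from a background. The statistic is
#' the sum of specificity values of the list per cell type; `n_boot` random
#' same-size lists are drawn uniformly without replacement from the
#' background, and the bootstrap tail gives
#' `p = (#\{bootstrap >= observed\} + 1) / (n_boot + 1)`, so p is never
#' exactly 0 — results at the floor are annotated `"< 1/n_boot"`.
#' Benjamini-Hochberg adjustment is applied across cell types.
#'
#' @param target Character vector of gene symbols (>= 5 after matching).
#' @param background Character vector of gene symbols; the sampling
#'   universe. Must contain the target.
#' @param spec Specificity matrix from [compute_specificity()].
#' @param n_boot Number of bootstrap lists (default 20000).
#' @param seed Random seed.
#' @param level_match When `TRUE`, bootstrap lists match the target's
#'   distribution over expression-level deciles (requires the `"avg_expr"`
#'   attribute on `spec`); default `FALSE` (plain uniform lists).
#'
#' @return data.frame, one row per cell type: `cell_type`, `observed`,
#'   `boot_mean`, `boot_sd`, `fold` (observed / bootstrap mean), `z` (SD
#'   from the bootstrap mean), `p`, `p_adj`, `at_floor`, `p_label`.
#' @export
ewce_bootstrap <- function(target, background, spec, n_boot = 20000,
                           seed = 1L, level_match = FALSE) {
  target <- unique(toupper(target))
  background <- unique(toupper(background))
  rn <- toupper(rownames(spec))
  background <- background[background %in% rn]
  if (length(background) == 0) stop("background has no genes in the specificity matrix")
  missing_target <- setdiff(target, background)
  if (length(missing_target) > 0) {
    message(sprintf("dropping %d target genes absent from background/specificity",
                    length(missing_target)))
  }
  target <- intersect(target, background)
  if (length(target) == 0) stop("no target genes left after harmonization")
  if (length(target) < 5) warning("fewer than 5 target genes; enrichment is unstable")

  S <- spec[match(background, rn), , drop = FALSE]
  rownames(S) <- background
  k <- length(target)
  observed <- colSums(S[target, , drop = FALSE])

  set.seed(seed)
  nb <- length(background)
  if (level_match) {
    avg <- attr(spec, "avg_expr")
    if (is.null(avg)) stop("level_match requires the avg_expr attribute on spec")
    avg <- avg[match(background, rn)]
    bins <- cut(rank(avg, ties.method = "first"),
                breaks = 10, labels = FALSE)
    target_bins <- bins[match(target, background)]
    bin_counts <- tabulate(target_bins, nbins = 10)
    by_bin <- split(seq_len(nb), bins)
    draw_idx <- function() {
      unlist(lapply(which(bin_counts > 0), function(b) {
        sample(by_bin[[b]], bin_counts[b])
      }), use.names = FALSE)
    }
  } else {
    draw_idx <- function() sample.int(nb, k)
  }
  boot <- matrix(0, nrow = n_boot, ncol = ncol(S))
  for (b in seq_len(n_boot)) {
    boot[b, ] <- colSums(S[draw_idx(), , drop = FALSE])
  }
  boot_mean <- colMeans(boot)
  boot_sd <- apply(boot, 2, stats::sd)
  p <- (colSums(sweep(boot, 2, observed, ">=")) + 1) / (n_boot + 1)
  at_floor <- p <= 1 / (n_boot + 1)
  data.frame(
    cell_type = colnames(S),
    observed = observed,
    boot_mean = boot_mean,
    boot_sd = boot_sd,
    fold = observed / boot_mean,
    z = (observed - boot_mean) / boot_sd,
    p = p,
    p_adj = stats::p.adjust(p, method = "BH"),
    at_floor = at_floor,
    p_label = ifelse(at_floor, sprintf("< %.2g", 1 / n_boot), sprintf("%.4g", p)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Classify proteins highly enriched for one cell type
#'
#' A protein is called highly enriched for the unique cell type whose
#' specificity reaches `threshold` (default 0.5). With
#' `merge_neurons = TRUE`, the excitatory and inhibitory neuron columns are
#' summed into a single `neuron` column before thresholding, so proteins
#' specific to neurons as a class are captured. With a threshold above 0.5
#' (strictly) at most one type can qualify; at exactly 0.5, or after
#' merging, ties are broken by the larger specificity, then column order.
#'
#' @param spec Specificity matrix (genes x cell types).
#' @param proteins Character vector of protein/gene symbols to classify.
#' @param threshold Specificity threshold (default 0.5, inclusive).
#' @param merge_neurons Sum excitatory + inhibitory specificities first.
#' @param neuron_cols Column names merged when `merge_neurons` is `TRUE`.
#' @param merged_name Name of the merged column.
#'
#' @return Named character vector protein -> cell type; `NA` where no type
#'   reaches the threshold. Proteins absent from `spec` are `NA` as well.
#' @export
classify_highly_enriched <- function(spec, proteins, threshold = 0.5,
                                     merge_neurons = FALSE,
                                     neuron_cols = c("excitatory", "inhibitory"),
                                     merged_name = "neuron") {
  rn <- toupper(rownames(spec))
  S <- spec
  if (merge_neurons && all(neuron_cols %in% colnames(S))) {
    merged <- rowSums(S[, neuron_cols, drop = FALSE])
    S <- cbind(S[, setdiff(colnames(S), neuron_cols), drop = FALSE],
               merged)
    colnames(S)[ncol(S)] <- merged_name
  }
  idx <- match(toupper(proteins), rn)
  out <- rep(NA_character_, length(proteins))
  found <- !is.na(idx)
  if (any(found)) {
    sub <- S[idx[found], , drop = FALSE]
    best <- max.col(sub, ties.method = "first")
    best_val <- sub[cbind(seq_len(nrow(sub)), best)]
    out[found] <- ifelse(best_val >= threshold, colnames(S)[best], NA_character_)
  }
  stats::setNames(out, proteins)
}

#' Pooled SD of control-vs-control log2 fold changes
#'
#' Estimates how large apparent fold changes get between groups of control
#' samples by chance: the control samples are split into two balanced
#' halves many times, per-protein log2 ratios of half-means are computed,
#' and the SD is pooled across proteins and splits. The +/- 2 SD band is the
#' reference range of the composition-change diagnostic.
#'
#' @param x Protein x sample matrix, linear scale.
#' @param control_samples Character vector of control sample ids (>= 4).
#' @param n_splits Number of random balanced splits (default 100);
#'   exhaustive enumeration is used when it needs no more splits than that.
#' @param seed Random seed.
#'
#' @return A list with `sd` (pooled SD, log2 units), `n_splits_used`, and
#'   `log2fc` (protein x split matrix of the half-vs-half log2 ratios).
#' @export
ndc_variation_sd <- function(x, control_samples, n_splits = 100, seed = 1L) {
  control_samples <- intersect(control_samples, colnames(x))
  n <- length(control_samples)
  if (n < 4) stop("need at least 4 control samples")
  k <- n %/% 2
  xx <- x[, control_samples, drop = FALSE]
  n_total <- choose(n, k)
  exhaustive <- n_total <= n_splits
  if (exhaustive) {
    combs <- utils::combn(n, k)
    if (n %% 2 == 0) {
      # each split appears twice as a complement pair; keep those with sample 1
      combs <- combs[, combs[1, ] == 1, drop = FALSE]
    }
  } else {
    set.seed(seed)
    combs <- vapply(seq_len(n_splits), function(i) sort(sample.int(n, k)),
                    integer(k))
  }
  lfc <- apply(combs, 2, function(half) {
    m1 <- rowMeans(xx[, half, drop = FALSE], na.rm = TRUE)
    m2 <- rowMeans(xx[, -half, drop = FALSE], na.rm = TRUE)
    base::log2(m1 / m2)
  })
  lfc <- matrix(lfc, nrow = nrow(xx), dimnames = list(rownames(xx), NULL))
  vals <- lfc[is.finite(lfc)]
  list(sd = stats::sd(vals), n_splits_used = ncol(combs), log2fc = lfc)
}

#' Composition-change diagnostic for cell-type protein sets
#'
#' Checks whether apparent cell-type-linked expression changes could be
#' explained by shifts in cell-type proportions: for each cell type's
#' highly-enriched protein set, reports the fraction of log2 fold changes
#' falling inside the control-variation band (+/- `band_sd_mult` times the
#' control SD) and the fraction of significant proteins outside it.
#' Proteins well inside the band behave like the control-only comparison;
#' a set predominantly outside indicates regulation beyond composition
#' change.
#'
#' @param de A `de_result` from [run_de()] (or its `table`).
#' @param assignments Named vector protein -> cell type from
#'   [classify_highly_enriched()].
#' @param sd Pooled control SD from [ndc_variation_sd()] (`$sd`).
#' @param band_sd_mult Width of the band in SD units (default 2).
#' @param alpha q-value threshold used for the "significant" fraction.
#'
#' @return A list with `summary` (data.frame per cell type: `cell_type`,
#'   `n`, `frac_inside`, `n_sig`, `frac_sig_outside`) and `points`
#'   (data.frame per protein: `protein`, `cell_type`, `log2fc`,
#'   `significant`, `inside`), ready for density plots.
#' @export
composition_check <- function(de, assignments, sd, band_sd_mult = 2,
                              alpha = 0.05) {
  tab <- if (inherits(de, "de_result")) de$table else de
  stopifnot(all(c("protein", "fold_change", "q") %in% names(tab)))
  bound <- band_sd_mult * sd
  assigned <- assignments[!is.na(assignments)]
  if (length(assigned) == 0) stop("no proteins assigned to a cell type")
  idx <- match(names(assigned), tab$protein)
  ok <- !is.na(idx)
  points <- data.frame(
    protein = names(assigned)[ok],
    cell_type = unname(assigned[ok]),
    log2fc = base::log2(tab$fold_change[idx[ok]]),
    significant = !is.na(tab$q[idx[ok]]) & tab$q[idx[ok]] < alpha,
    stringsAsFactors = FALSE
  )
  points <- points[is.finite(points$log2fc), , drop = FALSE]
  points$inside <- abs(points$log2fc) <= bound
  summary <- do.call(rbind, lapply(split(points, points$cell_type), function(g) {
    data.frame(cell_type = g$cell_type[1],
               n = nrow(g),
               frac_inside = mean(g$inside),
               n_sig = sum(g$significant),
               frac_sig_outside = if (any(g$significant))
                 mean(!g$inside[g$significant]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(summary = summary, points = points, bound = bound)
}
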