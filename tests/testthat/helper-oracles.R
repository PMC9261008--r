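# Independent brute-force oracles used to cross-check the package
# implementations. These are written as plain loops from the method
# definitions and deliberately share no code with the package.

# SAM oracle: d from the pooled-SE formula per feature, exhaustive balanced
# permutations, pooled-null p, per-threshold median-count q with pi0 from
# the null IQR. Complete data only.
oracle_sam_exhaustive <- function(x, labels, s0) {
  lv <- levels(factor(labels))
  g2_obs <- labels == lv[2]
  n <- ncol(x)
  n2 <- sum(g2_obs)
  d_of <- function(assign2) {
    apply(x, 1, function(row) {
      x1 <- row[!assign2]
      x2 <- row[assign2]
      ss <- sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)
      s <- sqrt((1 / length(x1) + 1 / length(x2)) * ss / (n - 2))
      num <- mean(x2) - mean(x1)
      if (num == 0 && s + s0 == 0) 0 else num / (s + s0)
    })
  }
  combs <- utils::combn(n, n2)
  D <- apply(combs, 2, function(idx) {
    a <- rep(FALSE, n)
    a[idx] <- TRUE
    d_of(a)
  })
  d_obs <- d_of(g2_obs)
  m <- length(d_obs)
  # thresholds relaxed by a relative epsilon, mirroring the tie convention:
  # assignments tying the observed |d| mathematically count as >=
  relax <- function(t) t * (1 - 1e-9)
  pool <- abs(as.vector(D))
  p <- vapply(abs(d_obs), function(t) mean(pool >= relax(t)), numeric(1))
  qs <- stats::quantile(as.vector(D), c(0.25, 0.75), names = FALSE)
  pi0 <- min(1, sum(d_obs >= qs[1] & d_obs <= qs[2]) / (0.5 * m))
  qv <- vapply(seq_len(m), function(i) {
    t <- relax(abs(d_obs)[i])
    med <- stats::median(apply(D, 2, function(col) sum(abs(col) >= t)))
    min(1, pi0 * med / sum(abs(d_obs) >= t))
  }, numeric(1))
  ord <- order(abs(d_obs), decreasing = TRUE)
  qq <- qv[ord]
  if (m > 1) for (j in rev(seq_len(m - 1))) qq[j] <- min(qq[j], qq[j + 1])
  qv[ord] <- qq
  list(d = unname(d_obs), p = unname(p), q = unname(qv), pi0 = pi0,
       n_assignments = ncol(combs))
}

# sort-slice-sum reference for top-k rollup of a linear matrix grouped by
# `groups`; global mean-based selection, ties by row name.
oracle_topk_rollup <- function(x, groups, k) {
  out <- NULL
  ids <- sort(unique(groups))
  for (g in ids) {
    sub <- x[groups == g, , drop = FALSE]
    mns <- apply(sub, 1, function(r) {
      if (all(is.na(r))) -Inf else mean(r, na.rm = TRUE)
    })
    sub <- sub[order(-mns, rownames(sub)), , drop = FALSE]
    sub <- sub[seq_len(min(k, nrow(sub))), , drop = FALSE]
    row <- numeric(ncol(x))
    for (j in seq_len(ncol(x))) {
      vals <- sub[, j]
      row[j] <- if (all(is.na(vals))) NA_real_ else sum(vals, na.rm = TRUE)
    }
    out <- rbind(out, row)
  }
  dimnames(out) <- list(ids, colnames(x))
  out
}

# presence-filter oracle: plain loops over every (peptide, fraction)
# stratum and condition.
oracle_filter <- function(table, metadata, mode, qcut, presence,
                          condition = "group") {
  conds <- unique(metadata[[condition]])
  keep_rows <- logical(nrow(table))
  for (pep in unique(table$peptide_id)) {
    for (fr in unique(table$fraction[table$peptide_id == pep])) {
      rows <- which(table$peptide_id == pep & table$fraction == fr)
      pass_samples <- table$sample_id[rows][table$qvalue[rows] <= qcut]
      if (mode == "global") {
        ok <- length(pass_samples) / nrow(metadata) >= presence
      } else {
        ok <- FALSE
        for (cc in conds) {
          cs <- metadata$sample_id[metadata[[condition]] == cc]
          if (length(intersect(pass_samples, cs)) / length(cs) >= presence) {
            ok <- TRUE
          }
        }
      }
      if (ok) keep_rows[rows[table$qvalue[rows] <= qcut]] <- TRUE
    }
  }
  out <- table[keep_rows, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# closed-form hypergeometric upper tail via binomial coefficients
oracle_hyper_p <- function(overlap, size, N, n) {
  ks <- overlap:min(size, n)
  sum(choose(size, ks) * choose(N - size, n - ks)) / choose(N, n)
}

# brute-force best-per-parent: for every parent with significant children,
# mark its minimum-p child (ties: larger overlap, then smaller id);
# significant parentless terms are kept.
oracle_best_per_parent <- function(results, edges, alpha) {
  sig <- results[!is.na(results$p_adj) & results$p_adj < alpha, , drop = FALSE]
  kept <- character(0)
  for (tid in sig$term_id) {
    pars <- edges$parent[edges$child == tid]
    if (length(pars) == 0) {
      kept <- c(kept, tid)
      next
    }
    for (pa in pars) {
      sibs <- edges$child[edges$parent == pa]
      cand <- sig[sig$term_id %in% sibs, , drop = FALSE]
      best <- cand$term_id[order(cand$p, -cand$overlap, cand$term_id)][1]
      if (best == tid) kept <- c(kept, tid)
    }
  }
  sort(unique(kept))
}

# reachability-based subtree membership oracle
oracle_subtree_members <- function(target, edges, sets, root) {
  reach <- root
  repeat {
    nxt <- unique(edges$child[edges$parent %in% reach])
    nxt <- setdiff(nxt, reach)
    if (length(nxt) == 0) break
    reach <- c(reach, nxt)
  }
  genes <- unique(unlist(sets[names(sets) %in% reach]))
  sort(intersect(target, genes))
}

# exact EWCE tail by subset enumeration (small backgrounds only)
oracle_ewce_exact <- function(target, background, spec) {
  k <- length(target)
  S <- spec[background, , drop = FALSE]
  obs <- colSums(S[target, , drop = FALSE])
  combs <- utils::combn(length(background), k)
  stats <- apply(combs, 2, function(idx) colSums(S[idx, , drop = FALSE]))
  stats <- matrix(stats, nrow = ncol(S))
  list(observed = obs,
       p_exact = rowMeans(stats >= obs),
       mean_exact = rowMeans(stats))
}

# small complete-data cohort helper used across test files
make_protein_matrix <- function(n_prot, n_per_group, effect_idx_up = integer(0),
                                effect_idx_dn = integer(0), log2fc = 2,
                                noise_sd = 0.3, base = 20, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  # per-protein baseline shared across samples; per-entry measurement noise
  x <- matrix(stats::rnorm(n_prot, base, 1), n_prot, n,
              dimnames = list(sprintf("p%04d", seq_len(n_prot)),
                              sprintf("s%02d", seq_len(n))))
  x <- x + matrix(stats::rnorm(n_prot * n, 0, noise_sd), n_prot, n)
  grp2 <- (n_per_group + 1):n
  x[effect_idx_up, grp2] <- x[effect_idx_up, grp2] + log2fc
  x[effect_idx_dn, grp2] <- x[effect_idx_dn, grp2] - log2fc
  list(log2 = x, linear = 2 ^ x,
       labels = factor(rep(c("NDC", "FTD"), each = n_per_group),
                       levels = c("NDC", "FTD")))
}
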