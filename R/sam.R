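#' SAM moderated t-statistics for a two-group comparison
#'
#' Computes the SAM relative difference for every feature:
#' `d_i = (mean2_i - mean1_i) / (s_i + s0)`, where `s_i` is the pooled
#' two-sample standard error
#' `sqrt((1/n1 + 1/n2) * (SS1 + SS2) / (n1 + n2 - 2))`
#' and `s0` is the exchangeability ("fudge") factor. By default `s0` is
#' chosen by the Tusher search: among the percentiles 0, 5, ..., 100 of the
#' `s_i`, pick the candidate minimizing the coefficient of variation of the
#' median absolute deviation of `d` computed within windows of `s`
#' quantiles. Missing values are handled pairwise-complete per feature;
#' features with fewer than two observed values in either group are
#' reported as untested (`NA` statistics).
#'
#' @param x Log2-scale feature x sample matrix.
#' @param labels Factor (or coercible) of length `ncol(x)` with exactly two
#'   levels; the first level is the reference, so positive `d` means higher
#'   abundance in the second level.
#' @param s0 `NULL` (default: Tusher search) or a fixed non-negative number.
#'
#' @return A list with `d`, `s` (numeric vectors named by feature), `s0`
#'   (scalar), `tested` (logical vector), and `mean_diff` (mean2 - mean1).
#' @export
sam_statistics <- function(x, labels, s0 = NULL) {
  stopifnot(is.matrix(x))
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two levels")
  if (length(labels) != ncol(x)) stop("labels must match columns of x")
  g2 <- labels == levels(labels)[2]
  st <- sam_moments(x, g2)
  tested <- st$n1 >= 2 & st$n2 >= 2
  if (any(!tested)) {
    message(sprintf("%d features untested (fewer than 2 observations per group)",
                    sum(!tested)))
  }
  s <- ifelse(tested, st$s, NA_real_)
  diff <- ifelse(tested, st$diff, NA_real_)
  if (is.null(s0)) {
    s0 <- tusher_s0(diff[tested], s[tested])
  } else {
    stopifnot(is.numeric(s0), length(s0) == 1, s0 >= 0)
  }
  d <- diff / (s + s0)
  d[!is.na(diff) & diff == 0 & (s + s0) == 0] <- 0
  names(d) <- names(s) <- rownames(x)
  list(d = d, s = s, s0 = s0, tested = stats::setNames(tested, rownames(x)),
       mean_diff = stats::setNames(diff, rownames(x)))
}

# Pairwise-complete group moments for one group assignment (logical g2).
# Returns per-feature counts, mean difference, and pooled-SE term s.
sam_moments <- function(x, g2) {
  obs <- !is.na(x)
  x0 <- x
  x0[!obs] <- 0
  n1 <- rowSums(obs[, !g2, drop = FALSE])
  n2 <- rowSums(obs[, g2, drop = FALSE])
  sum1 <- rowSums(x0[, !g2, drop = FALSE])
  sum2 <- rowSums(x0[, g2, drop = FALSE])
  ss1 <- rowSums(x0[, !g2, drop = FALSE] ^ 2)
  ss2 <- rowSums(x0[, g2, drop = FALSE] ^ 2)
  m1 <- sum1 / n1
  m2 <- sum2 / n2
  within1 <- ss1 - n1 * m1 ^ 2
  within2 <- ss2 - n2 * m2 ^ 2
  df <- n1 + n2 - 2
  s <- sqrt(pmax(0, (1 / n1 + 1 / n2) * (within1 + within2) / df))
  list(n1 = n1, n2 = n2, diff = m2 - m1, s = s)
}

# Tusher fudge-factor search: candidates are the 0,5,...,100 percentiles of
# s; the winner minimizes the CV of window-wise MADs of d, with windows
# delimited by s quantiles (percentile windows when enough features,
# quartile windows otherwise).
tusher_s0 <- function(diff, s, probs = seq(0, 1, by = 0.05)) {
  m <- length(s)
  if (m < 2 || all(s == 0)) return(if (m > 0) stats::median(s) else 0)
  cand <- unique(stats::quantile(s, probs, names = FALSE, type = 7))
  n_win <- if (m >= 500) 100L else if (m >= 100) 20L else 4L
  breaks <- unique(stats::quantile(s, seq(0, 1, length.out = n_win + 1L),
                                   names = FALSE))
  win <- cut(s, breaks, include.lowest = TRUE)
  cv <- vapply(cand, function(a) {
    dd <- diff / (s + a)
    v <- tapply(dd, win, stats::mad)
    v <- v[!is.na(v)]
    if (length(v) < 2 || mean(v) == 0) return(Inf)
    stats::sd(v) / mean(v)
  }, numeric(1))
  if (all(!is.finite(cv))) return(stats::median(s))
  cand[which.min(cv)]
}

# All (or a seeded random subset of) distinct assignments of samples to
# group 2, returned as an n x B logical matrix. The observed assignment is
# always column 1. Exhaustive when choose(n, n2) <= n_perm.
permutation_assignments <- function(g2, n_perm, seed) {
  n <- length(g2)
  n2 <- sum(g2)
  n_distinct <- choose(n, n2)
  if (n_distinct <= n_perm) {
    combs <- utils::combn(n, n2)
    P <- matrix(FALSE, nrow = n, ncol = ncol(combs))
    P[cbind(as.vector(combs), rep(seq_len(ncol(combs)), each = n2))] <- TRUE
    obs_col <- which(colSums(P == g2) == n)[1]
    P <- cbind(P[, obs_col], P[, -obs_col, drop = FALSE])
    attr(P, "exhaustive") <- TRUE
    return(P)
  }
  set.seed(seed)
  seen <- new.env(hash = TRUE)
  cols <- vector("list", n_perm)
  cols[[1]] <- which(g2)
  assign(paste(which(g2), collapse = ","), TRUE, envir = seen)
  filled <- 1L
  while (filled < n_perm) {
    cand <- sort(sample.int(n, n2))
    key <- paste(cand, collapse = ",")
    if (!exists(key, envir = seen, inherits = FALSE)) {
      filled <- filled + 1L
      cols[[filled]] <- cand
      assign(key, TRUE, envir = seen)
    }
  }
  P <- matrix(FALSE, nrow = n, ncol = n_perm)
  for (b in seq_len(n_perm)) P[cols[[b]], b] <- TRUE
  attr(P, "exhaustive") <- FALSE
  P
}

# d statistics for every assignment column of P (n x B logical), sharing
# one s0. Fully vectorized via cross-products; features with < 2
# observations in either group for a given assignment get NA.
sam_d_matrix <- function(x, P, s0) {
  obs <- !is.na(x)
  x0 <- x
  x0[!obs] <- 0
  x2 <- x0 ^ 2
  P1 <- (!P) * 1
  P2 <- P * 1
  n1 <- obs %*% P1
  n2 <- obs %*% P2
  m1 <- (x0 %*% P1) / n1
  m2 <- (x0 %*% P2) / n2
  within <- (x2 %*% P1) - n1 * m1 ^ 2 + (x2 %*% P2) - n2 * m2 ^ 2
  s <- sqrt(pmax(0, (1 / n1 + 1 / n2) * within / (n1 + n2 - 2)))
  d <- (m2 - m1) / (s + s0)
  d[is.nan(d)] <- 0
  d[n1 < 2 | n2 < 2] <- NA_real_
  d
}

#' Permutation p-values and FDR q-values for SAM statistics
#'
#' Builds the null distribution of `d` from balanced label permutations:
#' exhaustive when the number of distinct assignments does not exceed
#' `n_perm`, otherwise a seeded uniform random draw of distinct assignments
#' without replacement. The permutation p-value of feature `i` is the
#' proportion of the pooled (across features and permutations) null `|d|`
#' values at least `|d_i|`. The q-value at threshold `|d_i|` is
#' `pi0 * median_b #\{null |d_b| >= |d_i|\} / #\{observed |d| >= |d_i|\}`,
#' clipped to [0, 1] and made monotone non-increasing in `|d|`; `pi0` is
#' estimated from the share of observed `d` inside the interquartile range
#' of the pooled null (divided by 0.5, capped at 1).
#'
#' @inheritParams sam_statistics
#' @param n_perm Number of permutations (default 1000). A warning is issued
#'   below 100; when fewer than 10 distinct assignments exist, exhaustive
#'   enumeration is used regardless.
#' @param seed Seed for the random permutation draw.
#'
#' @return A list with `d`, `s`, `s0`, `p`, `q` (named vectors; untested
#'   features are `NA`), `pi0`, `n_perm_used`, and `exhaustive` (logical).
#' @export
permutation_fdr <- function(x, labels, n_perm = 1000, seed = 1L, s0 = NULL) {
  if (n_perm < 100) warning("n_perm < 100 gives unstable q-values")
  labels <- as.factor(labels)
  obs_stat <- sam_statistics(x, labels, s0 = s0)
  g2 <- labels == levels(labels)[2]
  P <- permutation_assignments(g2, n_perm = n_perm, seed = seed)
  exhaustive <- attr(P, "exhaustive")
  D <- sam_d_matrix(x, P, obs_stat$s0)
  d_obs <- obs_stat$d
  tested <- obs_stat$tested

  # the null pool spans every assignment, the observed one included (the
  # canonical SAM construction; its contribution vanishes as 1/n_perm)
  null_d <- D
  pooled <- abs(null_d[!is.na(null_d)])
  sorted_pool <- sort(pooled)
  abs_obs <- abs(d_obs)
  # thresholds are relaxed by a 1e-9 relative epsilon so that assignments
  # whose |d| ties the observed one mathematically (e.g. the complement
  # assignment) count as >= despite floating-point noise
  relax <- function(t) t * (1 - 1e-9)
  p <- rep(NA_real_, length(d_obs))
  ok <- tested & !is.na(abs_obs)
  p[ok] <- (length(sorted_pool) -
              findInterval(relax(abs_obs[ok]), sorted_pool, left.open = TRUE)) /
    length(sorted_pool)

  # pi0 from the IQR of the pooled null (signed d values)
  null_signed <- null_d[!is.na(null_d)]
  qs <- stats::quantile(null_signed, c(0.25, 0.75), names = FALSE)
  m_tested <- sum(ok)
  pi0 <- min(1, sum(d_obs[ok] >= qs[1] & d_obs[ok] <= qs[2]) / (0.5 * m_tested))

  # q-values: per-threshold median null count over permutations
  q <- rep(NA_real_, length(d_obs))
  if (m_tested > 0) {
    thr <- abs_obs[ok]
    B <- ncol(null_d)
    counts <- matrix(0, nrow = m_tested, ncol = B)
    for (b in seq_len(B)) {
      v <- sort(abs(null_d[, b][!is.na(null_d[, b])]))
      counts[, b] <- length(v) - findInterval(relax(thr), v, left.open = TRUE)
    }
    med_null <- apply(counts, 1, stats::median)
    obs_count <- vapply(thr, function(t) sum(abs_obs[ok] >= relax(t)),
                        numeric(1))
    qi <- pmin(1, pmax(0, pi0 * med_null / obs_count))
    # monotone non-increasing in |d|
    ord <- order(thr, decreasing = TRUE)
    qi_sorted <- qi[ord]
    for (j in rev(seq_len(m_tested - 1))) {
      qi_sorted[j] <- min(qi_sorted[j], qi_sorted[j + 1])
    }
    qi[ord] <- qi_sorted
    q[ok] <- qi
  }
  names(p) <- names(q) <- names(d_obs)
  list(d = d_obs, s = obs_stat$s, s0 = obs_stat$s0, p = p, q = q,
       pi0 = pi0, n_perm_used = ncol(null_d), exhaustive = exhaustive,
       tested = tested, mean_diff = obs_stat$mean_diff)
}

#' Per-protein fold changes between two conditions
#'
#' Ratio of group means on the linear scale (second level over first), or
#' optionally the exponentiated difference of mean log2 abundances.
#'
#' @param x Linear-scale feature x sample matrix.
#' @param labels Two-level factor over columns; first level is the
#'   reference (denominator).
#' @param method `"mean_ratio"` (default) or `"log_mean"`.
#'
#' @return Named numeric vector of fold changes; a zero or missing
#'   reference mean yields `NA`.
#' @export
fold_changes <- function(x, labels, method = c("mean_ratio", "log_mean")) {
  method <- match.arg(method)
  labels <- as.factor(labels)
  stopifnot(nlevels(labels) == 2, length(labels) == ncol(x))
  g2 <- labels == levels(labels)[2]
  if (method == "mean_ratio") {
    m1 <- rowMeans(x[, !g2, drop = FALSE], na.rm = TRUE)
    m2 <- rowMeans(x[, g2, drop = FALSE], na.rm = TRUE)
    fc <- m2 / m1
    fc[!is.finite(fc) | m1 == 0] <- NA_real_
  } else {
    lx <- base::log2(x)
    m1 <- rowMeans(lx[, !g2, drop = FALSE], na.rm = TRUE)
    m2 <- rowMeans(lx[, g2, drop = FALSE], na.rm = TRUE)
    fc <- 2 ^ (m2 - m1)
    fc[!is.finite(fc)] <- NA_real_
  }
  stats::setNames(fc, rownames(x))
}

#' Two-group differential expression with permutation FDR
#'
#' Runs the full differential-expression stage on a linear-scale protein
#' matrix: log2 transform, SAM statistics, permutation p/q values and fold
#' changes, and splits significant proteins into higher and lower expressed
#' relative to the reference condition.
#'
#' @param x Protein x sample matrix, linear scale.
#' @param labels Two-level factor over columns (first level = reference).
#' @param alpha q-value significance threshold (default 0.05).
#' @param n_perm,seed,s0 Passed to [permutation_fdr()].
#' @param fc_method Passed to [fold_changes()].
#'
#' @return A list of class `de_result` with `table` (data.frame: `protein`,
#'   `fold_change`, `d`, `s`, `p`, `q`, `significant`, `direction`,
#'   `tested`), `higher` / `lower` (character vectors of significant
#'   proteins), `s0`, `pi0`, `alpha` and `labels`.
#' @export
run_de <- function(x, labels, alpha = 0.05, n_perm = 1000, seed = 1L,
                   s0 = NULL, fc_method = "mean_ratio") {
  stopifnot(all(x > 0 | is.na(x)))
  lx <- base::log2(x)
  pf <- permutation_fdr(lx, labels, n_perm = n_perm, seed = seed, s0 = s0)
  fc <- fold_changes(x, labels, method = fc_method)
  sig <- !is.na(pf$q) & pf$q < alpha
  tab <- data.frame(
    protein = rownames(x),
    fold_change = fc,
    d = pf$d, s = pf$s, p = pf$p, q = pf$q,
    significant = sig,
    direction = ifelse(sig & fc > 1, "higher",
                       ifelse(sig & fc < 1, "lower", NA_character_)),
    tested = pf$tested,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(
    table = tab,
    higher = tab$protein[sig & !is.na(fc) & fc > 1],
    lower = tab$protein[sig & !is.na(fc) & fc < 1],
    s0 = pf$s0, pi0 = pf$pi0, alpha = alpha,
    labels = labels, exhaustive = pf$exhaustive
  ), class = "de_result")
}
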