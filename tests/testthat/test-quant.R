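make_toy_table <- function(qvals, samples, fractions = 1) {
  # qvals: named list sample -> vector over fractions
  do.call(rbind, lapply(samples, function(s) {
    data.frame(peptide_id = "pepA", sample_id = s,
               fraction = seq_len(fractions),
               peak_area = 100, qvalue = qvals[[s]],
               stringsAsFactors = FALSE)
  }))
}

test_that("pairwise presence threshold is inclusive at the 50% boundary", {
  meta <- data.frame(sample_id = c("n1", "n2", "f1", "f2"),
                     group = c("NDC", "NDC", "FTD", "FTD"))
  # passes in exactly 1 of 2 NDC samples, fails everywhere else
  tab <- make_toy_table(list(n1 = 1e-4, n2 = 1e-2, f1 = 1e-2, f2 = 1e-2),
                        meta$sample_id)
  out <- filter_peptides(tab, meta, mode = "pairwise")
  expect_equal(out$sample_id, "n1")  # stratum retained, failing rows dropped
  # fails everywhere: removed in both modes
  tab2 <- make_toy_table(list(n1 = 1e-2, n2 = 1e-2, f1 = 1e-2, f2 = 1e-2),
                         meta$sample_id)
  expect_equal(nrow(filter_peptides(tab2, meta, mode = "pairwise")), 0)
  expect_equal(nrow(filter_peptides(tab2, meta, mode = "global")), 0)
})

test_that("filter matches the brute-force oracle on scripted tables", {
  set.seed(21)
  meta <- data.frame(sample_id = sprintf("s%d", 1:6),
                     group = rep(c("NDC", "FTD"), each = 3))
  for (rep_i in 1:5) {
    tab <- expand.grid(peptide_id = sprintf("pep%d", 1:6),
                       sample_id = meta$sample_id,
                       fraction = 1:4, stringsAsFactors = FALSE)
    tab$peak_area <- stats::runif(nrow(tab), 10, 1000)
    tab$qvalue <- sample(c(1e-4, 1e-2), nrow(tab), replace = TRUE)
    for (mode in c("global", "pairwise")) {
      got <- filter_peptides(tab, meta, mode = mode)
      want <- oracle_filter(tab, meta, mode, 1e-3, 0.5)
      key <- function(d) sort(paste(d$peptide_id, d$sample_id, d$fraction))
      expect_identical(key(got), key(want))
    }
  }
})

test_that("filtering is idempotent and errors on bad inputs", {
  set.seed(3)
  meta <- data.frame(sample_id = sprintf("s%d", 1:4),
                     group = rep(c("A", "B"), each = 2))
  tab <- expand.grid(peptide_id = sprintf("pep%d", 1:10),
                     sample_id = meta$sample_id, fraction = 1:2,
                     stringsAsFactors = FALSE)
  tab$peak_area <- 100
  tab$qvalue <- sample(c(1e-4, 1e-2), nrow(tab), replace = TRUE)
  once <- filter_peptides(tab, meta)
  twice <- filter_peptides(once, meta)
  expect_identical(once, twice)
  expect_error(filter_peptides(transform(tab, sample_id = "ghost"), meta),
               "not in metadata")
  meta3 <- data.frame(sample_id = meta$sample_id, group = letters[1:4])
  expect_error(filter_peptides(tab, meta3, mode = "pairwise"),
               "exactly two conditions")
})

test_that("cyclic loess removes planted column shifts and is identity on equal columns", {
  set.seed(5)
  profile <- rnorm(1000, 20, 2)   # shared feature profile across samples
  base <- matrix(profile, 1000, 4) + matrix(rnorm(4000, 0, 0.05), 1000, 4)
  same <- cbind(base[, 1], base[, 1])
  expect_equal(normalize_cyclic_loess(same), same, tolerance = 1e-8)
  shifted <- base
  shifted[, 2] <- shifted[, 2] + 0.8
  norm <- normalize_cyclic_loess(shifted)
  med <- median(norm[, 2] - norm[, 1])
  expect_lt(abs(med), 0.01)
  expect_warning(normalize_cyclic_loess(base[, 1, drop = FALSE]),
                 "single-sample")
})

test_that("cyclic loess leaves the missingness mask untouched", {
  set.seed(6)
  x <- matrix(rnorm(600, 20, 2), 150, 4)
  x[sample(length(x), 60)] <- NA
  y <- normalize_cyclic_loess(x)
  expect_identical(is.na(x), is.na(y))
  x[1, ] <- NA
  expect_warning(y2 <- normalize_cyclic_loess(x), "all-missing")
  expect_equal(nrow(y2), 149)
})

test_that("fraction rollup sums the top-2 fractions chosen by cross-sample mean", {
  # 4 fractions with distinct means: hand-computed expectation
  lin <- rbind(c(10, 12), c(100, 110), c(50, 55), c(1, 2))
  rownames(lin) <- paste0("pepA::", 1:4)
  colnames(lin) <- c("s1", "s2")
  got <- rollup_fractions(log2(lin), k = 2)
  expect_equal(got["pepA", ], c(s1 = 150, s2 = 165))
  # single available fraction: value passes through
  one <- matrix(log2(c(40, 44)), 1, dimnames = list("pepB::3", c("s1", "s2")))
  expect_equal(rollup_fractions(one, k = 2)["pepB", ], c(s1 = 40, s2 = 44))
  # row order must not matter
  perm <- rollup_fractions(log2(lin)[c(3, 1, 4, 2), ], k = 2)
  expect_equal(perm, got)
})

test_that("protein rollup matches hand computation and is homogeneous", {
  means <- c(10, 9, 8, 7, 6, 5, 4)
  x <- matrix(rep(means, 3), ncol = 3,
              dimnames = list(sprintf("pep%d", 1:7), c("s1", "s2", "s3")))
  map <- data.frame(peptide_id = rownames(x), protein_id = "prot1")
  got <- rollup_proteins(x, map, k = 5)
  expect_equal(unname(got["prot1", ]), rep(sum(10:6), 3))
  # fewer peptides than k: plain sum
  map3 <- data.frame(peptide_id = rownames(x)[1:3], protein_id = "prot2")
  got3 <- rollup_proteins(x[1:3, ], map3, k = 5)
  expect_equal(unname(got3["prot2", ]), rep(27, 3))
  # homogeneity
  expect_equal(rollup_proteins(2 * x, map, k = 5), 2 * got)
})

test_that("shared-peptide policies behave as documented", {
  x <- matrix(c(8, 10, 4, 5), 2, 2, byrow = TRUE,
              dimnames = list(c("pep1", "pep2"), c("s1", "s2")))
  map <- data.frame(peptide_id = c("pep1", "pep2", "pep2"),
                    protein_id = c("A", "A", "B"))
  expect_error(rollup_proteins(x, map), "multiple proteins")
  dropped <- rollup_proteins(x, map, shared = "drop")
  expect_equal(rownames(dropped), "A")
  expect_equal(unname(dropped["A", ]), c(8, 10))
  both <- rollup_proteins(x, map, shared = "assign_all")
  expect_equal(unname(both["B", ]), c(4, 5))
  expect_error(rollup_proteins(x, map[1, , drop = FALSE]), "unmapped")
})

test_that("rollup equals the sort-slice-sum oracle on random tables with NAs", {
  set.seed(31)
  for (i in 1:25) {
    n_pep <- sample(5:20, 1)
    n_frac <- sample(2:10, 1)
    n_samp <- sample(2:6, 1)
    x <- matrix(2 ^ rnorm(n_pep * n_frac * n_samp, 10, 2),
                n_pep * n_frac, n_samp)
    x[sample(length(x), round(0.2 * length(x)))] <- NA
    rownames(x) <- as.vector(outer(sprintf("pep%02d", 1:n_pep),
                                   1:n_frac, function(p, f) paste0(p, "::", f)))
    colnames(x) <- sprintf("s%d", 1:n_samp)
    k <- sample(1:4, 1)
    got <- rollup_fractions(log2(x), k = k)
    want <- oracle_topk_rollup(x, sub("::[^:]*$", "", rownames(x)), k)
    expect_equal(got, want)
  }
})

test_that("replicate CoV matches the log-normal closed form and is scale invariant", {
  set.seed(41)
  s <- 0.2
  n_prot <- 1000
  # 8 replicates per group keep the small-sample bias of the SD negligible
  x <- matrix(exp(log(1e5) + rnorm(n_prot * 16, 0, s)), n_prot, 16,
              dimnames = list(sprintf("p%d", 1:n_prot),
                              c(sprintf("a%d", 1:8), sprintf("b%d", 1:8))))
  groups <- list(A = sprintf("a%d", 1:8), B = sprintf("b%d", 1:8))
  res <- replicate_cov(x, groups)
  expect_equal(res$median_cov, sqrt(exp(s^2) - 1), tolerance = 0.1)
  res_scaled <- replicate_cov(10 * x, groups)
  expect_equal(res$per_protein, res_scaled$per_protein)
  # identical replicates: zero CoV
  y <- matrix(5, 3, 2, dimnames = list(letters[1:3], c("r1", "r2")))
  expect_equal(unname(replicate_cov(y, list(g = c("r1", "r2")))$per_protein),
               rep(0, 3))
  expect_warning(replicate_cov(x, list(A = "a1", B = c("b1", "b2"))),
                 "size 1")
})

test_that("full quantification is homogeneous under global rescaling", {
  cfg <- sim_config(n_proteins = 40, seed = 17, noise_sd = 0.2,
                    n_samples_per_group = c(NDC = 4, FTD = 4))
  cohort <- simulate_dia_cohort(cfg)
  q1 <- quantify_proteins(cohort$peptides, cohort$metadata, cohort$map)
  tab2 <- transform(cohort$peptides, peak_area = peak_area * 7)
  q2 <- quantify_proteins(tab2, cohort$metadata, cohort$map)
  expect_equal(q2$proteins, 7 * q1$proteins, tolerance = 1e-6)
})
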