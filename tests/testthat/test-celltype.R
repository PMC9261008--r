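toy_spec <- function() {
  # 4 genes x 3 types, hand-checkable
  m <- matrix(c(0.6, 0.2, 0.2,
                0.0, 1.0, 0.0,
                1/3, 1/3, 1/3,
                0.1, 0.4, 0.5), 4, 3, byrow = TRUE,
              dimnames = list(c("GA", "GB", "GC", "GD"),
                              c("astrocyte", "excitatory", "inhibitory")))
  m
}

test_that("specificity matches hand computation on a printed toy matrix", {
  # cells x genes; two cells per type so library normalization matters
  counts <- rbind(
    a1 = c(g1 = 8, g2 = 2, g3 = 0),
    a2 = c(16, 4, 0),
    b1 = c(2, 2, 4),
    b2 = c(1, 1, 2),
    c1 = c(0, 5, 5),
    c2 = c(0, 10, 10)
  )
  labels <- c("A", "A", "B", "B", "C", "C")
  spec <- compute_specificity(counts, labels)
  # normalized per cell: A cells -> (.8,.2,0); B -> (.25,.25,.5); C -> (0,.5,.5)
  tm <- rbind(c(0.8, 0.2, 0), c(0.25, 0.25, 0.5), c(0, 0.5, 0.5))
  want <- t(tm) / colSums(tm)
  dimnames(want) <- list(c("g1", "g2", "g3"), c("A", "B", "C"))
  expect_equal(spec, want, ignore_attr = TRUE)
  expect_equal(unname(rowSums(spec)), rep(1, 3), tolerance = 1e-9)
  # gene expressed in a single type
  expect_equal(unname(spec["g1", ]), c(0.8 / 1.05, 0.25 / 1.05, 0),
               tolerance = 1e-12)
})

test_that("specificity drops unknown cells and zero genes", {
  counts <- rbind(a = c(5, 0), b = c(5, 0), u = c(100, 100))
  colnames(counts) <- c("g1", "g2")
  expect_warning(spec <- compute_specificity(counts, c("A", "B", "unknown")),
                 "zero total")
  expect_equal(rownames(spec), "g1")
  expect_error(compute_specificity(counts, c("A", "unknown", "unknown")),
               "2 cell types")
})

test_that("ewce bootstrap flags a planted marker list and matches enumeration", {
  set.seed(15)
  n_bg <- 12
  spec <- matrix(runif(n_bg * 3), n_bg, 3,
                 dimnames = list(sprintf("g%02d", 1:n_bg), c("t1", "t2", "t3")))
  spec <- spec / rowSums(spec)
  background <- rownames(spec)
  target <- background[1:4]
  # C(12,4) = 495 subsets: exact tail by enumeration
  want <- oracle_ewce_exact(toupper(target), toupper(background),
                            `rownames<-`(spec, toupper(rownames(spec))))
  got <- suppressWarnings(
    ewce_bootstrap(target, background, spec, n_boot = 20000, seed = 4))
  expect_equal(got$observed, unname(want$observed), tolerance = 1e-12)
  expect_true(all(abs(got$p - want$p_exact) < 0.02))
  expect_true(all(abs(got$boot_mean - want$mean_exact) < 0.02))
})

test_that("pure-marker targets hit the p floor with fold near the type count", {
  ref <- simulate_sc_reference(cell_types = c("a", "b", "c", "d"),
                               n_cells_per_type = 50, n_genes = 300,
                               n_marker_per_type = 20,
                               marker_enrichment = 1000, seed = 21)
  spec <- compute_specificity(ref$counts, ref$labels)
  background <- rownames(spec)
  markers <- ref$truth$gene[ref$truth$marker_type %in% "a"]
  res <- ewce_bootstrap(markers, background, spec, n_boot = 2000, seed = 7)
  row_a <- res[res$cell_type == "a", ]
  expect_true(row_a$at_floor)
  expect_equal(row_a$p, 1 / 2001, tolerance = 1e-12)
  expect_match(row_a$p_label, "^<")
  expected_fold <- row_a$observed / (length(markers) *
                                       mean(spec[background, "a"]))
  expect_equal(row_a$fold, expected_fold, tolerance = 0.05)
  expect_gt(row_a$fold, 2.5)
  # target = background: fold 1, p near 1 for every type
  res_bg <- ewce_bootstrap(background, background, spec, n_boot = 200, seed = 1)
  expect_equal(res_bg$fold, rep(1, 4), tolerance = 1e-9)
  expect_true(all(res_bg$p > 0.9))
})

test_that("ewce p-values are calibrated under random targets", {
  set.seed(23)
  n_bg <- 150
  spec <- matrix(rgamma(n_bg * 4, 2), n_bg, 4,
                 dimnames = list(sprintf("g%03d", 1:n_bg),
                                 c("t1", "t2", "t3", "t4")))
  spec <- spec / rowSums(spec)
  background <- rownames(spec)
  ps <- vapply(1:150, function(i) {
    target <- sample(background, 12)
    ewce_bootstrap(target, background, spec, n_boot = 400, seed = i)$p[1]
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("a planted marker list scores smaller p than its complement", {
  ref <- simulate_sc_reference(cell_types = c("a", "b", "c"),
                               n_cells_per_type = 40, n_genes = 120,
                               n_marker_per_type = 15, marker_enrichment = 30,
                               seed = 31)
  spec <- compute_specificity(ref$counts, ref$labels)
  background <- rownames(spec)
  markers <- intersect(ref$truth$gene[ref$truth$marker_type %in% "b"],
                       background)
  others <- sample(setdiff(background, markers), length(markers))
  p_mark <- ewce_bootstrap(markers, background, spec, n_boot = 1000,
                           seed = 2)
  p_oth <- ewce_bootstrap(others, background, spec, n_boot = 1000, seed = 2)
  expect_lt(p_mark$p[p_mark$cell_type == "b"],
            p_oth$p[p_oth$cell_type == "b"])
})

test_that("highly-enriched classification applies threshold, merging and ties", {
  spec <- toy_spec()
  got <- classify_highly_enriched(spec, rownames(spec))
  expect_equal(unname(got), c("astrocyte", "excitatory", NA, "inhibitory"))
  # exc 0.4 + inh 0.5 = 0.9 for GD; 0.2+0.2 = 0.4 for GA
  merged <- classify_highly_enriched(spec, rownames(spec),
                                     merge_neurons = TRUE)
  expect_equal(unname(merged["GD"]), "neuron")
  expect_equal(unname(merged["GA"]), "astrocyte")
  # exc = inh = 0.3, others 0.4: merging changes the call to neuron
  spec2 <- matrix(c(0.4, 0.3, 0.3), 1,
                  dimnames = list("GX", colnames(spec)))
  expect_true(is.na(classify_highly_enriched(spec2, "GX")))
  expect_equal(unname(classify_highly_enriched(spec2, "GX",
                                               merge_neurons = TRUE)),
               "neuron")
  # uniform vector: no call; unknown protein: NA
  spec3 <- matrix(rep(1/3, 3), 1, dimnames = list("GU", colnames(spec)))
  expect_true(is.na(classify_highly_enriched(spec3, "GU")))
  expect_true(is.na(classify_highly_enriched(spec, "missing_protein")))
})

test_that("control-variation SD matches the closed form and split modes agree", {
  set.seed(41)
  sigma <- 0.4   # log2 SD per sample
  n_ctrl <- 8
  x <- matrix(2 ^ (10 + rnorm(3000 * n_ctrl, 0, sigma)), 3000, n_ctrl,
              dimnames = list(sprintf("p%d", 1:3000),
                              sprintf("ndc%d", 1:n_ctrl)))
  res <- ndc_variation_sd(x, colnames(x), n_splits = 40, seed = 1)
  expect_equal(res$sd, sigma * sqrt(2 / (n_ctrl / 2)), tolerance = 0.1)
  # identical controls: SD exactly 0
  y <- matrix(7, 10, 4, dimnames = list(sprintf("p%d", 1:10),
                                        sprintf("n%d", 1:4)))
  expect_equal(ndc_variation_sd(y, colnames(y))$sd, 0)
  expect_error(ndc_variation_sd(x, colnames(x)[1:3]), "at least 4")
  # exhaustive vs random splits on 6 controls agree within 5%
  x6 <- x[1:800, 1:6]
  ex <- ndc_variation_sd(x6, colnames(x6), n_splits = 1000, seed = 1)
  rd <- ndc_variation_sd(x6, colnames(x6), n_splits = 12, seed = 5)
  expect_false(choose(6, 3) > 1000)  # first call is exhaustive
  expect_equal(rd$sd, ex$sd, tolerance = 0.05)
})

test_that("composition check separates regulated sets from composition noise", {
  # null: no regulation, everything inside the band
  sim <- make_protein_matrix(300, 8, noise_sd = 0.3, seed = 51)
  de <- run_de(sim$linear, sim$labels, n_perm = 200, seed = 1)
  assign <- stats::setNames(rep(c("astrocyte", "neuron", "oligo"), each = 60),
                            rownames(sim$linear)[1:180])
  ndc <- ndc_variation_sd(sim$linear,
                          colnames(sim$linear)[sim$labels == "NDC"],
                          n_splits = 50, seed = 2)
  chk <- composition_check(de, assign, ndc$sd)
  expect_true(all(chk$summary$frac_inside >= 0.9))
  # planted astrocyte shift lands outside the band
  sim2 <- make_protein_matrix(300, 8, effect_idx_up = 1:60, log2fc = 2,
                              noise_sd = 0.3, seed = 52)
  de2 <- run_de(sim2$linear, sim2$labels, n_perm = 200, seed = 1)
  ndc2 <- ndc_variation_sd(sim2$linear,
                           colnames(sim2$linear)[sim2$labels == "NDC"],
                           n_splits = 50, seed = 2)
  chk2 <- composition_check(de2, assign, ndc2$sd)
  s2 <- chk2$summary
  astro_out <- 1 - s2$frac_inside[s2$cell_type == "astrocyte"]
  other_out <- 1 - s2$frac_inside[s2$cell_type != "astrocyte"]
  expect_gt(astro_out, 0.9)
  expect_true(all(other_out < 0.2))
  # degenerate SD = 0: every nonzero fold change is outside
  chk0 <- composition_check(de2, assign, 0)
  nz <- chk0$points$log2fc != 0
  expect_true(all(!chk0$points$inside[nz]))
})
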