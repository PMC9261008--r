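test_that("hypergeometric p equals the closed-form summation", {
  # printed example: background 100, target 10, term 10, overlap 5
  bg <- sprintf("g%03d", 1:100)
  term <- bg[1:10]
  target <- c(bg[1:5], bg[96:100])
  res <- hypergeometric_enrichment(target, bg, list(tm = term), min_size = 5)
  expect_equal(res$p, oracle_hyper_p(5, 10, 100, 10))
  expect_equal(res$overlap, 5L)
  # systematic grid over small universes
  for (N in c(12, 20, 30)) {
    bg <- sprintf("x%02d", 1:N)
    for (K in unique(c(2, 5, N %/% 2, N))) {
      for (n in unique(c(1, 4, N %/% 3, N %/% 2))) {
        for (k in 0:min(K, n)) {
          if (n - k > N - K) next
          target <- c(bg[seq_len(k)], if (n - k > 0) bg[K + seq_len(n - k)])
          res <- hypergeometric_enrichment(target, bg,
                                           list(tm = bg[seq_len(K)]),
                                           min_size = 1)
          expect_equal(res$p, oracle_hyper_p(k, K, N, n), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("min-size and background-restriction rules apply", {
  bg <- sprintf("g%d", 1:20)
  sets <- list(small = bg[1:4],                     # size 4: excluded
               ok = bg[1:6],
               outside = sprintf("z%d", 1:10))      # fully outside background
  res <- hypergeometric_enrichment(bg[1:5], bg, sets, min_size = 5)
  expect_equal(res$term_id, "ok")
  # zero overlap is never enriched
  res0 <- hypergeometric_enrichment(bg[15:19], bg, list(tm = bg[1:6]),
                                    min_size = 5)
  expect_gte(res0$p, 0.5)
  # empty target, and target outside the background
  expect_equal(nrow(hypergeometric_enrichment(character(0), bg, sets)), 0)
  expect_error(hypergeometric_enrichment("nope", bg, sets), "absent")
})

test_that("BH adjustment is monotone and namespace-stratified", {
  set.seed(3)
  bg <- sprintf("g%03d", 1:60)
  sets <- lapply(1:12, function(i) sample(bg, 10))
  names(sets) <- sprintf("T%02d", 1:12)
  ns <- stats::setNames(rep(c("BP", "CC"), 6), names(sets))
  res <- hypergeometric_enrichment(sample(bg, 15), bg, sets, namespaces = ns)
  expect_true(all(res$p_adj >= res$p))
  ord <- order(res$p)
  # within a namespace, adjusted p is monotone in p
  for (nsx in c("BP", "CC")) {
    sub <- res[ns[res$term_id] == nsx, ]
    sub <- sub[order(sub$p), ]
    expect_true(all(diff(sub$p_adj) >= -1e-12))
  }
  expect_equal(res$p_adj[ns[res$term_id] == "BP"],
               stats::p.adjust(res$p[ns[res$term_id] == "BP"], "BH"))
})

test_that("best-per-parent keeps the strongest significant sibling", {
  # star DAG: three significant children, one winner
  edges <- data.frame(parent = "root", child = c("a", "b", "c"))
  res <- data.frame(term_id = c("a", "b", "c"),
                    overlap = c(5L, 5L, 5L), size = c(10L, 10L, 10L),
                    p = c(0.01, 0.02, 0.03), p_adj = c(0.03, 0.04, 0.045))
  out <- best_per_parent(res, edges)
  expect_equal(out$term_id, "a")
  # diamond: term best under one parent but not the other is retained
  edges2 <- data.frame(parent = c("r", "r", "p1", "p2", "p1"),
                       child = c("p1", "p2", "x", "x", "y"))
  res2 <- data.frame(term_id = c("p1", "p2", "x", "y"),
                     overlap = c(8L, 8L, 6L, 6L), size = rep(10L, 4),
                     p = c(0.001, 0.002, 0.004, 0.003),
                     p_adj = c(0.004, 0.008, 0.016, 0.012))
  out2 <- best_per_parent(res2, edges2)
  # x loses to y under p1 but wins under p2 (sole significant child there);
  # p2 is not the best child of r, so it drops out
  expect_setequal(out2$term_id, c("p1", "x", "y"))
  # no significant terms: empty result
  res3 <- transform(res, p_adj = 0.5)
  expect_equal(nrow(best_per_parent(res3, edges)), 0)
  # cycles are rejected
  cyc <- data.frame(parent = c("a", "b"), child = c("b", "a"))
  expect_error(best_per_parent(res, cyc), "cycle")
})

test_that("best-per-parent equals the brute-force rule on random DAGs", {
  set.seed(7)
  for (i in 1:30) {
    on <- simulate_ontology(n_terms = sample(10:50, 1),
                            max_depth = sample(2:4, 1),
                            n_genes = 100, seed = i)
    m <- nrow(on$terms)
    res <- data.frame(term_id = on$terms$term_id,
                      overlap = sample(1:20, m, replace = TRUE),
                      size = sample(5:30, m, replace = TRUE),
                      p = round(stats::runif(m, 0, 0.2), 3))
    res$p_adj <- pmin(1, res$p * 2)
    got <- best_per_parent(res, on$edges, alpha = 0.1)
    want <- oracle_best_per_parent(res, on$edges, alpha = 0.1)
    expect_setequal(got$term_id, want)
    # retained set is a subset of the significant input
    expect_true(all(got$p_adj < 0.1))
    # every parent with a significant child contributes at least one child
    sig <- res$term_id[res$p_adj < 0.1]
    for (pa in unique(on$edges$parent)) {
      ch <- on$edges$child[on$edges$parent == pa]
      if (any(ch %in% sig)) {
        expect_true(any(ch %in% c(got$term_id,
                                  oracle_best_per_parent(res, on$edges, 0.1))))
      }
    }
  }
})

test_that("subtree partition matches reachability and allows multi-assignment", {
  edges <- data.frame(parent = c("root", "root", "pre", "post"),
                      child = c("pre", "post", "preA", "postA"))
  sets <- list(pre = c("g1"), preA = c("g2"), post = c("g3"),
               postA = c("g2", "g4"), root = character(0))
  part <- partition_by_subtree(c("g1", "g2", "g3", "g5"), edges, sets,
                               c("pre", "post"))
  expect_setequal(part$members$pre, c("g1", "g2"))
  expect_setequal(part$members$post, c("g2", "g3"))
  expect_equal(part$unannotated, "g5")
  expect_error(partition_by_subtree("g1", edges, sets, "ghost"),
               "not in ontology")
  # random fixtures against the reachability oracle
  set.seed(9)
  for (i in 1:10) {
    on <- simulate_ontology(n_terms = 30, max_depth = 3, n_genes = 80,
                            seed = 100 + i)
    target <- sample(sprintf("G%04d", 1:80), 30)
    roots <- sample(on$terms$term_id, 3)
    part <- partition_by_subtree(target, on$edges, on$sets, roots)
    for (r in roots) {
      expect_setequal(part$members[[r]],
                      oracle_subtree_members(target, on$edges, on$sets, r))
    }
  }
})

test_that("GMT round-trips and deduplicates", {
  sets <- list(S1 = c("A", "B", "C"), S2 = c("B", "D"))
  attr(sets, "description") <- c(S1 = "first", S2 = "second")
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(back[["S1"]], sets[["S1"]])
  expect_equal(attr(back, "description")[["S2"]], "second")
  writeLines("dup\tdesc\tA\tB\tA", path)
  expect_warning(d <- read_gmt(path), "duplicate")
  expect_equal(d[["dup"]], c("A", "B"))
  writeLines("broken\tonly-two-fields", path)
  expect_error(read_gmt(path), "malformed")
})

test_that("OBO subset round-trips and rejects cycles", {
  on <- simulate_ontology(n_terms = 15, max_depth = 3, seed = 5)
  path <- withr::local_tempfile(fileext = ".obo")
  write_obo(on, path)
  back <- read_obo(path)
  expect_setequal(back$terms$term_id, on$terms$term_id)
  key <- function(e) sort(paste(e$parent, e$child))
  expect_equal(key(back$edges), key(on$edges))
  writeLines(c("[Term]", "id: T:1", "name: one", "is_a: T:2 ! two",
               "", "[Term]", "id: T:2", "name: two", "is_a: T:1"), path)
  expect_error(read_obo(path), "cycle")
})
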