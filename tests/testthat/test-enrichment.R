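test_that("hypergeometric tail matches enumeration and closed forms", {
  expect_equal(hypergeometric_tail(0, 4, 3, 10), 1)
  # all C(10,3) draws: (36 + 4)/120
  expect_equal(hypergeometric_tail(2, 4, 3, 10), 1 / 3)
  expect_equal(oracle_hyper_tail(2, 4, 3, 10), 1 / 3)
  # single-term tail
  expect_equal(hypergeometric_tail(5, 5, 5, 20), 1 / choose(20, 5))
  expect_equal(oracle_hyper_tail(5, 5, 5, 20), 1 / choose(20, 5))
  expect_error(hypergeometric_tail(4, 3, 5, 10), "k must not exceed")
  expect_error(hypergeometric_tail(1, 11, 5, 10), "exceed N")
})

test_that("hypergeometric tail stays accurate deep in the tail", {
  # log-space summation must survive the 1e-6-threshold regime
  p <- hypergeometric_tail(50, 60, 100, 2000)
  expect_gt(p, 0)
  expect_lt(p, 1e-50)
  expect_equal(p, stats::phyper(49, 60, 1940, 100, lower.tail = FALSE))
})

test_that("binomial tail equals direct summation", {
  expect_equal(binomial_tail(0, 10, 3, 100), 1)
  expect_equal(binomial_tail(3, 50, 3, 100), 0.125)
  expect_equal(binomial_tail(5, 10, 20, 100), oracle_binom_tail(5, 10, 20, 100))
})

test_that("one-sided 2x2 chi-square matches the shortcut formula", {
  # [[40,60],[10,90]]: X2 = N*(ad-bc)^2/(r1*r2*c1*c2) = 24
  expect_equal(chisq_2x2(40, 50, 100, 200),
               pchisq(24, 1, lower.tail = FALSE))
  expect_equal(chisq_2x2(40, 50, 100, 200),
               suppressWarnings(chisq.test(matrix(c(40, 60, 10, 90), 2,
                                                  byrow = TRUE),
                                           correct = FALSE)$p.value))
  # at or below expectation: no excess, p = 1
  expect_equal(chisq_2x2(5, 10, 100, 200), 1)   # k exactly n*K/N
  expect_equal(chisq_2x2(2, 10, 100, 200), 1)   # under-represented
  # zero-margin category is untestable
  expect_warning(p0 <- chisq_2x2(0, 0, 10, 100), "untestable")
  expect_equal(p0, 1)
  # Yates variant is more conservative
  expect_gt(chisq_2x2(40, 50, 100, 200, yates = TRUE),
            chisq_2x2(40, 50, 100, 200))
})

test_that("p-value adjustment follows the textbook formulas", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(0.01, "bonferroni"), 0.01)
  expect_equal(adjust_pvalues(c(0.01, 0.5), "bonferroni"), c(0.02, 1))
  expect_equal(adjust_pvalues(0.3, "BH"), 0.3)  # m = 1: unchanged
  expect_equal(adjust_pvalues(numeric(), "BH"), numeric())
  expect_equal(adjust_pvalues(c(0.5, 0.01), "none"), c(0.5, 0.01))
  expect_error(adjust_pvalues(c(0.5, 1.2), "BH"), "\\[0, 1\\]")
  set.seed(77)
  for (method in c("BH", "bonferroni", "holm")) {
    p <- runif(50)
    expect_equal(adjust_pvalues(p, method), oracle_adjust(p, method))
  }
})

test_that("BH output is monotone in sorted order and permutation-invariant", {
  set.seed(88)
  p <- runif(100)
  adj <- adjust_pvalues(p, "BH")
  expect_true(all(diff(adj[order(p)]) >= 0))
  perm <- sample(100)
  expect_equal(adjust_pvalues(p[perm], "BH"), adj[perm])
})

test_that("run_ora builds the 2x2 counts after background intersection", {
  background <- sprintf("g%03d", 1:100)
  collection <- toy_sets(S1 = sprintf("g%03d", 1:10))
  query <- c(sprintf("g%03d", 5:10), sprintf("g%03d", 50:63))  # 6 in S1, 20 total
  tab <- run_ora(query, collection, background)
  expect_equal(tab$k, 6L)
  expect_equal(tab$K, 10L)
  expect_equal(tab$n, 20L)
  expect_equal(tab$N, 100L)
  expect_equal(tab$p_raw, hypergeometric_tail(6, 10, 20, 100))
  expect_equal(tab$p_raw, phyper(5, 10, 90, 20, lower.tail = FALSE))
  expect_equal(tab$overlap_genes[[1]], sprintf("g%03d", 5:10))
  expect_equal(attr(tab, "m"), 1L)

  # query genes outside the background are discarded; duplicates ignored
  tab2 <- run_ora(c(rev(query), query, "not_a_gene"), collection, background)
  expect_equal(tab2$p_raw, tab$p_raw)
  expect_equal(tab2$n, 20L)

  expect_error(run_ora("not_a_gene", collection, background),
               "empty after intersection")
})

test_that("enrichment flag respects alpha and the minimum-gene filter", {
  background <- sprintf("g%03d", 1:100)
  collection <- toy_sets(S1 = c("g001", sprintf("x%02d", 1:9)),
                         S2 = sprintf("g%03d", 2:11))
  # k = 1 in S1: significant p would still not be flagged (min_genes = 2)
  query <- c("g001", sprintf("g%03d", 2:11))
  cfg <- method_config("perm", "hypergeometric", "none", alpha = 0.999)
  tab <- run_ora(query, collection, background, cfg)
  expect_equal(tab$k[tab$set_id == "S1"], 1L)
  expect_false(tab$enriched[tab$set_id == "S1"])
  expect_true(tab$enriched[tab$set_id == "S2"])

  # disjoint query: nothing enriched
  tab3 <- run_ora(sprintf("g%03d", 50:60), collection, background)
  expect_false(any(tab3$enriched))
})

test_that("stricter alpha yields a subset of enriched categories", {
  set.seed(99)
  genes <- simulate_genome(simulation_spec(n_genes = 500, seed = 99))
  sets <- simulate_genesets(genes, 50, size_mean = 15, seed = 100)
  query <- sample(genes$gene_id, 60)
  loose <- run_ora(query, sets, genes$gene_id,
                   method_config("loose", "hypergeometric", "BH", 0.5))
  strict <- run_ora(query, sets, genes$gene_id,
                    method_config("strict", "hypergeometric", "BH", 0.05))
  expect_true(all(enriched_ids(strict) %in% enriched_ids(loose)))
})

test_that("profile resolution knows defaults and inline specs", {
  profs <- default_method_profiles()
  expect_named(profs, c("strict-1e6", "strict-1e4", "mid-0.01", "default-0.05"))
  expect_equal(profs[["strict-1e6"]]$alpha, 1e-6)
  expect_true(all(vapply(profs, `[[`, 1L, "min_genes") == 2L))
  inline <- resolve_profiles(c("default-0.05", "binomial:holm:0.01"))
  expect_equal(inline[[2]]$statistic, "binomial")
  expect_equal(inline[[2]]$correction, "holm")
  expect_equal(inline[[2]]$alpha, 0.01)
  expect_error(resolve_profiles("nonsense"), "unknown profile")
})
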