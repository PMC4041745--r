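test_that("allelic test matches hand-computed chi-square values", {
  # balanced table: no association
  expect_equal(allelic_test(369, 369, 369, 369), 1)
  # X2 = 4*31^2/369 by the O/E formula
  x2 <- 4 * 31^2 / 369
  expect_equal(allelic_test(400, 338, 338, 400),
               pchisq(x2, 1, lower.tail = FALSE))
  expect_equal(allelic_test(400, 338, 338, 400), 0.00125, tolerance = 1e-2)
  # monomorphic: one allele absent from the pooled sample
  expect_equal(allelic_test(738, 0, 738, 0), 1)
  expect_error(allelic_test(-1, 2, 3, 4), "must be >= 0")
})

test_that("allelic test agrees with chisq.test on random tables", {
  set.seed(42)
  for (i in 1:50) {
    tab <- matrix(sample(0:200, 4, replace = TRUE) + 1L, 2)
    expect_equal(
      allelic_test(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
      suppressWarnings(chisq.test(tab, correct = FALSE)$p.value))
    expect_equal(
      allelic_test(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2], yates = TRUE),
      suppressWarnings(chisq.test(tab, correct = TRUE)$p.value))
  }
})

test_that("odds-ratio frequency map evaluates correctly", {
  expect_equal(causal_allele_freq(0.3, 2), 0.6 / 1.3)
  expect_equal(causal_allele_freq(0.2, 1), 0.2)  # theta = 1 is the null
  expect_true(all(causal_allele_freq(seq(0.05, 0.5, by = 0.05), 1.8) >
                    seq(0.05, 0.5, by = 0.05)))
})

test_that("simulated genome is ordered, non-overlapping and deterministic", {
  spec <- simulation_spec(n_genes = 3, seed = 11)
  g1 <- simulate_genome(spec)
  g2 <- simulate_genome(spec)
  expect_identical(g1, g2)
  expect_equal(nrow(g1), 3L)
  expect_true(all(g1$start < g1$end))
  expect_true(all(diff(g1$start) > 0))
  expect_true(all(g1$start[-1] >= g1$end[-3]))  # no overlap
})

test_that("simulated gene lengths hit the requested mean", {
  spec <- simulation_spec(n_genes = 1000, gene_len = 2000, seed = 5)
  g <- simulate_genome(spec)
  mean_len <- mean(g$end - g$start)
  expect_true(abs(mean_len - 2000) / 2000 < 0.1)
})

test_that("gene-set generation validates, is seeded and overlaps by chance", {
  genes <- simulate_genome(simulation_spec(n_genes = 2000, seed = 3))
  expect_error(simulate_genesets(genes, 1, size_mean = 1, seed = 1),
               "size_mean")
  one <- simulate_genesets(genes, 1, size_mean = 5, seed = 9)
  expect_true(all(one$members[[1]] %in% genes$gene_id))
  expect_gte(one$n_members, 2L)

  a <- simulate_genesets(genes, 2, size_mean = 10, seed = 7)
  b <- simulate_genesets(genes, 2, size_mean = 10, seed = 7)
  c <- simulate_genesets(genes, 2, size_mean = 10, seed = 8)
  expect_identical(a$members, b$members)
  expect_false(identical(a$members, c$members))

  # 200 sets of mean size 25 over 2000 genes: expected pairwise overlap
  # ~ 25*25/2000 ~ 0.31 shared members
  sets <- simulate_genesets(genes, 200, size_mean = 25, seed = 13)
  pair_overlap <- combn(200, 2, function(ij) {
    length(intersect(sets$members[[ij[1]]], sets$members[[ij[2]]]))
  })
  expect_equal(mean(pair_overlap), 25 * 25 / 2000, tolerance = 0.35)
})

test_that("simulated scans are deterministic and record planted truth", {
  genes <- simulate_genome(simulation_spec(n_genes = 200, seed = 21))
  sets <- simulate_genesets(genes, 20, size_mean = 10, seed = 22)
  spec <- simulation_spec(n_genes = 200, theta = 2, causal_sets = "SET0001",
                          seed = 21)
  s1 <- simulate_scan(spec, genes, sets)
  s2 <- simulate_scan(spec, genes, sets)
  expect_identical(s1, s2)

  d <- withr::local_tempdir()
  write_associations(s1$associations, file.path(d, "a1.tsv"))
  write_associations(s2$associations, file.path(d, "a2.tsv"))
  expect_identical(readBin(file.path(d, "a1.tsv"), "raw", 1e6),
                   readBin(file.path(d, "a2.tsv"), "raw", 1e6))

  truth <- s1$truth
  expect_equal(truth$causal_set_ids, "SET0001")
  members <- sets$members[[1]]
  expect_true(all(truth$causal_gene_ids %in% members))
  expect_equal(length(truth$causal_gene_ids),
               ceiling(0.5 * length(members)))
  expect_equal(length(truth$causal_snp_ids), length(truth$causal_gene_ids))
  # causal SNPs sit inside their genes' bodies
  mapping <- map_snps_to_genes(s1$associations, genes, 0)
  expect_true(all(truth$causal_snp_ids %in% mapping$snp_id))

  expect_error(simulate_scan(simulation_spec(causal_sets = "NOPE", seed = 1),
                             genes, sets),
               "absent from collection")
})

test_that("theta = 1 plants flags but no effect; power grows with theta", {
  genes <- simulate_genome(simulation_spec(n_genes = 300, seed = 31))
  sets <- simulate_genesets(genes, 10, size_mean = 20, seed = 32)
  mean_neglog <- vapply(c(1, 1.5, 2, 3), function(th) {
    spec <- simulation_spec(n_genes = 300, theta = th,
                            causal_sets = "SET0001", seed = 31)
    s <- simulate_scan(spec, genes, sets)
    idx <- s$associations$snp_id %in% s$truth$causal_snp_ids
    mean(-log10(s$associations$p[idx]))
  }, 0)
  expect_true(length(simulate_scan(
    simulation_spec(n_genes = 300, theta = 1, causal_sets = "SET0001",
                    seed = 31), genes, sets)$truth$causal_snp_ids) > 0)
  expect_true(all(diff(mean_neglog) >= 0))
})
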