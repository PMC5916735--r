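test_that("cpm is correct, scale-invariant and stabilized in log mode", {
  counts <- matrix(c(10, 0, 20, 40), nrow = 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  cm <- count_matrix(counts, c("A", "B"), lib_size = c(1e6, 1e6))
  expect_equal(cpm(cm)["g1", "s1"], 10)
  expect_equal(cpm(cm, log = TRUE, prior_count = 0.5)["g2", "s1"],
               log2(0.5 / (1e6 + 1) * 1e6))

  cm2 <- count_matrix(2 * counts, c("A", "B"), lib_size = c(2e6, 2e6))
  expect_equal(cpm(cm2), cpm(cm))
})

test_that("TMM factors: symmetry, depth invariance, and edgeR agreement", {
  set.seed(1)
  base <- matrix(rnbinom(4000, mu = 100, size = 10), ncol = 4,
                 dimnames = list(NULL, paste0("s", 1:4)))
  same <- count_matrix(cbind(base[, 1], base[, 1], base[, 1], base[, 1]),
                       c("A", "A", "B", "B"))
  expect_equal(tmm_factors(same)$norm_factors, rep(1, 4))

  # pure depth difference is absorbed by library size, not the factor
  depth <- count_matrix(cbind(base[, 1], 2 * base[, 1]), c("A", "B"))
  f <- tmm_factors(depth)$norm_factors
  expect_equal(f[1], f[2], tolerance = 1e-10)

  # 5% of genes 16x inflated in sample 4 pushes its factor below 1
  infl <- base
  idx <- sample(nrow(infl), 50)
  infl[idx, 4] <- infl[idx, 4] * 16
  cm <- count_matrix(infl, c("A", "A", "B", "B"))
  ours <- tmm_factors(cm)$norm_factors
  expect_lt(ours[4], 1)
  ref <- edgeR::calcNormFactors(
    edgeR::DGEList(infl, lib.size = cm$lib_size))$samples$norm.factors
  expect_equal(ours, ref, tolerance = 0.02)

  allz <- base
  allz[, 2] <- 0
  cm0 <- count_matrix(allz, c("A", "A", "B", "B"),
                      lib_size = rep(1e5, 4))
  expect_error(tmm_factors(cm0), "all-zero")
})

test_that("moment dispersion estimator recovers phi", {
  ann <- uniform_annotation(2000, seed = 30)
  # Poisson data: estimate near zero
  p0 <- simulate_counts(ann, expression_spec(de_fraction = 0,
                                             dispersion = 0, seed = 31))
  expect_lt(estimate_common_dispersion(p0$counts), 0.02)
  # NB phi = 0.1: estimate within a factor of 2
  p1 <- simulate_counts(ann, expression_spec(de_fraction = 0,
                                             dispersion = 0.1, seed = 32))
  est <- estimate_common_dispersion(p1$counts)
  expect_gte(est, 0.05)
  expect_lte(est, 0.2)
  # constant genes: zero dispersion
  const <- count_matrix(matrix(5L, 10, 4), c("A", "A", "B", "B"))
  expect_equal(estimate_common_dispersion(const), 0)
  one_each <- count_matrix(matrix(5L, 10, 2), c("A", "B"))
  expect_error(estimate_common_dispersion(one_each), "dispersion")
})

test_that("BH adjustment with a test universe matches the published table", {
  tab <- stickleback_top_genes()
  published_fdr <- c(4.753656e-47, 7.383376e-47, 1.775419e-42,
                     3.378099e-37, 1.112547e-36, 2.815753e-36,
                     1.714387e-33, 1.061745e-31, 1.061745e-31,
                     2.118991e-31)
  adj <- bh_adjust(tab$pvalue, n_total = 22456)
  expect_equal(signif(adj, 6), signif(published_fdr, 6))
  # the step-up minimum ties ranks 8 and 9
  expect_equal(adj[8], adj[9])
  expect_equal(signif(adj[8], 7), 1.061745e-31)
})

test_that("BH adjustment properties and p.adjust agreement", {
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1)) ^ sample(1:3, 1)
    adj <- bh_adjust(p)
    expect_equal(adj, p.adjust(p, method = "BH"))
    expect_true(all(adj >= p))
    ord <- order(p)
    expect_true(!is.unsorted(adj[ord]))
    # re-adjusting never lowers an adjusted value
    expect_true(all(bh_adjust(adj) >= adj - 1e-12))
  }
  expect_equal(bh_adjust(1), 1)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.1, 0.2), n_total = 1), "n_total")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("NB exact test: symmetry, binomial limit, antisymmetry", {
  # balanced identical group sums: P = 1, logFC = 0
  counts <- matrix(c(50, 50, 50, 50), nrow = 1,
                   dimnames = list("g1", paste0("s", 1:4)))
  cm <- count_matrix(counts, c("A", "A", "B", "B"))
  res <- nb_exact_test(cm, 0.1)
  expect_equal(res$PValue, 1)
  expect_equal(res$logFC, 0)

  # phi = 0, one sample per group, 0 vs 10: doubled binomial tail
  cm2 <- count_matrix(matrix(c(0, 10), nrow = 1,
                             dimnames = list("g1", c("a", "b"))),
                      c("A", "B"), lib_size = c(1e6, 1e6))
  res2 <- nb_exact_test(cm2, 0)
  expect_equal(res2$PValue, 2 * 0.5^10)

  # label swap: identical P, negated logFC
  set.seed(8)
  mat <- matrix(rnbinom(800, mu = 50, size = 10), ncol = 8)
  rownames(mat) <- paste0("g", 1:100)
  grp <- rep(c("A", "B"), each = 4)
  r1 <- nb_exact_test(count_matrix(mat, grp), 0.1)
  r2 <- nb_exact_test(count_matrix(mat, rev(grp)), 0.1)
  expect_equal(r1$PValue, r2$PValue, tolerance = 1e-12)
  expect_equal(r1$logFC, -r2$logFC, tolerance = 1e-12)

  # all-zero gene is untestable
  mat0 <- rbind(mat, g0 = 0L)
  r0 <- nb_exact_test(count_matrix(mat0, grp), 0.1)
  expect_equal(r0$PValue[r0$gene_id == "g0"], 1)
  expect_true(r0$untestable[r0$gene_id == "g0"])
})

test_that("NB exact test agrees with the edgeR reference implementation", {
  ann <- uniform_annotation(400, seed = 40)
  sim <- simulate_counts(ann, expression_spec(
    library_sizes = rep(2e6, 8), de_fraction = 0.15, seed = 41))
  cm <- tmm_factors(sim$counts)
  mine <- nb_exact_test(cm, 0.1)
  d <- edgeR::DGEList(cm$counts, group = cm$group, lib.size = cm$lib_size,
                      norm.factors = cm$norm_factors)
  ref <- edgeR::exactTest(d, dispersion = 0.1)$table
  # same decisions: log-P agreement and near-identical ranking
  expect_gt(cor(log10(mine$PValue + 1e-300),
                log10(ref$PValue + 1e-300)), 0.999)
  expect_gt(cor(mine$logFC, ref$logFC), 0.99)
})

test_that("de_analysis flags DE at the FDR threshold with sane columns", {
  ann <- uniform_annotation(500, seed = 50)
  sim <- simulate_counts(ann, expression_spec(library_sizes = rep(2e6, 8),
                                              seed = 51))
  res <- de_analysis(sim$counts, fdr = 0.05)
  expect_s3_class(res, "de_result")
  expect_true(all(res$PValue >= 0 & res$PValue <= 1))
  expect_true(all(res$FDR >= res$PValue - 1e-12))
  expect_true(all(res$FDR <= 1))
  expect_equal(res$is_de, res$FDR < 0.05)
  expect_gt(mean(res$is_de[sim$truth$is_de]), 0.5)
})
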