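test_that("simulated annotations respect bounds, ordering and determinism", {
  spec <- genome_spec(chromosome_names = c("c1", "c2"),
                      chromosome_lengths = c(1e7, 5e6),
                      n_genes_per_chromosome = c(400, 200), seed = 42)
  ann <- simulate_annotation(spec)
  expect_s3_class(ann, "gene_annotation")
  expect_equal(nrow(ann), 600)
  expect_true(all(ann$start >= 0))
  expect_true(all(ann$end[ann$chrom == "c1"] <= 1e7))
  expect_true(all(ann$end[ann$chrom == "c2"] <= 5e6))
  expect_false(anyDuplicated(ann$gene_id) > 0)
  by_chr <- split(ann$start, ann$chrom)
  expect_true(all(vapply(by_chr, function(s) !is.unsorted(s), logical(1))))
  expect_identical(ann, simulate_annotation(spec))

  empty <- simulate_annotation(genome_spec(
    chromosome_names = "c1", chromosome_lengths = 1e6,
    n_genes_per_chromosome = 0, seed = 1))
  expect_equal(nrow(empty), 0)
})

test_that("infeasible gene packing errors and names the chromosome", {
  spec <- genome_spec(chromosome_names = c("big", "tiny"),
                      chromosome_lengths = c(1e8, 30000),
                      n_genes_per_chromosome = c(10, 50),
                      gene_length_range = c(1000, 2000), seed = 1)
  expect_error(simulate_annotation(spec), "tiny")
})

test_that("uniform placement approaches the L/3 mean-distance law", {
  spec <- genome_spec(chromosome_names = "c1", chromosome_lengths = 1e7,
                      n_genes_per_chromosome = 2000, seed = 7)
  ann <- simulate_annotation(spec)
  m <- mean_pairwise_distance(sort(ann$midpoint))$mean
  expect_lt(abs(m - 1e7 / 3) / (1e7 / 3), 0.05)
})

test_that("clustered placement shrinks the mean pairwise distance", {
  # with k clusters the expected all-pairs mean is ~ (1 - 1/k) L/3, so
  # average the ratio over chromosomes and use k = 3 for a robust margin
  L <- 1e7
  spec <- genome_spec(chromosome_names = paste0("c", 1:10),
                      chromosome_lengths = rep(L, 10),
                      n_genes_per_chromosome = rep(200, 10),
                      placement_mode = "clustered", cluster_count = 3,
                      cluster_spread = L / 500, seed = 7)
  ann <- simulate_annotation(spec)
  ratio <- vapply(levels(ann$chrom), function(ch) {
    mean_pairwise_distance(sort(ann$midpoint[ann$chrom == ch]))$mean
  }, numeric(1)) / (L / 3)
  expect_lt(mean(ratio), 0.8)
})

test_that("island simulation covers genes as expected and handles edges", {
  ann <- uniform_annotation(2000, L = 2e7, seed = 3)

  none <- simulate_islands(ann, c(chr1 = 2e7), n_islands = 0)
  expect_equal(nrow(none$islands), 0)
  expect_length(none$covered_genes, 0)

  isl <- simulate_islands(ann, c(chr1 = 2e7), n_islands = 10,
                          island_length = 1e5, seed = 5)
  expect_equal(nrow(isl$islands), 10)
  # non-overlapping
  o <- order(isl$islands$start)
  expect_true(all(diff(isl$islands$start[o]) >= 1e5))
  # covered-gene count near n * covered fraction (Poisson error band)
  expected <- 2000 * (10 * 1e5 / 2e7)
  expect_lt(abs(length(isl$covered_genes) - expected),
            4 * sqrt(expected) + 1)

  # islands tiling a whole chromosome cover every gene
  tile <- gene_annotation(rep("chr1", 20), seq(0, 1.9e7, by = 1e6),
                          seq(1e6, 2e7, by = 1e6), paste0("tile", 1:20))
  covered <- count_island_genes(ann, tile)$island_genes
  expect_setequal(covered, ann$gene_id)

  expect_error(simulate_islands(ann, c(chr1 = 2e7), n_islands = 1,
                                island_length = 3e7),
               "island_length")
})

test_that("simulated counts match the NB model and ground truth bookkeeping", {
  ann <- uniform_annotation(300, seed = 4)
  spec <- expression_spec(library_sizes = rep(1e6, 8),
                          de_fraction = 0.2, seed = 9)
  sim <- simulate_counts(ann, spec)
  expect_s3_class(sim$counts, "count_matrix")
  expect_equal(dim(sim$counts$counts), c(300, 8))
  expect_equal(sum(sim$truth$is_de), round(0.2 * 300))
  n_up <- sum(sim$truth$true_logfc > 0)
  expect_lte(abs(n_up - round(spec$prop_up * 60)), 1)
  expect_true(all(sim$truth$true_logfc[!sim$truth$is_de] == 0))

  # determinism
  sim2 <- simulate_counts(ann, spec)
  expect_identical(sim$counts$counts, sim2$counts$counts)

  # dispersion 0 gives Poisson-like counts (variance ~ mean)
  p0 <- simulate_counts(ann, expression_spec(
    library_sizes = rep(1e6, 40), n_samples_group_a = 20,
    n_samples_group_b = 20, de_fraction = 0, dispersion = 0, seed = 2))
  mu <- rowMeans(p0$counts$counts)
  v <- apply(p0$counts$counts, 1, var)
  keep <- mu > 20
  expect_lt(abs(median(v[keep] / mu[keep]) - 1), 0.3)
})

test_that("NB moments across many replicate samples match mu + phi mu^2", {
  ann <- uniform_annotation(5, seed = 6)
  phi <- 0.2
  sim <- simulate_counts(ann, expression_spec(
    n_samples_group_a = 5000, n_samples_group_b = 5000,
    library_sizes = rep(1e6, 10000), de_fraction = 0,
    dispersion = phi, seed = 8))
  mu <- rowMeans(sim$counts$counts)
  v <- apply(sim$counts$counts, 1, var)
  expected <- mu + phi * mu^2
  expect_true(all(abs(v / expected - 1) < 0.15))
})

test_that("island-linked DE placement enriches island genes", {
  ann <- uniform_annotation(2000, L = 2e7, seed = 10)
  isl <- simulate_islands(ann, c(chr1 = 2e7), n_islands = 10,
                          island_length = 3e5, seed = 11)
  spec <- expression_spec(library_sizes = rep(1e6, 8), de_fraction = 0.15,
                          de_placement = "island_linked", island_odds = 5,
                          seed = 12)
  sim <- simulate_counts(ann, spec, islands = isl$islands)
  de_ids <- sim$truth$gene_id[sim$truth$is_de]
  in_isl <- ann$gene_id %in% isl$covered_genes
  rate_island <- mean(ann$gene_id[in_isl] %in% de_ids)
  rate_rest <- mean(ann$gene_id[!in_isl] %in% de_ids)
  expect_gt(rate_island, 2 * rate_rest)
  expect_error(simulate_counts(ann, spec), "islands")
})
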