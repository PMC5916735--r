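#' All-pairs distances between gene positions
#'
#' Materializes `|x_i - x_j|` for every unordered pair of positions on one
#' chromosome (length `n (n - 1) / 2`). Fine for per-chromosome gene counts;
#' use [mean_pairwise_distance()] when only the mean is needed.
#'
#' @param positions numeric vector of gene positions (midpoints).
#' @return numeric vector of pairwise distances; empty if fewer than two
#'   positions.
#' @export
pairwise_distances <- function(positions) {
  if (length(positions) < 2L) return(numeric(0))
  as.numeric(dist(matrix(positions, ncol = 1L)))
}

#' Mean pairwise distance by prefix sums
#'
#' For sorted positions, `sum_{i<j} (x_j - x_i)` equals
#' `sum_j x_j (2j - n + 1)` over 0-indexed sorted positions, giving the mean
#' over all `n (n - 1) / 2` unordered pairs in O(n) instead of O(n^2). The
#' result equals the brute-force mean exactly. For n i.i.d. uniform
#' positions on `[0, L]` the expectation is `L / 3`.
#'
#' @param positions numeric vector, sorted ascending.
#' @return list with `mean` (NA if fewer than 2 positions) and `n_pairs`.
#' @export
mean_pairwise_distance <- function(positions) {
  n <- length(positions)
  if (n < 2L) return(list(mean = NA_real_, n_pairs = 0))
  if (is.unsorted(positions)) stop("positions must be sorted ascending")
  j <- seq_len(n) - 1
  total <- sum(positions * (2 * j - n + 1))
  n_pairs <- n * (n - 1) / 2
  list(mean = total / n_pairs, n_pairs = n_pairs)
}

de_positions <- function(annotation, de_gene_ids, chromosome) {
  onchr <- annotation[as.character(annotation$chrom) == chromosome, ,
                      drop = FALSE]
  list(all = onchr$midpoint,
       de = onchr$midpoint[onchr$gene_id %in% de_gene_ids])
}

#' Per-chromosome clustering test for DE genes
#'
#' Compares the array of all-pairs intergenic distances among every gene on
#' a chromosome with the same array restricted to the differentially
#' expressed genes, by a two-sample t-test (Welch by default). A DE mean
#' significantly below the all-genes mean indicates spatial clustering of
#' the DE genes; above, dispersion.
#'
#' The DE pair distances are a subset of the all-genes pair distances and
#' pair distances sharing a gene are not independent, so the t-test P-value
#' is approximate by construction; [permutation_clustering_test()] provides
#' a null that respects both features and is reported alongside by
#' [clustering_analysis()].
#'
#' @param annotation a [gene_annotation()].
#' @param de_gene_ids character vector of DE gene ids.
#' @param chromosome chromosome label to test.
#' @param var_equal use the pooled-variance t-test instead of Welch?
#' @return one-row data.frame of class `"clustering_result"`: `chromosome`,
#'   `n_genes`, `n_de_genes`, `mean_dist_all`, `mean_dist_de`,
#'   `t_statistic`, `pvalue`, `perm_pvalue` (NA here), `direction`
#'   (`"clustered"`, `"dispersed"` or `"none"` at P < 0.05). Test fields are
#'   NA when either array has fewer than two distances.
#' @export
clustering_test <- function(annotation, de_gene_ids, chromosome,
                            var_equal = FALSE) {
  pos <- de_positions(annotation, de_gene_ids, chromosome)
  d_all <- pairwise_distances(pos$all)
  d_de <- pairwise_distances(pos$de)
  mean_all <- if (length(d_all)) mean(d_all) else NA_real_
  mean_de <- if (length(d_de)) mean(d_de) else NA_real_
  tstat <- NA_real_
  pval <- NA_real_
  if (length(d_all) >= 2L && length(d_de) >= 2L &&
      (sd(d_all) > 0 || sd(d_de) > 0)) {
    tt <- t.test(d_all, d_de, var.equal = var_equal)
    tstat <- unname(tt$statistic)
    pval <- tt$p.value
  }
  direction <- "none"
  if (!is.na(pval) && pval < 0.05) {
    direction <- if (mean_de < mean_all) "clustered" else "dispersed"
  }
  out <- data.frame(
    chromosome = chromosome,
    n_genes = length(pos$all), n_de_genes = length(pos$de),
    mean_dist_all = mean_all, mean_dist_de = mean_de,
    t_statistic = tstat, pvalue = pval, perm_pvalue = NA_real_,
    direction = direction, stringsAsFactors = FALSE
  )
  class(out) <- c("clustering_result", "data.frame")
  out
}

#' Permutation null for DE-gene spatial clustering
#'
#' The statistic is the mean pairwise distance among the DE genes of the
#' chromosome; the null draws uniform random gene subsets of the same size
#' from the chromosome. The two-sided P-value is
#' `(1 + #{|perm - null_mean| >= |obs - null_mean|}) / (n_perm + 1)`,
#' which is valid (conservative) despite the subset dependence the t-test
#' ignores.
#'
#' @inheritParams clustering_test
#' @param n_perm number of permutations (default 10000; a warning is issued
#'   below 100).
#' @param seed RNG seed.
#' @return list with `perm_pvalue`, `observed` (mean DE pair distance) and
#'   `null_mean`.
#' @export
permutation_clustering_test <- function(annotation, de_gene_ids, chromosome,
                                        n_perm = 10000, seed = 1) {
  if (n_perm < 100) warning("n_perm < 100 gives a coarse P-value")
  pos <- de_positions(annotation, de_gene_ids, chromosome)
  m <- length(pos$de)
  n <- length(pos$all)
  if (m < 2L || n < 2L) {
    return(list(perm_pvalue = NA_real_, observed = NA_real_,
                null_mean = NA_real_))
  }
  obs <- mean_pairwise_distance(sort(pos$de))$mean
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  perm <- vapply(seq_len(n_perm), function(i) {
    mean_pairwise_distance(sort(sample(pos$all, m)))$mean
  }, numeric(1L))
  null_mean <- mean(perm)
  p <- (1 + sum(abs(perm - null_mean) >= abs(obs - null_mean))) /
    (n_perm + 1)
  list(perm_pvalue = min(1, p), observed = obs, null_mean = null_mean)
}

#' Genome-wide clustering analysis
#'
#' Runs [clustering_test()] (and optionally the permutation companion) on
#' every chromosome with at least two genes and two DE genes; chromosomes
#' with fewer are reported with NA test fields.
#'
#' @inheritParams clustering_test
#' @param n_perm permutations per chromosome; 0 skips the permutation test.
#' @param seed RNG seed for the permutation tests.
#' @return a `"clustering_result"` data.frame, one row per chromosome.
#' @export
clustering_analysis <- function(annotation, de_gene_ids, var_equal = FALSE,
                                n_perm = 0, seed = 1) {
  chroms <- levels(annotation$chrom)
  rows <- lapply(seq_along(chroms), function(i) {
    res <- clustering_test(annotation, de_gene_ids, chroms[i], var_equal)
    if (n_perm > 0 && res$n_de_genes >= 2L && res$n_genes >= 2L) {
      res$perm_pvalue <- permutation_clustering_test(
        annotation, de_gene_ids, chroms[i],
        n_perm = n_perm, seed = seed + i
      )$perm_pvalue
    }
    res
  })
  out <- do.call(rbind, rows)
  class(out) <- c("clustering_result", "data.frame")
  out
}
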