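#' Counts per million
#'
#' CPM uses the effective library size (library size times TMM factor). In
#' log mode a pseudo-count stabilizes low counts:
#' `log2((count + prior) / (eff_lib + 2 * prior) * 1e6)`, so a zero count in
#' a million-read library with `prior_count = 0.5` maps to roughly -1.
#'
#' @param cm a [count_matrix()] (run [tmm_factors()] first if TMM-adjusted
#'   CPM is wanted).
#' @param log return log2 values?
#' @param prior_count pseudo-count used in log mode (default 0.5).
#' @return numeric matrix, genes x samples.
#' @export
cpm <- function(cm, log = FALSE, prior_count = 0.5) {
  lib <- eff_lib_size(cm)
  if (any(lib <= 0)) stop("library sizes must be positive")
  if (!log) {
    sweep(cm$counts, 2L, lib / 1e6, "/")
  } else {
    log2(sweep(cm$counts + prior_count, 2L,
               (lib + 2 * prior_count) / 1e6, "/"))
  }
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values: for each sample against a reference, per-gene
#' log-ratios (M) and average log-abundances (A) are computed on
#' library-size-scaled counts, genes with a zero in either sample are
#' dropped, the most extreme 30% of M and 5% of A are trimmed, and the
#' factor is 2 to the precision-weighted mean of the remaining M-values.
#' The reference sample is the one whose upper-quartile CPM is closest to
#' the mean upper-quartile. Factors are rescaled to geometric mean 1, so a
#' pure sequencing-depth difference is absorbed by the library size, not
#' the factor.
#'
#' @param cm a [count_matrix()].
#' @param trim_m two-sided trim fraction on M-values (default 0.30).
#' @param trim_a two-sided trim fraction on A-values (default 0.05).
#' @return the `count_matrix` with `norm_factors` filled in.
#' @references Robinson MD, Oshlack A (2010) Genome Biology 11:R25.
#' @export
tmm_factors <- function(cm, trim_m = 0.30, trim_a = 0.05) {
  counts <- cm$counts
  lib <- cm$lib_size
  if (ncol(counts) < 2L) stop("TMM needs at least two samples")
  if (any(colSums(counts) == 0)) stop("sample with all-zero counts")
  uq <- apply(sweep(counts, 2L, lib / 1e6, "/"), 2L,
              quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(s) {
    tmm_pair(counts[, s], counts[, ref], lib[s], lib[ref],
             trim_m, trim_a)
  }, numeric(1L))
  f <- f / exp(mean(log(f)))
  cm$norm_factors <- f
  cm
}

# one sample vs reference; obs/ref are count vectors, nobs/nref library sizes
tmm_pair <- function(obs, ref, nobs, nref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) return(1)
  obs <- obs[keep]; ref <- ref[keep]
  p_o <- obs / nobs
  p_r <- ref / nref
  m <- log2(p_o / p_r)
  a <- 0.5 * log2(p_o * p_r)
  # asymptotic variance of M (delta method) -> precision weights
  w <- (nobs - obs) / (nobs * obs) + (nref - ref) / (nref * ref)
  fin <- is.finite(m) & is.finite(a) & is.finite(w)
  m <- m[fin]; a <- a[fin]; w <- w[fin]
  if (length(m) == 0L) return(1)
  if (max(abs(m)) < 1e-6) return(1) # identical profiles
  lo_m <- quantile(m, trim_m); hi_m <- quantile(m, 1 - trim_m)
  lo_a <- quantile(a, trim_a); hi_a <- quantile(a, 1 - trim_a)
  keep2 <- m >= lo_m & m <= hi_m & a >= lo_a & a <= hi_a
  if (!any(keep2)) return(1)
  2 ^ (sum(m[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

#' Estimate a common NB dispersion by the method of moments
#'
#' Counts are scaled to a common library size; for each gene the
#' within-group sample mean and variance are pooled across the two groups
#' and a per-gene moment estimate `phi_g = (s^2 - mu) / mu^2` is formed
#' (floored at 0). The common dispersion is the 20% trimmed mean of the
#' per-gene estimates over genes whose mean scaled count is at least
#' `mean_floor`.
#'
#' @param cm a [count_matrix()] with at least two samples in one group.
#' @param mean_floor minimum mean scaled count for a gene to contribute
#'   (default 1).
#' @param trim trimmed-mean fraction (default 0.2).
#' @return a single non-negative dispersion estimate.
#' @export
estimate_common_dispersion <- function(cm, mean_floor = 1, trim = 0.2) {
  tab <- table(cm$group)
  if (all(tab < 2L)) {
    stop("no replicated group: supply a dispersion value explicitly")
  }
  lib <- eff_lib_size(cm)
  scaled <- sweep(cm$counts, 2L, mean(lib) / lib, "*")
  groups <- levels(cm$group)
  stats <- lapply(groups, function(g) {
    x <- scaled[, cm$group == g, drop = FALSE]
    if (ncol(x) < 2L) return(NULL)
    list(n = ncol(x), mean = rowMeans(x), var = apply(x, 1L, var))
  })
  stats <- Filter(Negate(is.null), stats)
  df <- vapply(stats, function(s) s$n - 1L, numeric(1L))
  mu <- rowMeans(do.call(cbind, lapply(stats, `[[`, "mean")))
  s2 <- Reduce(`+`, Map(function(s, d) d * s$var, stats, df)) / sum(df)
  keep <- mu >= mean_floor
  if (!any(keep)) return(0)
  phi_g <- pmax(0, (s2[keep] - mu[keep]) / mu[keep] ^ 2)
  mean(phi_g, trim = trim)
}

#' Benjamini-Hochberg step-up adjustment with an explicit test universe
#'
#' Standard BH adjustment, except that the total number of tests `n_total`
#' may exceed the number of supplied P-values. This supports adjusting a
#' printed top-k excerpt of a larger experiment: each sorted P-value is
#' scaled by `n_total / rank` and the step-up minimum is taken within the
#' supplied list (tail tests are assumed not to lower the running minimum).
#' With `n_total` equal to the list length this is exactly
#' `p.adjust(method = "BH")`.
#'
#' @param pvalues numeric vector of P-values in \[0, 1\].
#' @param n_total total number of tests, at least `length(pvalues)`.
#' @return adjusted values in the original order, capped at 1.
#' @examples
#' # the smallest of 22,456 tests
#' bh_adjust(2.116876e-51, n_total = 22456)
#' @export
bh_adjust <- function(pvalues, n_total = length(pvalues)) {
  k <- length(pvalues)
  if (k == 0L) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("pvalues must lie in [0, 1]")
  }
  if (n_total < k) stop("n_total must be >= length(pvalues)")
  ord <- order(pvalues)
  raw <- pvalues[ord] * n_total / seq_len(k)
  adj <- pmin(1, rev(cummin(rev(raw))))
  out <- numeric(k)
  out[ord] <- adj
  out
}

#' Conditioned negative-binomial exact test for two groups
#'
#' The classic exact test for two-group RNA-seq comparison with a common
#' dispersion. Counts are first scaled to a common effective library size
#' (the geometric mean of effective library sizes) and rounded to integer
#' pseudo-counts. For each gene the two group sums `y_A`, `y_B` are then
#' exchangeable NB variables with aggregate size `n_g / phi`; conditioning
#' on `s = y_A + y_B`, the probability of every split is computed from the
#' NB sum distributions and the two-sided P-value is twice the smaller
#' cumulative tail (including the observed split), capped at 1. With
#' `dispersion = 0` the conditional distribution degenerates to
#' binomial(s, n_A / (n_A + n_B)).
#'
#' `logFC` is `log2((y_B + 0.5 n_B) / (y_A + 0.5 n_A)) - log2(n_B / n_A)`
#' (group B over group A, half-count stabilized); `logCPM` is the log2 CPM
#' of the average pseudo-count. Genes with `s = 0` are untestable and get
#' `pvalue = 1`, `logFC = 0`.
#'
#' @param cm a [count_matrix()] (TMM factors honoured if present).
#' @param dispersion common NB dispersion `phi` (variance = mu + phi mu^2).
#' @return data.frame with `gene_id`, `logFC`, `logCPM`, `PValue`,
#'   `untestable`.
#' @references Robinson MD, Smyth GK (2008) Biostatistics 9:321-332.
#' @export
nb_exact_test <- function(cm, dispersion) {
  stopifnot(dispersion >= 0)
  lib <- eff_lib_size(cm)
  common_lib <- exp(mean(log(lib)))
  pseudo <- round(sweep(cm$counts, 2L, common_lib / lib, "*"))
  ga <- levels(cm$group)[1L]
  na <- sum(cm$group == ga)
  nb <- sum(cm$group != ga)
  ya <- rowSums(pseudo[, cm$group == ga, drop = FALSE])
  yb <- rowSums(pseudo[, cm$group != ga, drop = FALSE])
  pv <- exact_nb_pvalue(ya, yb, na, nb, dispersion)
  logfc <- log2((yb + 0.5 * nb) / (ya + 0.5 * na)) - log2(nb / na)
  logfc[ya + yb == 0] <- 0
  ave <- (ya + yb) / (na + nb)
  logcpm <- log2((ave + 0.5) / (common_lib + 1) * 1e6)
  data.frame(
    gene_id = rownames(cm$counts),
    logFC = logfc, logCPM = logcpm, PValue = pv,
    untestable = (ya + yb) == 0,
    stringsAsFactors = FALSE
  )
}

# vectorized over genes; conditional two-sided exact P for splits (ya, yb)
exact_nb_pvalue <- function(ya, yb, na, nb, phi) {
  s <- ya + yb
  pv <- rep(1, length(s))
  todo <- which(s > 0)
  for (g in todo) {
    pv[g] <- exact_split_pvalue(ya[g], s[g], na, nb, phi)
  }
  pv
}

# P-value for one gene: observed split (k, s - k) of total s between
# aggregates of na and nb samples sharing per-sample mean mu = s / (na + nb)
exact_split_pvalue <- function(k, s, na, nb, phi) {
  n <- na + nb
  if (phi == 0) {
    # Poisson limit: conditional distribution is binomial(s, na / n)
    lo <- pbinom(k, s, na / n)
    hi <- pbinom(k - 1, s, na / n, lower.tail = FALSE)
    return(min(1, 2 * min(lo, hi)))
  }
  mu <- s / n
  size_a <- na / phi
  size_b <- nb / phi
  # joint density of a split j, shared success probability cancels in ratio
  dens <- function(j) {
    dnbinom(j, size = size_a, mu = na * mu) *
      dnbinom(s - j, size = size_b, mu = nb * mu)
  }
  denom <- dnbinom(s, size = n / phi, mu = s)
  center <- s * na / n
  # sum the shorter tail exactly; complement gives the other (both tails
  # include the observed split)
  if (k <= center) {
    lo <- sum(dens(0:k)) / denom
    hi <- 1 - lo + dens(k) / denom
  } else {
    hi <- sum(dens(k:s)) / denom
    lo <- 1 - hi + dens(k) / denom
  }
  min(1, 2 * min(lo, hi))
}

#' Two-group differential-expression analysis
#'
#' The full expression stage: TMM normalization, common-dispersion
#' estimation (unless supplied), the NB exact test, BH FDR and the DE flag.
#'
#' @param cm a [count_matrix()].
#' @param fdr FDR threshold for the `is_de` flag (default 0.05).
#' @param dispersion `"auto"` (moment estimate) or a non-negative number.
#' @param n_total test universe for BH (defaults to the number of genes).
#' @return A data.frame of class `"de_result"` with columns `gene_id`,
#'   `logFC` (group B over group A), `logCPM`, `PValue`, `FDR`, `is_de`,
#'   plus attributes `dispersion`, `fdr_threshold`, `norm_factors`.
#' @examples
#' sim <- simulate_counts(simulate_annotation(genome_spec(
#'   chromosome_names = "chrI", chromosome_lengths = 5e6,
#'   n_genes_per_chromosome = 200, seed = 1)),
#'   expression_spec(library_sizes = rep(1e6, 8), seed = 1))
#' res <- de_analysis(sim$counts)
#' table(planted = sim$truth$is_de, detected = res$is_de)
#' @export
de_analysis <- function(cm, fdr = 0.05, dispersion = "auto",
                        n_total = nrow(cm$counts)) {
  cm <- tmm_factors(cm)
  phi <- if (identical(dispersion, "auto")) {
    estimate_common_dispersion(cm)
  } else {
    as.numeric(dispersion)
  }
  res <- nb_exact_test(cm, phi)
  res$FDR <- bh_adjust(res$PValue, n_total = n_total)
  res$is_de <- res$FDR < fdr & !res$untestable
  res$untestable <- NULL
  attr(res, "dispersion") <- phi
  attr(res, "fdr_threshold") <- fdr
  attr(res, "norm_factors") <- cm$norm_factors
  class(res) <- c("de_result", "data.frame")
  res
}

#' @export
print.de_result <- function(x, ...) {
  up <- sum(x$is_de & x$logFC > 0)
  dn <- sum(x$is_de & x$logFC < 0)
  cat("DE analysis:", nrow(x), "genes tested, dispersion =",
      signif(attr(x, "dispersion"), 4), "\n")
  cat("DE at FDR <", attr(x, "fdr_threshold"), ":", sum(x$is_de),
      sprintf("(%d up, %d down in group B)\n", up, dn))
  print.data.frame(head(as.data.frame(x)[order(x$PValue), ], 6L), ...)
  invisible(x)
}
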