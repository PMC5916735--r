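#' Genes overlapping divergence-island intervals
#'
#' A gene overlaps an island if the intersection of their 0-based half-open
#' intervals is at least 1 bp; each gene is counted once no matter how many
#' islands it touches. Islands on chromosomes absent from the annotation
#' are ignored with a warning.
#'
#' @param annotation a [gene_annotation()] of genes.
#' @param islands a [gene_annotation()]-like table of island intervals.
#' @param de_gene_ids optional character vector of DE gene ids.
#' @return list with `island_genes` (ids of all genes overlapping any
#'   island) and, when `de_gene_ids` is given, `de_island_genes` (the
#'   intersection).
#' @export
count_island_genes <- function(annotation, islands, de_gene_ids = NULL) {
  unknown <- setdiff(unique(as.character(islands$chrom)),
                     unique(as.character(annotation$chrom)))
  if (length(unknown)) {
    warning("islands on chromosomes absent from the annotation ignored: ",
            paste(unknown, collapse = ", "))
    islands <- islands[!as.character(islands$chrom) %in% unknown, ,
                       drop = FALSE]
  }
  if (nrow(islands) == 0L || nrow(annotation) == 0L) {
    out <- list(island_genes = character(0))
    if (!is.null(de_gene_ids)) out$de_island_genes <- character(0)
    return(out)
  }
  # half-open [start, end) -> 1-based closed IRanges [start + 1, end]
  g <- GenomicRanges::GRanges(
    as.character(annotation$chrom),
    IRanges::IRanges(annotation$start + 1, annotation$end)
  )
  isl <- GenomicRanges::GRanges(
    as.character(islands$chrom),
    IRanges::IRanges(islands$start + 1, islands$end)
  )
  hits <- GenomicRanges::findOverlaps(g, isl, minoverlap = 1L)
  idx <- unique(S4Vectors::queryHits(hits))
  out <- list(island_genes = annotation$gene_id[sort(idx)])
  if (!is.null(de_gene_ids)) {
    out$de_island_genes <- intersect(out$island_genes, de_gene_ids)
  }
  out
}

#' Poisson enrichment test for DE genes in islands
#'
#' Under island-agnostic placement, the number of DE genes falling in
#' islands is approximately Poisson with mean
#' `lambda = n_de * m_island / n_total` (gene-count proportions). The
#' P-value is the upper tail `P(X >= k)` (enrichment); the hypergeometric
#' upper tail - drawing `n_de` genes from `n_total` with `m_island`
#' successes - is reported alongside as `alt_pvalue`. Set
#' `alternative = "less"` for depletion (`P(X <= k)`).
#'
#' @param n_total total annotated genes.
#' @param m_island genes overlapping islands.
#' @param n_de DE genes.
#' @param k_observed DE genes overlapping islands.
#' @param alternative `"greater"` (enrichment, default) or `"less"`.
#' @return one-row data.frame of class `"enrichment_result"` with fields
#'   `n_total`, `m_island`, `n_de`, `k_observed`, `lambda_expected`,
#'   `pvalue`, `alt_pvalue`.
#' @examples
#' poisson_enrichment(n_total = 29245, m_island = 212,
#'                    n_de = 2982, k_observed = 28)
#' @export
poisson_enrichment <- function(n_total, m_island, n_de, k_observed,
                               alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (m_island > n_total) stop("m_island cannot exceed n_total")
  if (n_de > n_total) stop("n_de cannot exceed n_total")
  if (k_observed > n_de) stop("k_observed cannot exceed n_de")
  if (k_observed > m_island) stop("k_observed cannot exceed m_island")
  lambda <- n_de * m_island / n_total
  if (alternative == "greater") {
    pval <- ppois(k_observed - 1, lambda, lower.tail = FALSE)
    alt <- phyper(k_observed - 1, m_island, n_total - m_island, n_de,
                  lower.tail = FALSE)
  } else {
    pval <- ppois(k_observed, lambda)
    alt <- phyper(k_observed, m_island, n_total - m_island, n_de)
  }
  out <- data.frame(
    n_total = n_total, m_island = m_island, n_de = n_de,
    k_observed = k_observed, lambda_expected = lambda,
    pvalue = pval, alt_pvalue = alt
  )
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Island enrichment from annotation, islands and a DE gene set
#'
#' Counts island-overlapping genes with [count_island_genes()] and applies
#' [poisson_enrichment()].
#'
#' @inheritParams count_island_genes
#' @param de_gene_ids character vector of DE gene ids.
#' @param alternative passed to [poisson_enrichment()].
#' @return an `"enrichment_result"`.
#' @export
island_enrichment <- function(annotation, islands, de_gene_ids,
                              alternative = "greater") {
  sets <- count_island_genes(annotation, islands, de_gene_ids)
  poisson_enrichment(
    n_total = nrow(annotation),
    m_island = length(sets$island_genes),
    n_de = length(unique(de_gene_ids)),
    k_observed = length(sets$de_island_genes),
    alternative = alternative
  )
}
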