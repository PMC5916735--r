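#' Construct a gene annotation table
#'
#' The coordinate substrate for all positional statistics. Coordinates are
#' 0-based half-open (BED convention) throughout the package; the derived
#' `midpoint` column (`floor((start + end) / 2)`) is the gene position used
#' by the intergenic-distance statistics. Genes are sorted by
#' (chromosome, start); chromosome order follows first appearance in the
#' input, not alphabetical order.
#'
#' @param chrom character vector of chromosome labels.
#' @param start,end integer vectors, 0-based half-open interval per gene.
#' @param gene_id character vector of unique gene identifiers.
#' @param strand optional strand (`"+"`, `"-"`, `"."`); parsed if present but
#'   ignored by every statistic in the package.
#' @return A `data.frame` of class `"gene_annotation"` with columns `chrom`
#'   (factor, levels in first-appearance order), `start`, `end`, `gene_id`,
#'   `midpoint` and optionally `strand`, sorted by (chromosome, start).
#' @examples
#' ann <- gene_annotation("chrI", 0L, 100L, "g1")
#' ann$midpoint # 50
#' @export
gene_annotation <- function(chrom, start, end, gene_id, strand = NULL) {
  n <- length(chrom)
  stopifnot(length(start) == n, length(end) == n, length(gene_id) == n)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (n > 0) {
    if (any(start < 0)) stop("negative start coordinate")
    if (any(start >= end)) stop("start must be < end for all genes")
    if (anyDuplicated(gene_id)) {
      stop("duplicate gene id: ", gene_id[duplicated(gene_id)][1L])
    }
  }
  chrom <- factor(as.character(chrom), levels = unique(as.character(chrom)))
  ann <- data.frame(
    chrom = chrom, start = start, end = end,
    gene_id = as.character(gene_id),
    midpoint = floor((start + end) / 2),
    stringsAsFactors = FALSE
  )
  if (!is.null(strand)) ann$strand <- as.character(strand)
  ann <- ann[order(as.integer(ann$chrom), ann$start), , drop = FALSE]
  rownames(ann) <- NULL
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("Gene annotation:", nrow(x), "genes on",
      nlevels(x$chrom), "chromosomes\n")
  print.data.frame(head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat("...", nrow(x) - 6L, "more genes\n")
  invisible(x)
}

#' Construct a two-group count matrix
#'
#' Container for integer read counts (genes x samples) with the two-level
#' group factor and per-sample library sizes needed by normalization and the
#' exact test. Library size defaults to the column sum but can be supplied
#' explicitly (e.g. total mapped reads when these differ from in-gene
#' counts).
#'
#' @param counts numeric matrix of non-negative integers, genes in rows,
#'   samples in columns; `dimnames` supply gene and sample ids.
#' @param group vector coercible to a factor assigning each sample to one of
#'   exactly two groups.
#' @param lib_size optional numeric vector of per-sample library sizes;
#'   defaults to `colSums(counts)`.
#' @return A list of class `"count_matrix"` with elements `counts`, `group`,
#'   `lib_size`, and `norm_factors` (all 1 until [tmm_factors()] is applied).
#' @seealso [read_counts()], [tmm_factors()], [de_analysis()]
#' @export
count_matrix <- function(counts, group, lib_size = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("gene_%d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("sample_%d", seq_len(ncol(counts)))
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8)) {
    bad <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)[1L, ]
    stop("non-integer count for gene '", rownames(counts)[bad[1L]],
         "', sample '", colnames(counts)[bad[2L]], "'")
  }
  group <- factor(group)
  if (length(group) != ncol(counts)) {
    stop("group must have one label per sample")
  }
  if (nlevels(group) != 2L) stop("two groups required")
  if (any(table(group) < 1L)) stop("each group needs at least one sample")
  if (is.null(lib_size)) lib_size <- colSums(counts)
  lib_size <- as.numeric(lib_size)
  if (length(lib_size) != ncol(counts) || any(lib_size <= 0)) {
    stop("lib_size must be positive, one value per sample")
  }
  structure(
    list(counts = counts, group = group, lib_size = lib_size,
         norm_factors = rep(1, ncol(counts))),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("Count matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples\n")
  cat("Groups:", paste(sprintf("%s (n=%d)", levels(x$group),
                               table(x$group)), collapse = ", "), "\n")
  cat("Library sizes:", paste(format(x$lib_size, big.mark = ","),
                              collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# effective library sizes = lib_size * TMM factor
eff_lib_size <- function(cm) cm$lib_size * cm$norm_factors
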