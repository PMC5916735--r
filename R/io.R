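#' Read a BED file into a gene annotation
#'
#' Tolerant of 3- to 6-column BED. `track`, `browser` and `#` comment lines
#' are skipped. With only three columns, gene ids are auto-generated as
#' `chrom:start-end`. Coordinates are validated (0 <= start < end, unique
#' ids) and offending records are reported with their line number. Strand
#' (column 6) is kept if present but ignored by all statistics.
#'
#' @param path path to a BED file.
#' @return A [gene_annotation()] (also used for island intervals).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) &
    nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(gene_annotation(character(), integer(), integer(), character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("line ", lineno[which(nf < 3L)[1L]], ": fewer than 3 BED columns")
  }
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop("line ", lineno[bad[1L]], ": non-numeric coordinate")
  }
  if (any(start < 0)) {
    stop("line ", lineno[which(start < 0)[1L]], ": negative coordinate")
  }
  if (any(start >= end)) {
    stop("line ", lineno[which(start >= end)[1L]], ": start >= end")
  }
  name <- ifelse(nf >= 4L, vapply(fields, function(f) f[4L], ""),
                 sprintf("%s:%d-%d", chrom, start, end))
  if (anyDuplicated(name)) {
    first_dup <- which(duplicated(name))[1L]
    stop("line ", lineno[first_dup], ": duplicate gene id '",
         name[first_dup], "'")
  }
  strand <- if (any(nf >= 6L)) {
    vapply(fields, function(f) if (length(f) >= 6L) f[6L] else ".", "")
  } else NULL
  gene_annotation(chrom, start, end, name, strand = strand)
}

#' Write a gene annotation (or island set) as BED
#'
#' Four columns (chrom, start, end, name), 0-based half-open,
#' tab-separated, no header.
#'
#' @param annotation a [gene_annotation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(annotation, path) {
  df <- data.frame(chrom = as.character(annotation$chrom),
                   start = format(annotation$start, scientific = FALSE,
                                  trim = TRUE),
                   end = format(annotation$end, scientific = FALSE,
                                trim = TRUE),
                   name = annotation$gene_id)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene features from a GFF3 file
#'
#' Extracts `gene`-type features and converts the 1-based closed GFF
#' coordinates to the package's 0-based half-open convention. Gene ids are
#' taken from the `ID` attribute. Requires the `rtracklayer` package.
#'
#' @param path path to a GFF3 file.
#' @return A [gene_annotation()].
#' @export
read_gff_genes <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_gff_genes() requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
    sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(gr)),
            GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
  gene_annotation(as.character(GenomicRanges::seqnames(gr)),
                  GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
                  ids, strand = as.character(GenomicRanges::strand(gr)))
}

#' Read a counts TSV into a count matrix
#'
#' Expects a header row of sample ids with gene ids in the first column.
#' Every cell must be a non-negative integer; every sample must be assigned
#' to one of exactly two groups by `group_map`.
#'
#' @param path path to a tab-separated counts file.
#' @param group_map named vector mapping sample id to group label, or a path
#'   to a two-column (sample, group) TSV without header.
#' @param lib_size optional per-sample library sizes (named or in column
#'   order); defaults to column sums.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, group_map, lib_size = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("counts file needs a gene column and >=2 samples")
  gene_ids <- as.character(tab[[1L]])
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric entries in counts file")
  dimnames(mat) <- list(gene_ids, colnames(tab)[-1L])
  if (is.character(group_map) && length(group_map) == 1L &&
      file.exists(group_map)) {
    gm <- read.table(group_map, header = FALSE, sep = "\t",
                     stringsAsFactors = FALSE)
    group_map <- setNames(as.character(gm[[2L]]), as.character(gm[[1L]]))
  }
  missing <- setdiff(colnames(mat), names(group_map))
  if (length(missing)) {
    stop("samples without a group assignment: ",
         paste(missing, collapse = ", "))
  }
  group <- unname(group_map[colnames(mat)])
  if (length(unique(group)) != 2L) stop("two groups required")
  if (any(table(group) < 2L)) stop("need >=2 samples per group")
  if (!is.null(lib_size) && !is.null(names(lib_size))) {
    lib_size <- unname(lib_size[colnames(mat)])
  }
  count_matrix(mat, group, lib_size = lib_size)
}

#' Write counts as TSV
#'
#' Header row of sample ids, first column `gene_id`.
#'
#' @param cm a [count_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path) {
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a result table as TSV
#'
#' Column order is fixed per result type; P-values and FDRs are written in
#' scientific notation with 6 significant digits so round-trips reproduce
#' values to printed precision.
#'
#' \describe{
#'   \item{`de_result`}{`gene_id, logFC, logCPM, pvalue, fdr, is_de`}
#'   \item{`clustering_result`}{`chromosome, n_genes, n_de_genes,
#'     mean_dist_all, mean_dist_de, t_statistic, pvalue, perm_pvalue,
#'     direction`}
#'   \item{`enrichment_result`}{`n_total, m_island, n_de, k_observed,
#'     lambda_expected, pvalue, alt_pvalue`}
#' }
#'
#' @param result a result object produced by the pipeline.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path) UseMethod("write_results")

fmt_p <- function(p) {
  ifelse(is.na(p), "NA", sprintf("%.6e", p))
}

#' @export
write_results.de_result <- function(result, path) {
  df <- data.frame(
    gene_id = result$gene_id,
    logFC = sprintf("%.6f", result$logFC),
    logCPM = sprintf("%.6f", result$logCPM),
    pvalue = fmt_p(result$PValue),
    fdr = fmt_p(result$FDR),
    is_de = result$is_de
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
write_results.clustering_result <- function(result, path) {
  df <- data.frame(
    chromosome = result$chromosome,
    n_genes = result$n_genes,
    n_de_genes = result$n_de_genes,
    mean_dist_all = sprintf("%.3f", result$mean_dist_all),
    mean_dist_de = ifelse(is.na(result$mean_dist_de), "NA",
                          sprintf("%.3f", result$mean_dist_de)),
    t_statistic = ifelse(is.na(result$t_statistic), "NA",
                         sprintf("%.6f", result$t_statistic)),
    pvalue = fmt_p(result$pvalue),
    perm_pvalue = fmt_p(result$perm_pvalue),
    direction = result$direction
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
write_results.enrichment_result <- function(result, path) {
  df <- data.frame(
    n_total = result$n_total, m_island = result$m_island,
    n_de = result$n_de, k_observed = result$k_observed,
    lambda_expected = sprintf("%.6f", result$lambda_expected),
    pvalue = fmt_p(result$pvalue),
    alt_pvalue = fmt_p(result$alt_pvalue)
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
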