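#' Default pipeline configuration
#'
#' A flat named list controlling [run_pipeline()]. In real-data mode supply
#' `counts`, `groups` (named vector or sample/group TSV) and `annotation`
#' (BED); with all three `NULL` the pipeline runs in synthetic mode using
#' `genome` and `expression` specs. `islands` (BED or island table) is
#' optional - without it the enrichment stage is skipped.
#'
#' @param ... overrides of the defaults.
#' @return named list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    counts = NULL, groups = NULL, annotation = NULL, islands = NULL,
    out_dir = NULL,
    fdr = 0.05, dispersion = "auto",
    t_test = c("welch"), n_perm = 0, seed = 1,
    mds_top_n = 500,
    genome = genome_spec(),
    expression = expression_spec()
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Run the full ecotype expression pipeline
#'
#' Stages: load or simulate inputs, TMM + NB exact test + BH FDR,
#' leading-logFC MDS, per-chromosome clustering test of the DE genes, and
#' (when islands are available) Poisson island enrichment. All randomness
#' derives from the seeds in the config, so a rerun with the same config
#' produces identical outputs. When `out_dir` is set, every result table is
#' written as TSV together with a plain-text run manifest (configuration
#' echo, seeds, and gene-count bookkeeping at each stage).
#'
#' @param config a [pipeline_config()].
#' @return list with `annotation`, `counts`, `truth` (synthetic mode only),
#'   `de`, `mds`, `clustering`, `enrichment` (NULL when skipped) and
#'   `manifest` (character vector).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  synthetic <- is.null(config$counts)
  manifest <- c(
    "ecotypeDE run manifest",
    paste0("mode: ", if (synthetic) "synthetic" else "real"),
    paste0("seed: ", config$seed),
    paste0("fdr: ", config$fdr)
  )
  truth <- NULL
  islands <- NULL
  if (synthetic) {
    ann <- simulate_annotation(config$genome)
    isl_sim <- simulate_islands(ann, setNames(
      config$genome$chromosome_lengths, config$genome$chromosome_names),
                                seed = config$seed + 1L)
    islands <- isl_sim$islands
    sim <- simulate_counts(ann, config$expression, islands = islands)
    cm <- sim$counts
    truth <- sim$truth
    manifest <- c(manifest,
                  paste0("genes simulated: ", nrow(ann)),
                  paste0("planted DE: ", sum(truth$is_de)))
  } else {
    ann <- if (is.character(config$annotation)) {
      read_bed(config$annotation)
    } else config$annotation
    cm <- if (is.character(config$counts)) {
      read_counts(config$counts, config$groups)
    } else config$counts
    if (!is.null(config$islands)) {
      islands <- if (is.character(config$islands)) {
        read_bed(config$islands)
      } else config$islands
    }
  }

  de <- de_analysis(cm, fdr = config$fdr, dispersion = config$dispersion)
  de_ids <- de$gene_id[de$is_de]
  manifest <- c(
    manifest,
    paste0("genes in: ", nrow(cm$counts)),
    paste0("genes tested: ", sum(!is.na(de$PValue))),
    paste0("dispersion: ", signif(attr(de, "dispersion"), 6)),
    paste0("TMM factors: ",
           paste(signif(attr(de, "norm_factors"), 4), collapse = " ")),
    paste0("DE at FDR < ", config$fdr, ": ", length(de_ids),
           " (up ", sum(de$is_de & de$logFC > 0),
           ", down ", sum(de$is_de & de$logFC < 0), ")")
  )

  mds <- mds_leading_logfc(cpm(cm, log = TRUE), top_n = config$mds_top_n)

  clustering <- clustering_analysis(
    ann, de_ids, var_equal = identical(config$t_test, "pooled"),
    n_perm = config$n_perm, seed = config$seed
  )
  manifest <- c(manifest,
                paste0("chromosomes tested: ",
                       sum(!is.na(clustering$pvalue))))

  enrichment <- NULL
  if (!is.null(islands)) {
    enrichment <- island_enrichment(ann, islands, de_ids)
    manifest <- c(manifest,
                  paste0("island genes: ", enrichment$m_island,
                         "; DE in islands: ", enrichment$k_observed,
                         "; enrichment P = ",
                         signif(enrichment$pvalue, 4)))
  } else {
    manifest <- c(manifest, "enrichment: skipped (no islands)")
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results(de, file.path(config$out_dir, "results_de.tsv"))
    write_results(clustering,
                  file.path(config$out_dir, "results_clustering.tsv"))
    if (!is.null(enrichment)) {
      write_results(enrichment,
                    file.path(config$out_dir, "results_enrichment.tsv"))
    }
    write_bed(ann, file.path(config$out_dir, "annotation.bed"))
    if (!is.null(islands)) {
      write_bed(islands, file.path(config$out_dir, "islands.bed"))
    }
    if (!is.null(truth)) {
      write.table(truth, file.path(config$out_dir, "truth.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    mds_df <- data.frame(sample = rownames(mds$points),
                         round(mds$points, 6))
    write.table(mds_df, file.path(config$out_dir, "mds.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(manifest, file.path(config$out_dir, "manifest.txt"))
  }

  list(annotation = ann, counts = cm, truth = truth, de = de, mds = mds,
       clustering = clustering, enrichment = enrichment,
       manifest = manifest)
}

#' Worked-example table: top DE genes of a stickleback gill comparison
#'
#' The ten genes with the largest expression differences between marine and
#' freshwater stickleback gill samples in a published 4 + 4 comparison of
#' 22,456 annotated genes, with their binary log fold changes, average
#' abundances and exact-test P-values. Used throughout the documentation
#' and tests as the worked-example surface for [bh_adjust()]: adjusting
#' these ten P-values as the ten smallest of `n_total = 22456` tests
#' reproduces their published FDR column.
#'
#' @return data.frame with `gene_id`, `logFC`, `logCPM`, `pvalue`.
#' @examples
#' tab <- stickleback_top_genes()
#' signif(bh_adjust(tab$pvalue, n_total = 22456), 7)
#' @export
stickleback_top_genes <- function() {
  data.frame(
    gene_id = c("ENSGACG00000013714", "ENSGACG00000011986",
                "ENSGACG00000001275", "ENSGACG00000014967",
                "ENSGACG00000018764", "ENSGACG00000014959",
                "ENSGACG00000003404", "ENSGACG00000001373",
                "ENSGACG00000019813", "ENSGACG00000014691"),
    logFC = c(-4.193912, -5.259545, 3.860307, 4.253744, -4.056880,
              4.706814, -4.617256, 3.762800, 5.816259, 4.449242),
    logCPM = c(10.693346, 11.215562, 6.117474, 6.943885, 9.038716,
               5.650018, 8.036567, 5.512202, 4.613614, 4.901331),
    pvalue = c(2.116876e-51, 6.575861e-51, 2.371864e-46, 6.017277e-41,
               2.477170e-40, 7.523387e-40, 5.344099e-37, 4.071101e-35,
               4.255301e-35, 9.436192e-35),
    stringsAsFactors = FALSE
  )
}
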