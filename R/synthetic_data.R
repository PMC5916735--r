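#' Reference genome regime: the three-spined stickleback chromosome table
#'
#' Chromosome lengths (Ensembl BROAD S1 assembly) and annotated gene counts
#' for the 21 stickleback chromosome groups, used as the default regime of
#' [genome_spec()]. Built in code, so the package carries no binary data.
#'
#' @return data.frame with `chrom`, `length_bp`, `n_genes`.
#' @export
stickleback_chromosomes <- function() {
  data.frame(
    chrom = paste0("group", c("I", "II", "III", "IV", "V", "VI", "VII",
                              "VIII", "IX", "X", "XI", "XII", "XIII",
                              "XIV", "XV", "XVI", "XVII", "XVIII", "XIX",
                              "XX", "XXI")),
    length_bp = c(28185914, 23295652, 16798506, 32632948, 12251397,
                  17083675, 27937443, 19368704, 20249479, 15657440,
                  16706052, 18401067, 20083130, 15246461, 16198764,
                  18115788, 14603141, 16282716, 20240660, 19732071,
                  11717487),
    n_genes = c(1647, 1158, 1226, 1719, 980, 965, 1726, 1177, 1374, 1050,
                1344, 1301, 1303, 984, 1026, 1063, 929, 1020, 1373, 1259,
                599),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic genome annotation
#'
#' Defaults emulate the stickleback chromosome regime of
#' [stickleback_chromosomes()]: 21 chromosomes of 11.7-32.6 Mb carrying
#' 25,223 genes in total.
#'
#' @param chromosome_names chromosome labels.
#' @param chromosome_lengths chromosome lengths in bp (> 0).
#' @param n_genes_per_chromosome genes per chromosome (>= 0), recycled.
#' @param gene_length_range min/max gene length in bp.
#' @param placement_mode `"uniform"` (midpoints i.i.d. uniform) or
#'   `"clustered"` (Matern-style: uniform cluster centers with
#'   truncated-normal offsets).
#' @param cluster_count clusters per chromosome in clustered mode.
#' @param cluster_spread sd (bp) of gene midpoints around cluster centers.
#' @param seed RNG seed.
#' @return list of class `"genome_spec"`.
#' @export
genome_spec <- function(chromosome_names = stickleback_chromosomes()$chrom,
                        chromosome_lengths =
                          stickleback_chromosomes()$length_bp,
                        n_genes_per_chromosome =
                          stickleback_chromosomes()$n_genes,
                        gene_length_range = c(1000, 20000),
                        placement_mode = c("uniform", "clustered"),
                        cluster_count = 10,
                        cluster_spread = 100000,
                        seed = 1) {
  placement_mode <- match.arg(placement_mode)
  n_chr <- length(chromosome_names)
  chromosome_lengths <- rep_len(as.numeric(chromosome_lengths), n_chr)
  n_genes_per_chromosome <- rep_len(as.integer(n_genes_per_chromosome),
                                    n_chr)
  if (any(chromosome_lengths <= 0)) stop("chromosome lengths must be > 0")
  if (any(n_genes_per_chromosome < 0)) stop("gene counts must be >= 0")
  if (gene_length_range[1L] > gene_length_range[2L]) {
    stop("gene_length_range must be (min, max) with min <= max")
  }
  if (any(gene_length_range[2L] > chromosome_lengths)) {
    stop("maximum gene length exceeds a chromosome length")
  }
  if (placement_mode == "clustered" && cluster_spread <= 0) {
    stop("cluster_spread must be > 0 in clustered mode")
  }
  structure(list(
    chromosome_names = as.character(chromosome_names),
    chromosome_lengths = chromosome_lengths,
    n_genes_per_chromosome = n_genes_per_chromosome,
    gene_length_range = as.numeric(gene_length_range),
    placement_mode = placement_mode,
    cluster_count = as.integer(cluster_count),
    cluster_spread = as.numeric(cluster_spread),
    seed = as.integer(seed)
  ), class = "genome_spec")
}

#' Specification of a synthetic two-group expression experiment
#'
#' Defaults emulate a 4 + 4 marine/freshwater gill comparison: per-sample
#' library sizes of 18-29 million in-gene reads, a log-normal baseline
#' abundance (log2 CPM ~ N(4, 2), which makes total CPM close to 1e6 for
#' ~25k genes), NB dispersion 0.1, 13.3% of genes DE with planted |log2FC|
#' ~ N(2, 0.5) and 56% of the effects up in group B (the 1,678 : 1,304
#' freshwater-up : marine-up proportion).
#'
#' @param n_samples_group_a,n_samples_group_b samples per group.
#' @param library_sizes per-sample library sizes, group A then group B.
#' @param baseline_logcpm `c(mean, sd)` of per-gene baseline log2 CPM.
#' @param dispersion NB dispersion phi (variance = mu + phi mu^2; 0 gives
#'   Poisson counts).
#' @param de_fraction fraction of genes with a planted effect.
#' @param logfc_distribution `c(mean, sd)` of planted |log2FC| magnitudes.
#' @param prop_up fraction of planted effects with positive sign (up in
#'   group B).
#' @param de_placement `"random"`, `"clustered"` (DE labels concentrated in
#'   contiguous genomic windows) or `"island_linked"` (DE odds multiplied
#'   for island-overlapping genes).
#' @param de_window_fraction in clustered mode, fraction of each chromosome
#'   forming the DE-enriched window.
#' @param island_odds in island_linked mode, odds multiplier for island
#'   genes.
#' @param seed RNG seed.
#' @return list of class `"expression_spec"`.
#' @export
expression_spec <- function(n_samples_group_a = 4,
                            n_samples_group_b = 4,
                            library_sizes = c(17993109, 18161521, 18489001,
                                              19450343, 24692145, 28960967,
                                              26307475, 23609866),
                            baseline_logcpm = c(4, 2),
                            dispersion = 0.1,
                            de_fraction = 2982 / 22456,
                            logfc_distribution = c(2, 0.5),
                            prop_up = 1678 / 2982,
                            de_placement = c("random", "clustered",
                                             "island_linked"),
                            de_window_fraction = 0.05,
                            island_odds = 3,
                            seed = 1) {
  de_placement <- match.arg(de_placement)
  n <- n_samples_group_a + n_samples_group_b
  library_sizes <- rep_len(as.numeric(library_sizes), n)
  if (any(library_sizes <= 0)) stop("library sizes must be > 0")
  if (de_fraction < 0 || de_fraction > 1) {
    stop("de_fraction must be in [0, 1]")
  }
  if (dispersion < 0) stop("dispersion must be >= 0")
  structure(list(
    n_samples_group_a = as.integer(n_samples_group_a),
    n_samples_group_b = as.integer(n_samples_group_b),
    library_sizes = library_sizes,
    baseline_logcpm = as.numeric(baseline_logcpm),
    dispersion = as.numeric(dispersion),
    de_fraction = as.numeric(de_fraction),
    logfc_distribution = as.numeric(logfc_distribution),
    prop_up = as.numeric(prop_up),
    de_placement = de_placement,
    de_window_fraction = as.numeric(de_window_fraction),
    island_odds = as.numeric(island_odds),
    seed = as.integer(seed)
  ), class = "expression_spec")
}

#' Simulate a genome annotation
#'
#' Draws gene midpoints per chromosome (uniform, or Matern-style clustered:
#' cluster centers uniform on the chromosome, midpoints normal around a
#' random center and re-drawn until inside `[0, L]`), gene lengths uniform
#' in `gene_length_range`, and intervals clipped to chromosome bounds.
#' Overlapping gene bodies are permitted, as in real annotations; all
#' downstream positional statistics use midpoints only.
#'
#' @param spec a [genome_spec()].
#' @return a [gene_annotation()] with ids `g<chrom>_<k>` sorted by
#'   (chromosome, start).
#' @export
simulate_annotation <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  # gene bodies may overlap, so packing is infeasible only when even
  # minimum-length genes cannot fit the chromosome end to end
  infeasible <- spec$n_genes_per_chromosome * spec$gene_length_range[1L] >
    spec$chromosome_lengths
  if (any(infeasible)) {
    stop("requested gene content exceeds chromosome length on ",
         spec$chromosome_names[which(infeasible)[1L]])
  }
  old <- local_seed(spec$seed)
  on.exit(restore_seed(old))
  pieces <- lapply(seq_along(spec$chromosome_names), function(i) {
    n <- spec$n_genes_per_chromosome[i]
    if (n == 0L) return(NULL)
    L <- spec$chromosome_lengths[i]
    mid <- if (spec$placement_mode == "uniform") {
      runif(n, 0, L)
    } else {
      centers <- runif(spec$cluster_count, 0, L)
      draw_clustered(n, centers, spec$cluster_spread, L)
    }
    len <- runif(n, spec$gene_length_range[1L], spec$gene_length_range[2L])
    start <- pmax(0, round(mid - len / 2))
    end <- pmin(L, round(mid + len / 2))
    data.frame(chrom = spec$chromosome_names[i], start = start, end = end,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, Filter(Negate(is.null), pieces))
  if (is.null(df) || nrow(df) == 0L) {
    return(gene_annotation(character(), integer(), integer(), character()))
  }
  ids <- stats::ave(seq_len(nrow(df)), df$chrom, FUN = seq_along)
  gene_annotation(df$chrom, df$start, df$end,
                  sprintf("g%s_%04d", df$chrom, ids))
}

# truncated-normal midpoints around random cluster centers
draw_clustered <- function(n, centers, spread, L) {
  assigned <- if (length(centers) == 1L) rep(centers, n) else
    sample(centers, n, replace = TRUE)
  mid <- rnorm(n, assigned, spread)
  bad <- which(mid < 0 | mid > L)
  while (length(bad)) {
    mid[bad] <- rnorm(length(bad), assigned[bad], spread)
    bad <- bad[mid[bad] < 0 | mid[bad] > L]
  }
  mid
}

#' Simulate divergence-island intervals
#'
#' Places `n_islands` non-overlapping intervals of fixed length, choosing a
#' chromosome with probability proportional to its length and a start
#' uniform within bounds; placement of each island is retried (up to 1000
#' times) until it overlaps no previous island.
#'
#' @param annotation a [gene_annotation()] (defines the chromosome
#'   namespace and the genes reported as covered).
#' @param chromosome_lengths named vector of chromosome lengths; defaults
#'   to the maximum gene end per chromosome.
#' @param n_islands number of islands.
#' @param island_length island length in bp, smaller than every chromosome.
#' @param seed RNG seed.
#' @return list with `islands` (a [gene_annotation()]-like interval table,
#'   ids `island_<k>`) and `covered_genes` (ids of genes overlapping any
#'   island by >= 1 bp).
#' @export
simulate_islands <- function(annotation, chromosome_lengths = NULL,
                             n_islands = 19, island_length = 150000,
                             seed = 1) {
  chroms <- levels(annotation$chrom)
  if (is.null(chromosome_lengths)) {
    chromosome_lengths <- vapply(
      chroms, function(ch) max(annotation$end[annotation$chrom == ch]),
      numeric(1L)
    )
  }
  if (is.null(names(chromosome_lengths))) {
    if (length(chromosome_lengths) != length(chroms)) {
      stop("chromosome_lengths must be named or match the chromosomes ",
           "of the annotation")
    }
    names(chromosome_lengths) <- chroms
  }
  chromosome_lengths <- chromosome_lengths[chroms]
  if (anyNA(chromosome_lengths)) {
    stop("chromosome_lengths missing for: ",
         paste(chroms[is.na(chromosome_lengths)], collapse = ", "))
  }
  if (any(island_length >= chromosome_lengths)) {
    stop("island_length must be smaller than every chromosome length")
  }
  if (n_islands == 0L) {
    empty <- gene_annotation(character(), integer(), integer(), character())
    return(list(islands = empty, covered_genes = character(0)))
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  placed <- vector("list", n_islands)
  for (k in seq_len(n_islands)) {
    ok <- FALSE
    for (try in seq_len(1000L)) {
      ch <- sample(chroms, 1L, prob = chromosome_lengths)
      s <- floor(runif(1L, 0, chromosome_lengths[ch] - island_length))
      e <- s + island_length
      clash <- any(vapply(placed[seq_len(k - 1L)], function(p) {
        !is.null(p) && p$chrom == ch && s < p$end && p$start < e
      }, logical(1L)))
      if (!clash) {
        placed[[k]] <- list(chrom = ch, start = s, end = e)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place island ", k, " without overlap")
  }
  islands <- gene_annotation(
    vapply(placed, `[[`, "", "chrom"),
    vapply(placed, `[[`, numeric(1L), "start"),
    vapply(placed, `[[`, numeric(1L), "end"),
    sprintf("island_%03d", seq_len(n_islands))
  )
  covered <- count_island_genes(annotation, islands)$island_genes
  list(islands = islands, covered_genes = covered)
}

#' Simulate a two-group NB count matrix with planted DE
#'
#' Per-gene baseline log2 CPM is drawn from the spec's normal distribution;
#' `round(de_fraction * n_genes)` genes receive a planted log2 fold change
#' (magnitude from `logfc_distribution`, sign up in group B with
#' probability `prop_up`, up/down counts matched to `prop_up` within one
#' gene). Counts are NB with mean
#' `mu_gs = library_size_s * 2^(baseline_g + lfc_g * I[group B]) / 1e6`
#' and variance `mu + phi mu^2` (`phi = 0` gives Poisson). DE labels are
#' placed at random, in contiguous genomic windows (`"clustered"`), or with
#' boosted odds for island-overlapping genes (`"island_linked"`).
#'
#' @param annotation a [gene_annotation()]; genes are simulated in its
#'   order.
#' @param spec an [expression_spec()].
#' @param islands optional island table, required for island-linked
#'   placement.
#' @return list with `counts` (a [count_matrix()], groups `A`/`B`) and
#'   `truth` (data.frame `gene_id`, `is_de`, `true_logfc`).
#' @export
simulate_counts <- function(annotation, spec, islands = NULL) {
  stopifnot(inherits(spec, "expression_spec"))
  n_genes <- nrow(annotation)
  if (n_genes == 0L) stop("annotation has no genes")
  if (spec$de_placement == "island_linked" && is.null(islands)) {
    stop("island_linked placement requires islands")
  }
  old <- local_seed(spec$seed)
  on.exit(restore_seed(old))
  baseline <- rnorm(n_genes, spec$baseline_logcpm[1L],
                    spec$baseline_logcpm[2L])
  n_de <- round(spec$de_fraction * n_genes)
  de_idx <- pick_de_genes(annotation, spec, islands, n_de)
  lfc <- numeric(n_genes)
  if (n_de > 0L) {
    mag <- abs(rnorm(n_de, spec$logfc_distribution[1L],
                     spec$logfc_distribution[2L]))
    n_up <- round(spec$prop_up * n_de)
    signs <- c(rep(1, n_up), rep(-1, n_de - n_up))
    if (length(signs) > 1L) signs <- sample(signs)
    lfc[de_idx] <- mag * signs
  }
  na <- spec$n_samples_group_a
  nb <- spec$n_samples_group_b
  group <- rep(c("A", "B"), c(na, nb))
  phi <- spec$dispersion
  counts <- matrix(0L, n_genes, na + nb)
  for (s in seq_len(na + nb)) {
    logcpm <- baseline + if (group[s] == "B") lfc else 0
    mu <- spec$library_sizes[s] * 2 ^ logcpm / 1e6
    counts[, s] <- if (phi == 0) {
      rpois(n_genes, mu)
    } else {
      rnbinom(n_genes, size = 1 / phi, mu = mu)
    }
  }
  dimnames(counts) <- list(
    annotation$gene_id,
    paste0(group, stats::ave(seq_along(group), group, FUN = seq_along))
  )
  list(
    counts = count_matrix(counts, group, lib_size = spec$library_sizes),
    truth = data.frame(gene_id = annotation$gene_id,
                       is_de = seq_len(n_genes) %in% de_idx,
                       true_logfc = lfc, stringsAsFactors = FALSE)
  )
}

pick_de_genes <- function(annotation, spec, islands, n_de) {
  n_genes <- nrow(annotation)
  if (n_de == 0L) return(integer(0))
  switch(spec$de_placement,
    random = sample(n_genes, n_de),
    clustered = {
      # DE-enriched window at a random offset on each chromosome
      w <- rep(1e-3, n_genes)
      for (ch in levels(annotation$chrom)) {
        onchr <- which(annotation$chrom == ch)
        if (!length(onchr)) next
        L <- max(annotation$end[onchr])
        width <- spec$de_window_fraction * L
        lo <- runif(1L, 0, L - width)
        inside <- annotation$midpoint[onchr] >= lo &
          annotation$midpoint[onchr] <= lo + width
        w[onchr][inside] <- 1
      }
      sample(n_genes, n_de, prob = w)
    },
    island_linked = {
      isl <- count_island_genes(annotation, islands)$island_genes
      w <- ifelse(annotation$gene_id %in% isl, spec$island_odds, 1)
      sample(n_genes, n_de, prob = w)
    }
  )
}
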