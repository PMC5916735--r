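# Shared fixtures, all built in code at test time.

# n genes with uniform midpoints on [0, L], one chromosome
uniform_annotation <- function(n, L = 2e7, chrom = "chr1", seed = 1) {
  set.seed(seed)
  mid <- sort(runif(n, 100, L - 100))
  gene_annotation(rep(chrom, n), floor(mid - 50), floor(mid + 50),
                  sprintf("%s_g%04d", chrom, seq_len(n)))
}

# tiny deterministic two-group count matrix
toy_counts <- function() {
  counts <- matrix(c(10, 100, 0, 50,
                     12, 110, 1, 45,
                     40, 95, 0, 200,
                     38, 105, 2, 190),
                   nrow = 4,
                   dimnames = list(paste0("g", 1:4), c("A1", "A2", "B1", "B2")))
  count_matrix(counts, c("A", "A", "B", "B"))
}

# brute-force O(n^2) pairwise-distance oracle (direct |x_i - x_j| table)
brute_pairwise <- function(pos) {
  n <- length(pos)
  if (n < 2) return(numeric(0))
  m <- abs(outer(pos, pos, "-"))
  m[lower.tri(m)]
}

# brute-force O(n * m) half-open interval-overlap oracle
brute_island_genes <- function(annotation, islands) {
  hits <- character(0)
  for (g in seq_len(nrow(annotation))) {
    for (i in seq_len(nrow(islands))) {
      if (as.character(annotation$chrom[g]) ==
            as.character(islands$chrom[i]) &&
          annotation$start[g] < islands$end[i] &&
          islands$start[i] < annotation$end[g]) {
        hits <- c(hits, annotation$gene_id[g])
        break
      }
    }
  }
  hits
}
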