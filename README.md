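# ecotypeDE

Differential expression and genomic clustering of marine–freshwater
ecotype genes.

## The problem

When a marine fish population colonizes fresh water — the textbook case is
the three-spined stickleback, *Gasterosteus aculeatus* — gill tissue must
rework its osmoregulatory machinery, and bulk RNA-seq of marine vs
freshwater individuals reveals thousands of differentially expressed (DE)
genes. Two follow-up questions are genomic rather than transcriptomic:

1. **Are the DE genes spatially clustered along chromosomes?** Eukaryotic
   genes are not arranged entirely at random; co-expressed clusters are a
   recurring observation. The statistic used here compares, per
   chromosome, the array of all-pairs intergenic distances among every
   annotated gene with the same array restricted to the DE genes.
2. **Are DE genes concentrated in "divergence islands"** — the short
   genomic intervals where marine/freshwater-differentiating sequence
   variants accumulate?

`ecotypeDE` packages the full analysis path for a two-group comparison:
normalization and exact-test DE calling, sample ordination, the
per-chromosome distance statistic, and the island enrichment test —
together with a synthetic-data generator that reproduces the statistical
structure of such an experiment (21 chromosomes with realistic lengths and
gene counts, 4 + 4 samples with 17–29 M mapped reads, ~13% DE genes), so
every stage is testable and calibratable without external data.

## The statistics

* **Normalization.** Counts-per-million with TMM (trimmed mean of
  M-values) factors: per sample, log-ratios *M* against a reference are
  trimmed (30% by *M*, 5% by *A*) and precision-weight averaged; factors
  are rescaled to geometric mean 1.
* **DE testing.** The classic conditioned negative-binomial exact test
  with a common dispersion φ (variance = μ + φμ²), method-of-moments
  estimated. Counts are scaled to a common library size; conditioning on
  each gene's total *s* = *y*<sub>A</sub> + *y*<sub>B</sub>, the two-sided
  P-value is twice the smaller cumulative tail of the conditional split
  distribution (binomial when φ = 0). FDR control is Benjamini–Hochberg;
  `bh_adjust()` optionally adjusts a top-*k* excerpt against a larger test
  universe *N* (each sorted *p*<sub>(i)</sub> scaled by *N*/*i*, step-up
  minimum).
* **Ordination.** Leading-logFC multidimensional scaling: the distance
  between two samples is the root-mean-square of their `top_n` largest
  absolute logCPM differences, embedded by classical MDS.
* **Spatial clustering.** Per chromosome, all n(n−1)/2 pairwise distances
  between gene midpoints vs the m(m−1)/2 distances among DE genes,
  compared by a Welch t-test (the historical procedure) *and* by a
  permutation test whose null redraws same-size gene subsets — the
  statistically defensible companion, since DE pairs are a dependent
  subset of all pairs. A prefix-sum identity gives the mean pairwise
  distance in O(n).
* **Island enrichment.** With *m* of *n* genes in islands and *d* DE
  genes, the number of DE genes in islands is ~Poisson(λ = *d·m/n*);
  the upper tail P(X ≥ k) tests enrichment, with the hypergeometric tail
  reported alongside.

## Worked example

```r
library(ecotypeDE)

ann <- simulate_annotation(genome_spec(
  chromosome_names = c("chrI", "chrII"), chromosome_lengths = c(2e7, 1.5e7),
  n_genes_per_chromosome = c(550, 450), seed = 1))
isl <- simulate_islands(ann, c(chrI = 2e7, chrII = 1.5e7),
                        n_islands = 6, island_length = 2e5, seed = 2)
sim <- simulate_counts(ann, expression_spec(seed = 3), islands = isl$islands)

res <- de_analysis(sim$counts, fdr = 0.05)
#> DE analysis: 1000 genes tested, dispersion = 0.09393
#> DE at FDR < 0.05 : 131 (74 up, 57 down in group B)
```

The moment estimator recovers the simulated dispersion (φ = 0.1 planted,
0.094 estimated) and 131 of the ~133 planted DE genes are flagged
(sensitivity 0.93 at FDR 0.05). Where do they sit on the genome?

```r
de_ids <- res$gene_id[res$is_de]
clustering_analysis(ann, de_ids, n_perm = 1999, seed = 4)
#>   chromosome n_genes n_de_genes mean_dist_all mean_dist_de t_statistic pvalue perm_pvalue
#> 1       chrI     550         79       6536989      6858228       -3.67 2.5e-4      0.3375
#> 2      chrII     450         52       5110754      4861253        2.69 7.3e-3      0.4110
```

DE labels were planted at random here, yet the t-test "detects"
clustering/dispersion on both chromosomes — the dependence of pair
distances makes it anti-conservative. The permutation P-values (0.34,
0.41) correctly find nothing, which is why both are reported.

```r
island_enrichment(ann, isl$islands, de_ids)
#>   n_total m_island n_de k_observed lambda_expected  pvalue alt_pvalue
#> 1    1000       32  131          9           4.192 0.02765    0.01706
```

Nine DE genes fall in islands against an expectation of 4.2 — mild
enrichment (the simulation planted DE with 3× odds inside islands).

`run_pipeline(pipeline_config())` chains all stages (a full-scale
synthetic run: 25,223 genes on the 21 stickleback-regime chromosomes) and
writes TSV results plus a run manifest; `inst/scripts/run-pipeline.R` is a
command-line wrapper.

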