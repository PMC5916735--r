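---
title: "Methods: differential expression and genomic clustering of ecotype genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential expression and genomic clustering of ecotype genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecotypeDE)
```

`ecotypeDE` implements the analysis path of a two-group bulk RNA-seq
ecotype comparison — the motivating system is marine vs freshwater
three-spined stickleback gills — from a raw count matrix to three
questions: which genes are differentially expressed (DE), whether the DE
genes cluster along chromosomes, and whether they concentrate in
divergence islands. This vignette records the models, the parameter
choices, and the design decisions, in enough detail that every number the
package produces can be traced to a formula.

## 1. The count model and the exact test

Counts are modelled as negative binomial: for gene $g$ in sample $s$,
$y_{gs} \sim \mathrm{NB}(\mu_{gs}, \phi)$ with
$\mathrm{Var} = \mu + \phi\mu^2$. The common dispersion $\phi$ is shared
across genes — the simplest model with replicate-level overdispersion.
Tagwise or trended dispersion shrinkage is deliberately out of scope: with
4 + 4 samples a common $\phi$ is the defensible default, and the
multiple-testing arithmetic that constitutes the package's verifiable
reference surface does not depend on the dispersion model.

**Normalization.** Library sizes are multiplied by TMM factors
(`tmm_factors()`): against a reference sample (the one whose
upper-quartile CPM is closest to the mean upper-quartile), per-gene
log-ratios $M$ and average abundances $A$ are computed on scaled counts,
genes with a zero in either sample are dropped, the extreme 30% of $M$
and 5% of $A$ are trimmed, and the factor is $2$ to the precision-weighted
mean $M$ (inverse delta-method variances as weights). Factors are rescaled
to geometric mean 1 so a pure depth difference moves library sizes, not
factors. The trim fractions are the standard TMM defaults; the unit tests
check agreement with the independent edgeR implementation to 2%.

**Dispersion estimation** (`estimate_common_dispersion()`) is by the
method of moments: counts are scaled to the mean effective library size;
per gene, within-group means and variances are pooled across the two
groups, giving $\hat\phi_g = \max(0, (s^2-\bar\mu)/\bar\mu^2)$; the common
estimate is the 20% trimmed mean over genes with mean scaled count
$\ge 1$. The mean floor exists because $\hat\phi_g$ is dominated by noise
for near-zero counts; the trim guards against the genuinely DE genes,
whose between-group signal inflates the within-gene variance less than the
pooling assumes but which still sit in the upper tail. On simulated data
(2,000 genes, 4 + 4 samples at the default library sizes) the tests
require recovery of $\phi = 0.1$ within a factor of two, and an estimate
below 0.02 for Poisson data.

**The exact test** (`nb_exact_test()`) is the conditioned two-group NB
test. Counts are first scaled to a common library size (the geometric
mean of effective library sizes) and rounded to integer pseudo-counts, so
the per-sample means are exchangeable under the null. For a gene with
group sums $y_A, y_B$ and total $s$, both sums are NB with sizes
$n_A/\phi$ and $n_B/\phi$ and a shared success probability, so their sum
is NB with size $(n_A+n_B)/\phi$ and the conditional probability of any
split $(k, s-k)$ is a ratio of NB densities with $\mu$ estimated as
$s/(n_A+n_B)$. The two-sided P-value is $\min(1, 2\min(\text{lower},
\text{upper}))$ with both tails including the observed split — the common
doubled-tail convention, chosen over minimum-likelihood summation because
it is deterministic and easy to verify (at $\phi = 0$ it reduces exactly
to the doubled binomial tail; the tests pin
$2 \cdot (1/2)^{10}$ for a 0-vs-10 split). Numerically, only the shorter
tail is summed directly and the other is obtained by complementation, so
cost per gene is $O(\min(k, s-k))$ densities. Genes with $s = 0$ are
untestable and reported with $P = 1$, $\log\mathrm{FC} = 0$.

The doubled inclusive tail makes the test slightly conservative at low
counts. At the package's default library sizes (17–29 M reads) P-values
under a simulated null are uniform to a Kolmogorov–Smirnov statistic
below 0.05 at 2,000 genes; at much shallower depth (~2 M reads) the
discreteness becomes visible as super-uniformity. That is a property of
exact tests, not a defect, but it is worth knowing when simulating small
libraries.

**Fold change and abundance.** $\log\mathrm{FC} = \log_2\{(y_B + 0.5 n_B)
/ (y_A + 0.5 n_A)\} - \log_2(n_B/n_A)$ — half a pseudo-count per sample
stabilizes zeros; logCPM is the log2 CPM of the average pseudo-count with
prior 0.5. Both are conventional; neither is a calibration target.

**FDR.** `bh_adjust()` is Benjamini–Hochberg with an explicit test
universe `n_total`: sorted $p_{(i)}$ becomes $p_{(i)} N / i$, followed by
the step-up minimum within the supplied list, capped at 1. The `n_total`
parameter exists so a printed top-$k$ table can be adjusted as the
smallest $k$ of $N$ tests; the step-up minimum is then taken within the
excerpt, which assumes the unseen tail does not lower the running minimum
— true whenever the excerpt's largest raw value is attained inside it, and
verified on the reference table the package ships
(`stickleback_top_genes()`, where ranks 8 and 9 tie at the step-up
minimum). The DE flag applies `fdr < 0.05` by default; the threshold is
the conventional reading of a "95% significance level" on FDR-adjusted
values and is exposed as a parameter.

## 2. Leading-logFC MDS

`mds_leading_logfc()` measures the distance between two samples as the
root-mean-square of their `top_n` (default 500) largest absolute logCPM
differences — the genes that most distinguish the pair, hence "leading
logFC". Classical MDS (double-centering, eigendecomposition, coordinates
scaled by root eigenvalues, via `stats::cmdscale`) embeds the samples; the
sign of each axis is fixed by making the first sample's loading
non-negative so runs are reproducible. If fewer positive eigenvalues than
requested dimensions exist the result is truncated with a warning. The
pair-specific gene selection means the distance matrix need not be exactly
Euclidean-embeddable; with `top_n` equal to all genes it is (a scaled
Euclidean distance), which the tests exploit as an oracle by reconstructing
the distance matrix from full-rank coordinates.

## 3. The intergenic-distance clustering statistic

For each chromosome, the positions of all $n$ genes (interval midpoints)
yield $n(n-1)/2$ pairwise distances; the $m$ DE genes yield $m(m-1)/2$.
The procedure compares the two arrays with a two-sample t-test (Welch by
default — the common default of generic two-sample routines; a pooled
variant is available). A DE mean below the all-genes mean at significance
is reported as `clustered`, above as `dispersed`.

Two decisions deserve explanation:

* **Midpoints, not gaps.** Gene position is the interval midpoint, and
  "intergenic distance" means all-pairs positional distance. For roughly
  uniform positions on a chromosome of length $L$ the expected mean is
  $L/3$ (mean $|X-Y|$ for i.i.d. uniforms), i.e. megabases — the scale on
  which per-chromosome means of this statistic are meaningful. Adjacent-
  gene gaps would instead average $\sim L/n$ (kilobases). The package's
  fast path (`mean_pairwise_distance()`) uses the prefix-sum identity
  $\sum_{i<j}(x_{(j)}-x_{(i)}) = \sum_j x_{(j)}(2j-n+1)$, exact and
  $O(n)$, property-tested against brute force.
* **The t-test is kept, but not trusted alone.** Pair distances sharing a
  gene are dependent, and the DE array is a subset of the all-genes array,
  so the t-test's nominal level is wildly anti-conservative: with randomly
  planted DE labels it can report $P < 10^{-14}$ while a valid null finds
  nothing. The package therefore always offers
  `permutation_clustering_test()`: the statistic is the DE-subset mean
  distance, the null redraws uniform same-size gene subsets of the same
  chromosome, and the two-sided P-value uses the $+1$-corrected count, so
  it is valid (slightly conservative) under the actual dependence. The
  calibration suite requires the permutation test's type-I error at the
  0.05 level to fall in $[0.03, 0.08]$ over 500 null replicates and
  $P < 0.01$ when DE genes are planted inside a 5% window. No uniformity
  claim is made — or tested — for the t-test; it is reproduced as the
  historical procedure so its outputs can be compared with published
  per-chromosome tables.

## 4. Island enrichment

With $m$ of $n$ annotated genes overlapping islands and $d$ DE genes, the
island-agnostic expectation for DE genes in islands is
$\lambda = d\,m/n$ — gene-count proportions, not base-pair proportions,
because both published numerator and denominator are gene counts. The
P-value is the Poisson upper tail $P(X \ge k)$ (via `stats::ppois`, i.e.
the regularized incomplete gamma; the tests check it against direct
summation to $10^{-12}$). The hypergeometric tail (draw $d$ of $n$ with
$m$ successes) is reported alongside: it is the exact finite-population
answer, and the two agree within an order of magnitude whenever
$m \ll n$. Overlap is $\ge 1$ bp on 0-based half-open intervals
(touching intervals do not overlap), computed with interval trees
(`GenomicRanges::findOverlaps`) and cross-checked against an $O(nm)$
sweep in the tests. Enrichment is one-sided upper by default, matching
the directional question; depletion is available via `alternative`.

On the reference gene counts of the motivating study (212 of 29,245
annotated genes in islands, 28 of 2,982 DE genes), $\lambda \approx
21.62$; the standard upper tail at $k = 28$ is $\approx 0.106$. The
package reports this computed value; no attempt is made to reproduce
other published P-values for these counts, whose test construction is not
derivable from the inputs.

## 5. What the simulator emulates — and what it does not

`genome_spec()` defaults to the 21-chromosome stickleback regime
(`stickleback_chromosomes()`: 11.7–32.6 Mb chromosomes, 25,223 genes).
`expression_spec()` defaults to 4 + 4 samples with the study's per-sample
in-gene read totals (17.99–29.0 M), baseline $\log_2$ CPM $\sim N(4, 2)$
(chosen so that total CPM across ~25k genes is close to $10^6$,
i.e. the baselines are self-consistent as CPMs), $\phi = 0.1$ (a typical
bulk RNA-seq replicate dispersion), DE fraction $2982/22456 \approx
13.3\%$ with $|\log_2\mathrm{FC}| \sim N(2, 0.5)$ and 56% of effects up
in group B (the published freshwater-up : marine-up proportion). Gene
lengths are uniform on 1–20 kb and gene bodies may overlap, as in real
annotations; positional statistics use midpoints only, so overlap is
harmless. Island defaults (19 islands of 150 kb) give an island gene
fraction comparable to the reference counts above.

The generator supports three DE placements: `random`; `clustered` (a DE-
enriched window per chromosome, for power studies of the clustering
statistic); and `island_linked` (DE odds multiplied by `island_odds`,
default 3, for island-overlapping genes, making the enrichment test's
power measurable). Each operation consumes its own seeded RNG stream and
restores the caller's RNG state, so stages are individually reproducible
and never couple.

Not emulated: read-level artefacts (GC/length bias, mapping ambiguity),
batch effects, isoforms, library-preparation variation, and biological
correlation between expression and genomic position beyond the explicit
placement modes. Consequently, passing calibration on synthetic data
demonstrates that the statistics behave as designed under their assumed
model — not that real gill RNA-seq satisfies that model.

**Infeasibility rule.** `simulate_annotation()` refuses a chromosome only
when even minimum-length genes could not fit end to end
(`n × min length > L`); since bodies may overlap, any softer bound would
reject realistic dense annotations.

## 6. Numerical choices and degenerate inputs

* Exact-test tails sum the shorter side and complement, in double
  precision; the denominator is a single NB density (no explicit
  normalizing loop).
* `clustering_test()` returns NA test fields when either distance array
  has fewer than two entries or both are constant; `direction` is `none`
  unless $P < 0.05$.
* `bh_adjust()` errors if `n_total` is smaller than the list; P-values
  outside $[0,1]$ are rejected.
* BED is 0-based half-open throughout; GFF3 gene features are shifted on
  read. Strand is parsed and ignored. Duplicate gene ids, negative and
  inverted coordinates are rejected with line numbers.
* Result TSVs print P-values with six significant digits; round-trips
  reproduce values to that precision.
* Library size defaults to the column sum but can be overridden, because
  produced vs in-gene mapped totals differ in real experiments and CPM
  depends on the choice.

## 7. Problem sizes in the test suite

The suite simulates at 300–3,000 genes for module tests and 2,000 genes
at the default (full-depth) library sizes for the calibration blocks;
permutation calibration uses 500 replicates of a 300-gene chromosome with
199 permutations each, and power checks use 10,000 permutations once.
These sizes give Monte-Carlo error comfortably inside the asserted bands
while keeping the suite fast; the full 25,223-gene default regime is
exercised end-to-end by `run_pipeline(pipeline_config())` as in the
README.

## 8. Interface notes

The package's surface is R functions; `run_pipeline()` orchestrates the
stages from a flat `pipeline_config()` list, writes every result table as
TSV plus a manifest, and is wrapped by the thin command-line script
`inst/scripts/run-pipeline.R` for shell use. Exit behaviour, flags and
output schemas are documented in the function help pages.

## 9. Known limitations

* Common dispersion only; no tagwise shrinkage, no GLM/covariate designs.
* The t-test route of the clustering statistic inherits the dependence
  problem discussed above by design; use the permutation P-value for
  inference.
* The Poisson enrichment tail treats gene–island overlap as independent
  thinning; genes clustered inside a single island violate this mildly
  (the hypergeometric companion is reported for that reason).
* The BH excerpt mode assumes the unseen tail of the experiment does not
  lower the step-up minimum; this holds whenever the excerpt is the
  top-$k$ by P-value, the intended use.
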