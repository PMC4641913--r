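---
title: "Methods: exact-test DE and SOM clustering of expression reaction norms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact-test DE and SOM clustering of expression reaction norms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reactnorm)
```

# The design this package models

`reactnorm` analyses an unreplicated, pooled-library RNA-seq time course
contrasting two environments. Each library is a pool of biological
replicates sequenced once, so there is exactly one count per gene per
(condition, time) cell: one shared baseline library at 0 h plus a
pond/upland pair at each of 8 later time points — 17 libraries for the
default 9-point grid. A gene's expression reaction norm is its vector of
log2(pond/upland) abundance ratios over the post-baseline grid.

Because there are no within-cell replicates, dispersion cannot be
estimated per gene; the sampling model is Poisson counting of a pooled
library. All downstream inference inherits that assumption, which is why
the synthetic generator defaults to `dispersion = 0` (negative-binomial
counts are available to study robustness, not as the default condition).

# Differential expression

## The exact test

For counts $x$, $y$ of one gene in two libraries with uniquely mapped
totals $N_1$, $N_2$, conditioning on the total $n = x + y$ removes the
unknown absolute abundance: under the null of equal relative expression,

$$Y \mid n \;\sim\; \mathrm{Binomial}\!\left(n,\; \frac{N_2}{N_1 + N_2}\right).$$

The two-sided p-value doubles the smaller of $P(Y \le y)$ and
$P(Y \ge y)$ (each tail includes the observed count) and caps at 1. Two
properties motivated this construction over the closely related
posterior-predictive form (which places $Y \mid x$ on a negative binomial
with $x + 1$ successes): the conditional test is *exactly* symmetric
under swapping $(x, N_1) \leftrightarrow (y, N_2)$, which the doubled-tail
predictive form is not, and its tails are computable to full double
precision through `pbinom` for counts up to at least $10^6$. The test
suite checks both: symmetry to $10^{-12}$ and agreement with a direct
log-space summation of the conditional pmf to $10^{-10}$ relative over the
full grid $x, y \le 200$, $N \in \{10^4, 10^6\}$. Underflowing two-sided
p-values are floored at the smallest positive normalized double so that
p always lies in $(0, 1]$.

## Multiple testing and calling

p-values are adjusted by the Benjamini–Hochberg step-up rule (via
`p.adjust`; an independent brute-force implementation of the step-up
minimum lives in the tests). The FDR family is **per time point**: each of
the 8 pond-vs-upland comparisons is corrected on its own, because each
comparison is a self-contained two-library experiment; the DE gene set is
the union afterwards. A global family across all 8 comparisons is the main
alternative reading; it would couple calls across time points and slightly
change borderline q-values, but the per-time-point family matches how the
comparisons are actually made.

A gene enters a time point's family when it has at least `min_reads = 2`
uniquely mapped reads in at least one of the two libraries — the same
2-read rule used to call a gene expressed at all. The call requires both
`q <= 0.001` and `|log2 ratio| >= 1` (units: log2 fold change).

## Fold changes and zeros

Fold changes are RPKM ratios, RPKM $= 10^9 C / (N L)$ with $L$ in bp. When
one side is 0, that side is replaced by the RPKM a *single read* would
have in that library ($10^9 / (N L)$): a bounded, data-driven floor that
keeps ratios finite and comparable across genes of different lengths.
Genes with zero RPKM on both sides at a time point are untestable there
(`NA`, excluded from calling; imputed as 0 change if the gene still enters
the profile stage through other time points). `library_total` defaults to
the column sums of the count matrix and can be overridden when an external
mapper reports different uniquely-mapped totals.

# Co-expression clustering

## Histogram normalization

Raw log2 ratios have very unequal spread across time points (early
impulses are larger than late drifts), so each column is rank-transformed
onto an equally spaced grid in $[-1, 1]$ (ties take the mean of their
span; a constant column maps to 0). This equalizes every time point's
histogram — hence the name — making the Euclidean metric of the SOM treat
all time points alike. It is invariant under any strictly monotone
per-column transform, which the tests exercise directly.

## Batch SOM on a hexagonal lattice

Profiles are mapped onto a 26 x 17 hexagonal lattice (442 units; the unit
count is canonical for this analysis, and the near-golden-ratio aspect is
the customary default when only the unit count is given). Training is the
*batch* algorithm: assign every profile to its best-matching unit (BMU,
nearest codebook in Euclidean distance, lowest index on ties), then set
every codebook to the Gaussian-neighborhood-weighted mean of the data,
with the neighborhood radius decaying linearly from `max(grid)/2` to 0.5
over `epochs = 40` epochs. Codebooks are initialized on the plane of the
first two principal components (eigenvector signs fixed by convention), so
training consumes no random numbers and is exactly reproducible from the
data alone. The quantization error is recorded before each update; the
first broad-neighborhood epoch coarsens the PCA initialization, so the
trace typically rises once from epoch 1 to 2 and decreases monotonically
from then on — the tests assert monotonicity from epoch 2 onwards.

## k-means on codebooks, coherence filter, summaries

k-means with `k = 11` runs on the 442 codebook vectors, not on genes:
k-means++ seeding, Lloyd iterations, best of `n_restarts = 25` by
within-cluster sum of squares, deterministic under the configured seed.
25 restarts is a numerical-robustness choice — with few restarts the
best-WCSS solution occasionally lands in a local optimum that merges two
adjacent map regions.

The coherence filter then unassigns units whose codebook lies farther
than 0.3 from their cluster centroid (centroids computed once from the
k-means partition; no iteration). The distance coefficient is, by
default, the **dimension-normalized** Euclidean distance (Euclidean
divided by $\sqrt{8}$, i.e. the per-time-point RMS difference in
normalized units): 0.3 then means the same degree of per-point
disagreement for any grid length, whereas a plain Euclidean 0.3 in an
8-dimensional $[-1,1]$ space retains almost nothing and can leave
single-gene clusters whose "median" is one noisy profile. The plain
reading remains available (`metric = "euclidean"`), and whether the
cutoff should apply to unit–centroid or unit–unit distances is genuinely
open; unit–centroid is the most direct reading of "coherent units".

Cluster summaries return to **raw** log2 ratios: the median profile is the
per-time-point median over member genes (median values of log2 ratio, not
of the rank-normalized values), each member's match is its Euclidean
distance to that median, and the best-matched 50% are the
$\lceil n/2 \rceil$ smallest distances with ties broken by gene
identifier. Clusters are renumbered by descending size for stable
reporting. `recovery_score()` computes the adjusted Rand index
(chance-corrected partition agreement) and per-archetype purity against
planted truth.

# Enrichment

Each cluster is tested against the universe of annotated genes (all genes
carrying at least one term — the customary over-representation universe;
switchable to any explicit universe). Per term, the one-sided Fisher exact
p is the hypergeometric upper tail $P(X \ge k)$ of the 2x2 table
$(k,\, n-k,\, K-k,\, N-n-K+k)$; terms with fewer than `min_term_size`
universe genes are vacuous and skipped. Enrichment is flagged at **raw**
p < 0.01 — no multiple-testing correction, matching the convention of
reporting plain Fisher p for cluster profiling, and no elim/weight
decorrelation (plain "classic" testing per term). Annotations can first be
closed under `is_a` ancestors (true-path rule); the closure is idempotent
and rejects cyclic ontologies.

# qRT-PCR

`delta_delta_ct()` implements the Livak method: replicate Ct values are
averaged on the Ct scale (the common convention; per-replicate RQ is a
straightforward variation), $\Delta Ct = Ct_{target} - Ct_{ref}$ within
each (condition, time), $\Delta\Delta Ct$ subtracts the calibrator
condition at the same time point, RQ $= 2^{-\Delta\Delta Ct}$. The
calibrator is the **same-time upland** sample (so qPCR log2 RQ is directly
comparable to the RNA-seq log2(pond/upland) ratio); calibrating against
0 h is the other defensible choice and is exposed through the `calibrator`
argument. `platform_concordance()` reports Pearson r over the complete
(gene, time) pairs, dropping and counting incomplete ones.

# The synthetic generator

`sim_config()` defaults *are* the emulated study conditions: 8 paired
post-baseline time points plus one shared 0 h library (17 libraries;
whether the real baseline was shared or condition-specific is not
documented — the shared reading matches the library count), 3.95 million
expected reads per library, ~77.96% of genes expressed, 11 planted
archetypes among 20% responsive genes, peak |log2 fold change| 2, and
per-gene per-time-point Gaussian profile jitter of sd 0.2.

Concrete choices a scientist must make that the design brief leaves open:

- **Abundance.** Expressed genes draw baseline expectations from a
  log-normal (sdlog 1.8), the typical long-tailed transcriptome shape;
  the non-expressed remainder get near-zero expectations (expected count
  0.001–0.05), planting the target sparsity directly rather than tuning a
  tail.
- **Who responds.** Responsive genes are drawn from below the top
  abundance decile. The hyper-abundant constitutive transcripts are not
  plausible environmental responders, and keeping them stable keeps the
  two conditions' sequencing depths comparable — with strongly induced
  high-abundance genes, pond library totals inflate and a composition
  bias of order 0.1–0.2 log2 units enters *every* RPKM ratio. That bias
  is a real property of depth-normalized measures, worth studying, but it
  should not be baked into the default truth.
- **Archetype shapes.** Eleven piecewise-linear-in-log-time templates
  (peak |value| 1, scaled by `effect_scale`): early and delayed sustained
  induction, induction impulses with slow and fast decay, an up-down
  impulse peaking at 3 h, sustained repression, transient induction
  followed by sustained repression, an early repression impulse, late
  induction, late repression, and a mid-course repression impulse
  (trough at 12 h). The set is deliberately well separated (minimum
  pairwise distance > 0.5 in template units); an earlier variant with two
  early repression impulses (troughs at 1 h and 3 h) was not separable
  and was replaced by the mid-course trough before the recovery
  conditions were frozen.
- **Counts.** Independent Poisson draws with pond mean = upland mean
  $\times\, 2^{\text{profile}(t)}$, so planted count ratios are exactly
  calibrated; realized library totals then vary around the nominal depth
  (they are Poisson sums), as real mapped-read totals do.
- **qPCR.** Ct tables are built so that noise-free 2^-ddCt inversion
  returns the planted profile exactly; the reference gene sits at Ct 20
  in every stratum.

What the generator does **not** emulate: biological replicate variance
(pooled libraries are the design), gene length biases in mappability,
correlated co-regulation beyond the shared archetype mean, batch effects,
and annotation incompleteness. Passing recovery tests on this generator
therefore demonstrates correctness of the pipeline's computations and its
behavior under the stated sampling model — not robustness to replicate
noise or mapping artifacts in field data.

# Problem sizes and numerical conventions

The test suite exercises the pipeline at 5,000 genes (20% responsive,
noise sd 0.2) for cluster recovery, 20 null simulations of 5,000 genes
for type-I control, and 1,000 random vectors for the FDR oracle; the
acceptance script runs the default 10,000-gene study. These sizes give
stable statistics while keeping a full run in seconds.

Numerical conventions collected in one place: p-values floored at the
smallest positive normalized double; BMU ties broken toward the lowest
unit index; best-50% ties broken by gene identifier; k-means ties resolved
by the WCSS-minimal restart; PCA eigenvector signs fixed so the largest
loading is positive; constant normalized columns map to 0; both-zero RPKM
pairs are untestable rather than 0-fold. Every stochastic stage takes an
explicit integer seed, and all TSV/JSON writers use fixed formats so
repeated runs are byte-identical — which the tests verify with file
checksums.

# Known limitations

- Without replicates, the exact test detects *library* differences;
  biological variability between pools is indistinguishable from
  treatment effect. Replicate-aware models (negative-binomial GLMs) are
  out of scope by design.
- RPKM ratios carry composition bias when overall expression shifts
  between conditions; no TMM-style correction is applied because plain
  RPKM ratios are the method's currency.
- The 0.3 coherence cutoff and k = 11 are taken as given, not selected
  from the data; no gap statistic or cluster-count selection is offered.
- GO enrichment reports raw Fisher p at 0.01 with no decorrelation of
  nested terms; treat term lists as descriptive profiling, not as
  corrected inference.
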