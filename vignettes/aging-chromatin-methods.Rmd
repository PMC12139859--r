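---
title: "Methods: hotspot detection, heterochromatin enrichment, and companion statistics for single-nucleus chromatin aging data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hotspot detection, heterochromatin enrichment, and companion statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromaging)
```

`chromaging` implements the computational core of a cell-type-resolved
analysis of chromatin accessibility in the aging mouse brain: how to call
age-differential peaks from binarized single-nucleus ATAC data, how to
find chromosomal *hotspots* where such peaks cluster, how to relate them
to H3K9me3-marked constitutive heterochromatin, and the companion
statistics (transposable-element pseudo-bulk testing, cell-composition
trends, cluster label transfer, Activity-By-Contact enhancer–gene
scoring). Everything runs on synthetic data produced by the package's own
seeded generator, so the full pipeline is testable on a laptop without
any external download.

## Differential accessibility on binarized matrices

Single-nucleus ATAC data are extremely sparse, so accessibility is
represented as a binary cell-by-peak matrix. For a peak $j$ and an age
group $g$ with $n_g$ cells, the pseudo-bulk summary is the detection
fraction $p_{jg}$ — the share of cells with any fragment in the peak
(`pseudobulk_fractions()`). The young/old comparison
(`test_differential_accessibility()`) is a two-sided two-proportion
z-test with pooled variance on these fractions, with effect size

$$\log_2\mathrm{FC}_j \;=\; \log_2\frac{p_{j,\mathrm{old}}+\varepsilon}
{p_{j,\mathrm{young}}+\varepsilon},
\qquad \varepsilon = \tfrac{1}{n_\mathrm{young}+n_\mathrm{old}},$$

where the pseudocount default is scale-free shrinkage that keeps the log
finite for empty fractions without dominating moderate ones. The
published analysis used an external differential-testing framework on the
same binarized representation; the z-test is this package's
dependency-free equivalent and is calibrated in the test suite (null
p-values uniform by Kolmogorov–Smirnov; FDR after Benjamini–Hochberg
within each cell type × region × sex family).

Filtering (`filter_dars()`) applies the three published rules: detection
in at least 1% of cells in either age group, a minimum absolute log2 fold
change, and adjusted p < 0.01. The literature states two effect-size
conventions — 0.25 for the primary screen and 0.5 for stricter reporting
— which genuinely disagree; both are supported through `min_abs_lfc`
(default 0.25) rather than silently picking one. Direction is the sign of
the fold change; a peak with log2FC exactly 0 belongs to neither
direction.

## The hotspot statistic

Aging-associated peaks are not scattered uniformly: some megabase-scale
regions accumulate many strong differential peaks. The hotspot statistic
makes that precise in four steps:

1. **Bin** the genome into 100 kb windows (`bin_genome()`); bins never
   cross chromosome boundaries and the last bin of a chromosome may be
   short.
2. **Count** qualifying DARs per bin (`count_dars_per_bin()`): raw
   p < 0.01 and |log2FC| > 1, i.e. only the strong tail of the DAR
   table. Each DAR increments exactly one bin — the bin containing its
   midpoint. DARs (~0.5 kb) are tiny relative to 100 kb bins, so
   fractional-overlap assignment would change nothing while complicating
   the arithmetic.
3. **Smooth** per chromosome with a symmetric Gaussian kernel
   (`gaussian_smooth()`), window 20 bins (~2 Mb), taps
   $w(j) = \exp\!\big(-\tfrac12 (\alpha j / (W/2))^2\big)$ for
   $j \in [-W/2, W/2]$ with shape $\alpha = 2.5$ — the common default
   behaviour of window-based Gaussian smoothers. At chromosome edges the
   kernel is renormalized over in-bounds bins, so a constant track is a
   fixed point and interior signal mass is conserved.
4. **Call** hotspot bins strictly above the genome-wide top-1% quantile
   of smoothed scores (`call_hotspots()`), merging adjacent hot bins into
   intervals. Ties at the threshold are excluded, so a constant track
   yields no calls. An optional absolute floor (`abs_threshold`) is
   supported for data on a known scale, but the quantile rule is primary:
   bin counts are left raw, and an absolute score only means something on
   the scale of the data it was derived from. The quantile is taken over
   all bins including zeros by default (`include_zero_bins = FALSE` gives
   the nonzero-only variant).

A consequence of the top-1% rule worth knowing: the number of supra-
threshold bins is fixed (~1% of bins), so hotspot detection operates
sensibly only when counted DARs are *sparse* — a handful of smoothed
"domes" competing for a small bin budget. This is exactly the regime of
real data: strong DARs number in the low thousands against a ~2.5 Gb
genome, well below one per 100 kb bin. The synthetic generator reproduces
this regime (below).

## Heterochromatin overlap and enrichment

`overlap_flags()` implements any-bp interval intersection in 0-based
half-open (BED) coordinates: `[100,200)` does not touch `[200,300)`.
`domain_enrichment()` contrasts the fraction of regions overlapping
H3K9me3-like domains with the genomic coverage of those domains and
reports two null models:

* an upper-tail **binomial** p-value
  $P(X \ge k \mid n, \text{coverage})$ — exact for point-like regions,
  slightly conservative-anticonservative for finite widths (the any-bp
  overlap probability exceeds coverage by roughly
  `n_domains × region_width / genome`, negligible when regions are small
  relative to domain spacing);
* a **permutation** p-value from re-placing each region uniformly on its
  own chromosome with its length preserved, upper tail with the standard
  $+1/(B+1)$ correction. Preserving chromosome and length controls for
  chromosome-level DAR density without modelling covariates the data do
  not constrain. The permutation engine is a sorted-boundary
  `findInterval()` scan, cross-checked in the tests against a quadratic
  GRanges oracle.

Because the permutation p-value counts ties (`count >= observed`) and
carries the $+1$ correction, its null distribution is discrete and
slightly conservative; calibration checks use enough regions and
permutations (1000 × 199 in the shipped checks) that the granularity no
longer distorts the uniformity statistic.

The Fig-5A-style direction analysis (`direction_split()`) partitions
filtered DARs by direction × domain membership per cell type and tests
the 2×2 association with an exact conditional test implemented by
hypergeometric enumeration (`fisher_exact_2x2()`, verified against
`fisher.test`). `biotype_top_composition()` reports, for the top-$n$
up- and downregulated genes, the fraction annotated lncRNA or pseudogene
— the readout showing repressed biotypes surfacing during
heterochromatin decay. The ranking key (ascending adjusted p, ties by
descending |log2FC|, then gene id) is a package choice; the source
analyses do not state theirs.

## Transposable-element pseudo-bulk testing

`aggregate_pseudobulk()` sums cell-by-subfamily counts over (cell type,
age, replicate) — exact integer sums, grand total conserved.
Normalization is median-of-ratios (`size_factors_median_of_ratios()`):
factor of group $g$ is the median over features of
$c_{fg}/\mathrm{geomean}_f$, computed over features positive in every
group. Size factors are defined only up to a common scale; they are
rescaled to median 1 so that, e.g., a column that is a doubled copy of
the others gets factor 2 and the rest keep 1.

The differential test (`test_te_differential()`) uses the statistic
$\log_2\!\big(\frac{\bar c_\mathrm{old}+0.5}{\bar c_\mathrm{young}+0.5}\big)$
on normalized means and permutes replicate age labels, exhaustively when
the number of distinct label assignments fits the permutation budget
(e.g. all $\binom{4}{2} = 6$ assignments at 2 vs 2). A permutation test
replaces the negative-binomial likelihood-ratio machinery of the original
pipeline deliberately: the contribution there is the aggregation design,
and permutation is assumption-free at the 2–4 replicates typical of these
experiments.

Two null modes are exposed, and the choice matters. **Per-feature** mode
is exact but floored: with 4 vs 4 replicates there are only 70 distinct
assignments, so no feature can score below p = 2/70 ≈ 0.029 — and
Benjamini–Hochberg at 0.05 across hundreds of features can then never
reject anything, no matter how strong the effect. **Pooled** mode pools
the permuted statistics of all features into one null distribution
(standard small-replicate practice), giving p-value resolution of about
1/(features × permutations) at the cost of assuming features share a
null scale after normalization. For genome-wide FDR control at small
replicate counts the pooled mode is the usable one; per-feature mode
remains the default because its p-values are exact and
self-contained.

## Cell-composition trends

`weighted_proportions()` computes per-sample cell-type proportions, a
sample being one biological unit (region × sex × replicate × age). The
default `"equal-sample"` weighting gives every sample at an age the same
weight, so a region contributing 19,000 nuclei does not drown one
contributing 1,000; `"by-cells"` weighting is available where
size-proportional averaging is wanted. "Weighted" is not further
specified in the source analyses, so the equal-sample default is a
package decision made for robustness to dissection yield.

`test_age_trend()` is the two-sided Wilcoxon rank-sum test on per-sample
proportions, exact (full enumeration) when both groups have ≤ 12
tie-free samples, normal approximation with tie and continuity
correction otherwise. Complete separation at 8 vs 8 gives the exact
two-sided floor $2/\binom{16}{8} = 2/12870$. Note the approximation
tracks the exact branch closely on the *absolute* p scale but loses
relative accuracy deep in the tail — a property of the normal
approximation, not of the implementation. Rank-sum p-values are
invariant under monotone transforms of the proportions, so the same
result holds on logit or arcsine scales.

## Label transfer

Two procedures are implemented exactly as used for spatial-data
annotation. `cluster_mean_zscore()` z-scores each gene across **all**
cells jointly, then averages within cluster (zero-variance genes are
excluded and reported). `correlate_and_assign()` computes Pearson
correlation between query and reference profiles over their sorted
shared-gene intersection and assigns each query cluster its argmax
reference label; exact ties leave the cluster unassigned — deterministic
and conservative, since the sources do not state tie handling.

For cell-level predictions with confidence scores,
`refine_subcluster_labels()` applies the confidence-gated majority vote:
within each subcluster only cells with score **strictly** above 0.85
vote; the modal label is adopted by the whole subcluster if it exceeds a
strict majority of voters, otherwise the subcluster is dropped.
`consistency_assign()` is the 80% rule: a subcluster is labelled only
when strictly more than 80% of *all* its cells map to one reference
label. Both thresholds are strict inequalities on purpose — the boundary
cases (score exactly 0.85, share exactly 80%) are excluded, matching the
stated rules, and the tests pin those boundaries.

## Activity-By-Contact linking

`candidate_elements()` selects, for each gene, the peaks whose midpoint
lies strictly within 5 Mb of the TSS on the same chromosome (TSS =
annotated start on the annotated strand; the `end` coordinate for
minus-strand genes). `abc_scores()` then computes

$$\mathrm{ABC}(e, g) \;=\;
\frac{A_e \, C_{e,g}}{\sum_{e' \in E(g)} A_{e'}\, C_{e',g}}$$

with $A$ the element's accessibility signal and $C$ the normalized
contact frequency; per-gene scores sum to 1 whenever any candidate is
productive, and genes with an all-zero denominator yield no links.
Activity here is accessibility alone — the matched histone data needed
for a geometric-mean activity are consumed upstream in the original
framework, not here — and a precomputed activity vector can be supplied
instead. Missing contact entries count as zero contact; no pseudocount
is added unless configured. The candidate window and any score threshold
follow the cited framework's defaults and are exposed, not asserted as
values used by any particular study.

## The synthetic-data generator

`sim_config()` + `simulate_genome()`/`simulate_dars()`/
`simulate_cells()`/`simulate_te_matrix()`/`simulate_label_profiles()`
generate every input the pipeline consumes, under one master seed split
deterministically into per-generator streams (adding a generator never
perturbs another's draws; identical configuration is bit-identical).

What the generator emulates, and the defaults it fixes:

* **Genome & domains** — a multi-chromosome genome (default 5 × 20 Mb);
  repressive domains as non-overlapping 250 kb blocks placed uniformly,
  totalling ~3% of the genome. Fixed-length blocks match the broad-domain
  character of H3K9me3 without inventing a length distribution the data
  do not constrain.
* **DARs** — 500 bp intervals (real hotspot example peaks are ~501 bp);
  background placed uniformly, except that the probability of landing in
  a domain is `enrichment × coverage` (excess mass drawn from outside),
  so the background set's observed/coverage ratio converges to the
  configured multiplier. Planted hotspots add exactly `n_dars` intervals
  within their spans *on top of* the background — hotspots are regions of
  excess density, which is what the statistic detects. Effect sizes are
  base-plus-exponential: background |log2FC| = 0.25 + Exp(rate 6) (most
  DARs sit just above the calling threshold; ~1% exceed the hotspot
  cutoff of 1), planted |log2FC| = 1 + Exp(rate 2) (all strong). This
  reproduces the sparse counted-DAR regime in which the published
  top-1% smoothing threshold (0.2 on their scale) lives. Directions are
  up/down with configurable probabilities, including a raised
  `domain_up_prob` to mimic the predominance of upregulation inside
  heterochromatin.
* **Cells** — multinomial cell-type composition per age and replicate;
  defaults encode a progenitor-like decline from 3% at 2 months to 0.01%
  at 18 months, an immature-oligodendrocyte-like decline 2% → 0.1%, and
  an immature-neuron decline 4% → 1%. Accessibility entries are
  independent Bernoulli draws with per-peak, per-age probabilities.
* **TE counts** — Poisson counts with per-(subfamily, sample) rates:
  log-uniform subfamily baselines, gamma replicate noise (mean 1,
  variance 0.05), and planted old-age fold changes.
* **Profiles** — reference cluster profiles i.i.d. normal; query =
  reference + Gaussian noise, with an optional confusion rate that
  regenerates a query cluster from a different reference cluster (the
  true map is returned for scoring).

What it deliberately does **not** model: read-level data, fragment
files, doublets, batch effects, peak co-accessibility structure, spatial
coordinates, or realistic TE genomic placement. Passing tests therefore
demonstrate that the statistics do what they claim under their stated
sampling assumptions — not that those assumptions hold in any particular
real dataset.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open throughout the file interfaces;
  `GRanges` is the in-memory interval container.
* Strict inequalities at every published threshold (top-1% quantile,
  score > 0.85, share > 80%, adjusted p < 0.01); ties fail the
  threshold.
* Empty groups yield missing flags, never silent zeros; peaks with a
  group under 2 cells are skipped with a warning; an empty domain set
  makes enrichment undefined rather than zero; an all-equal smoothed
  track warns and returns no hotspot calls.
* Degenerate proportions (all samples identical) return p = 1 directly,
  where the tie-corrected normal approximation would be 0/0.
* Invalid configurations (coverage ≥ 1, enrichment × coverage > 1,
  planted DARs exceeding span capacity at the 500 bp minimum spacing,
  probabilities outside [0,1]) raise a classed `invalid_config_error`.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run every check at desk scale,
chosen so the whole suite completes in a few minutes on one CPU: 500-bin
smoothing oracles; 5 × 20 Mb genomes with 30,000 background DARs and
five planted 50-DAR clusters; 5,000-region enrichment with 200-fold
calibration replicates at 1000 regions × 199 permutations; 2,000 null
peaks at 200 cells per group and 100-seed effect recovery; 8 vs 8
composition samples; 50-seed label-transfer recovery at 20 clusters ×
200 genes; 1,000 peaks × 100 genes for ABC; 500 TE subfamilies at 4 vs 4
replicates. The headline tallies of the motivating study (~10^6 nuclei,
~9 × 10^5 cCREs) require the full dataset and external annotation tracks
and are out of scope here; the package verifies the *procedures*, at
scales where every expected value can be computed independently.

## Known limitations

* The two-proportion z-test treats cells as independent; replicate
  structure enters only through the BH family definition, not the
  variance. With strong replicate effects a hierarchical test would be
  more conservative.
* The binomial enrichment null ignores region width (see above); the
  permutation null does not, and is the one to trust when they disagree.
* Pooled-null TE p-values assume comparable null scales across features
  after normalization; heteroskedastic features (very low counts) can
  violate this. The per-feature mode is immune but floored.
* The hotspot quantile threshold adapts to the data; two datasets are
  comparable through their calls only if counted at the same filters and
  bin width.
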