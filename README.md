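# chromaging

Chromatin-accessibility statistics for studying brain aging at
single-nucleus resolution: differential-accessibility filtering on
binarized cell-by-peak matrices, Gaussian-density **hotspot** detection
along the binned genome, H3K9me3 heterochromatin overlap and enrichment
testing, transposable-element (TE) pseudo-bulk quantification,
cell-composition trend testing, cluster-profile label transfer, and
Activity-By-Contact (ABC) enhancer–gene scoring. A seeded synthetic-data
generator produces genomes, peak sets, planted DAR clusters, repressive
domains, binary accessibility matrices, TE count matrices and cluster
expression profiles, so the entire pipeline is testable without any
external data.

**Who it is for.** Computational biologists analysing single-nucleus
ATAC-seq (or similar binarized accessibility data) across age groups who
need the bespoke statistics of this analysis style as tested, reusable R
functions rather than one-off scripts.

## The statistics in brief

*Differential accessibility.* For peak *j*, compare detection fractions
between age groups with a two-sided two-proportion z-test (pooled
variance); effect size `log2((p_old + eps)/(p_young + eps))` with
`eps = 1/(n_young + n_old)`; BH adjustment within each
(cell type, region, sex) family; filters: detected in ≥ 1% of cells in
either group, `|log2FC| >= 0.25` (or 0.5), adjusted p < 0.01.

*Hotspots.* Count strong DARs (p < 0.01, |log2FC| > 1) into 100 kb bins
by midpoint, smooth each chromosome with a Gaussian window of 20 bins
(taps `w(j) = exp(-((2.5 j)/(W/2))^2 / 2)`, edge-renormalized), and call
bins strictly above the genome-wide top-1% quantile, merging adjacent
hot bins into intervals.

*Heterochromatin enrichment.* Fraction of regions overlapping H3K9me3
domains (any-bp, half-open) versus domain genome coverage, with an
upper-tail binomial p-value and a chromosome- and length-preserving
permutation p-value; direction split (up/down × in/out) with an exact
2×2 test; lncRNA/pseudogene composition of top differential genes.

*TE pseudo-bulk.* Sum counts over (cell type, age, replicate),
median-of-ratios size factors, and a replicate label-permutation test
(exhaustive at small designs; per-feature or pooled null).

*Composition.* Per-sample cell-type proportions with equal-sample
weights and exact Wilcoxon rank-sum age testing.

*Label transfer.* Mean z-scored cluster profiles, Pearson-correlation
assignment, confidence-gated (> 0.85) majority-vote refinement, and the
strict > 80% consistency rule.

*ABC.* `ABC(e,g) = A_e C_eg / sum_{e' in candidates(g)} A_e' C_e'g` over
candidate elements within 5 Mb of the TSS.

See `vignettes/aging-chromatin-methods.Rmd` for models, assumptions,
parameter defaults and design rationale.

## Worked example

Simulate a 5 × 20 Mb genome with ~3% heterochromatin-like domain
coverage, 30,000 background DARs with an 8× domain placement bias and
85% upregulation inside domains, plus two planted hotspot clusters
(50 strong DARs in 500 kb each); then run the hotspot and enrichment
statistics.

```r
library(chromaging)

cfg <- sim_config(seed = 42,
                  n_background_dars = 30000,
                  domain_dar_enrichment = 8, domain_up_prob = 0.85,
                  planted_hotspots = data.frame(chrom = c("chr2", "chr4"),
                                                center_bp = c(5e6, 1.2e7),
                                                span_bp = 5e5, n_dars = 50))
g    <- simulate_genome(cfg)
dars <- simulate_dars(g$layout, g$domains, cfg)

raw      <- count_dars_per_bin(dars, bin_genome(g$layout, bin_width = 1e5),
                               lfc_min = 1, p_max = 0.01)
smooth   <- gaussian_smooth(raw, window_bins = 20)
hotspots <- call_hotspots(smooth, quantile = 0.99,
                          domains = g$domains, raw_track = raw)
hotspots
#>   chrom    start      end n_bins peak_score n_dars overlaps_domain
#> 1  chr2  4800000  5300000      5   4.781633     44           FALSE
#> 2  chr4 11800000 12300000      5   4.835464     46           FALSE
```

Both planted clusters — and nothing else — exceed the top-1% smoothed
density threshold; each call spans 5 bins (500 kb) around the planted
center and contains ~45 of the 50 strong DARs planted there (the rest
fall just outside the counting filters or the merged bins).

```r
strong <- filter_dars(dars, min_abs_lfc = 0.5)
domain_enrichment(dars_to_regions(strong), g$domains, g$layout,
                  n_permutations = 1000, seed = 1)
#> EnrichmentResult: 1648/6746 regions in domains (24.4%) vs 3.00% genome coverage
#>   enrichment ratio 8.14, binomial p 0, permutation p 0.000999 (n = 1000)
```

The strong (|log2FC| ≥ 0.5) DARs land in domains 8.1 times more often
than the 3% genome coverage predicts — recovering the configured 8×
bias — and no permutation among 1000 reaches the observed overlap
(p = 1/1001).

```r
direction_split(dars, g$domains)
#>   cell_type up_in down_in up_out down_out up_fraction_in up_fraction_out
#> 1       all  6204    1067  11268    11561      0.8532526       0.4935827
```

Inside domains 85% of DARs are upregulated (as configured) while outside
the split is balanced — the signature of heterochromatin opening with
age.

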