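# orzone

Analysis toolkit for zonal olfactory receptor (OR) regulation.

Every mature olfactory sensory neuron (OSN) expresses one OR allele out of
more than a thousand, and which receptors are eligible depends on the
neuron's dorsoventral position: the olfactory epithelium is divided into
five expression zones (plus the dorsal Class I receptors), with
heterochromatin — H3K9me3 read by HP1 proteins — silencing out-of-zone
receptors along a dorsoventral gradient. Studying this system requires a
recurring set of computations across bulk RNA-seq, single-cell RNA-seq,
chromatin profiling (CUT&RUN / ChIP / ATAC), soft X-ray tomography and
fluorescence imaging. `orzone` packages those computations, together with
seeded simulators that generate every input with planted ground truth so
the whole pipeline is testable end to end without any external data.

What it computes:

* **Zonal expression** — per-gene log2 fold changes with BH-adjusted
  t-tests; significance classification (padj < 0.05, |log2FC| > 0.58);
  zone-stratified summaries; the OR-group shift test (one-sample t of the
  OR log2FCs against zero,
  `t = mean(log2FC) / (sd(log2FC)/sqrt(n))`); FPKM→TPM; positive-cell
  fraction comparisons.
* **Single-cell identity** — chosen-OR calling (argmax of OR counts per
  cell), zonal choice fractions, OR masking, a linear-SVM dorsal/ventral
  classifier on standardized log1p counts-per-10k with an OR-leakage audit,
  marker selection, and OR co-expression tallies.
* **Chromatin signal** — per-10M track normalization, FRiP, per-gene and
  TSS-profile aggregation (strand-aware, BED half-open conventions), exact
  Wilcoxon comparisons, Spearman zonal-gradient statistics with permutation
  p-values, and peak-overlap counting.
* **Tomogram partitioning** — a smoothed two-component Gaussian-mixture
  segmentation of nuclear linear-absorption-coefficient volumes into eu-
  and heterochromatin (posterior > 0.5 after mask-restricted Gaussian
  smoothing), a 37% maturity gate, and a watershed split of heterochromatin
  into inner and outer compartments seeded from local-thickness
  percentiles (P50/P90) at the nuclear envelope.
* **Image quantification** — radial intensity profiles around foci, a
  peripheral enrichment index, Fisher-Z comparison of correlations, and
  bilinear line-intensity profiles.
* **Simulators** — bulk counts with planted OR-group shifts, monoallelic
  single-cell counts with dorsoventral marker structure, nucleus phantoms
  with exact planted chromatin fractions, zonal coverage tables, and focus
  images (ring / core / uniform modes).

## Worked example

Simulate a bulk experiment with a planted OR-group shift of −1.75 (300 OR
genes, 3000 non-OR genes, 3 vs 3 replicates), estimate per-gene fold
changes, and test the OR group:

```r
library(orzone)

sim <- sim_bulk_counts(n_or_genes = 300, n_nonor_genes = 3000,
                       or_group_log2fc = -1.75, seed = 1)
de  <- assign_zones(estimate_log2fc(sim$counts, sim$group), sim$zones)
or  <- de$zone != "nonOR"
group_shift_test(de$log2fc[or])
#> Group shift test (one_sample) for group 'OR'
#>   n = 300, mean log2FC = -1.6806
#>   t = -67.0481 (df = 299.0), p = 3.312e-182

zone_stratified_summary(de)[1:6, c("zone", "n", "mean", "median")]
#>     zone  n      mean    median
#> 1 classI 50 -1.686664 -1.753742
#> 2     z1 50 -1.584266 -1.588353
#> 3     z2 50 -1.588624 -1.627506
#> 4     z3 50 -1.705521 -1.636243
#> 5     z4 50 -1.720104 -1.688028
#> 6     z5 50 -1.798196 -1.723748
```

The group mean recovers the planted effect (−1.68 vs −1.75 at this problem
size; the residual is the known pseudocount/composition bias of the plain
estimator, analysed in the methods vignette), and the group test is
decisive even though per-gene power at 3 vs 3 replicates is low.

Partition a simulated tomogram planted at 43% heterochromatin and split it
into compartments:

```r
ph   <- sim_nucleus_phantom(seed = 1)       # 64^3 grid, 43% het planted
part <- fit_gmm_partition(ph$lac, ph$mask, sigma = 1.5, seed = 1)
part
#> Chromatin partition of 73824 nuclear voxels
#>   euchromatin 57.6%, heterochromatin 42.4% of nuclear volume
#>   mixture means (normalized LAC): eu 0.744, het 1.338
gate_mature(part)
#> [1] TRUE
sxt_inner_outer(ph$truth == 2L, ph$mask)
#> Heterochromatin compartments: outer 22221 voxels (70.0%), inner 9523 voxels (30.0%)
```

The recovered 42.4% matches the planted 43% to within the smoothing-induced
erosion budget, the nucleus passes the 37% maturity gate, and the watershed
recovers the planted 70/30 shell/blob split exactly.

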