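---
title: "Methods: zonal olfactory receptor expression, identity and chromatin analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: zonal olfactory receptor expression, identity and chromatin analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orzone)
```

## The biological problem

Each mature olfactory sensory neuron (OSN) in the mouse main olfactory
epithelium expresses a single olfactory receptor (OR) allele out of more than
a thousand candidates. Which receptor can be chosen is constrained by the
neuron's position: the epithelium is partitioned into five dorsoventral
expression zones (zone 1 dorsal through zone 5 ventral), with the ancient
Class I receptors confined to dorsal zone-1 territory. Heterochromatin —
H3K9me3 and its HP1 reader proteins — silences out-of-zone receptors, and
the depth of that silencing forms a dorsoventral gradient over the OR gene
clusters. `orzone` implements the quantitative analyses this model calls
for: zone-stratified differential expression, single-cell chosen-OR calling
and machine-learned zonal identity, chromatin-signal aggregation over OR
genes, partitioning of soft X-ray tomograms into eu- and heterochromatin,
and fluorescence-image quantification — together with seeded simulators
that generate every input with planted ground truth.

Every stochastic function takes an explicit `seed`; no global RNG state is
consumed or left behind, and a fixed seed reproduces output byte for byte.

## Synthetic data as the test bed

Real datasets of this kind are large and access-controlled; the package is
therefore exercised end to end on synthetic data whose generating
parameters are known exactly. Each generator returns the ground truth next
to the data, so a downstream estimator can be scored as a parameter-recovery
problem. The simulators emulate the statistical structure that matters for
the methods — they do not emulate read-level artifacts (alignment errors,
doublets, ambient RNA, reconstruction noise), so a passing suite certifies
the estimators against their stated noise models, not against every failure
mode of real data.

### Bulk counts (`sim_bulk_counts`)

Gene-level negative-binomial counts (variance $\mu + \phi\mu^2$, default
dispersion $\phi = 0.1$, the magnitude typical of bulk RNA-seq biological
replicates) for OR and non-OR genes across two genotype groups. OR genes are
assigned round-robin to Class I and zones 1–5, and their perturbed-group
means are scaled by a planted log2 fold change, global or per zone. Gene
baselines are log-normal (sdlog 0.5) around class means of 100 (OR) and 400
(non-OR): in whole-epithelium RNA each receptor is expressed in only the
small subset of neurons that chose it, so ORs sit well below typical genes.
This composition also keeps the OR share of the library small (~1.4%), which
matters because a *global* OR shift perturbs the library size itself; with a
small OR share the compositional bias of library-size normalization stays
within ~0.02 log2 units even for a planted shift of −1.75.

### Single-cell counts (`sim_sc_counts`)

Each cell draws a zone from `zone_choice_probs`, then one OR uniformly
within the zone — receptor choice is random within the zonal repertoire —
and expresses it at Poisson mean 50 against an ambient OR background of
0.05, the contamination level characteristic of droplet scRNA-seq; this
keeps cells monoallelic (one OR at high counts) as in the real system.
Dorsal (Class I + zones 1–3) and ventral (zones 4–5) cells are separated by
`marker_effect` log2 units on a 50-gene marker panel, mirroring the roughly
fifty transcripts that distinguish the two programs; 200 background genes
carry no class signal. `shift_ventral_frac` converts a fraction of
ventral-drawn cells to the dorsal program (dorsal markers *and* a dorsal
chosen OR), emulating the loss of ventral identity seen when
heterochromatic silencing fails.

### Nucleus phantoms (`sim_nucleus_phantom`)

A spherical nucleus (radius 26 voxels in a 64³ grid) with heterochromatin
planted as a peripheral shell plus chromocenter-like interior spheres, at an
exact target volume fraction (default 43%, the zone-1 control level; the
realised fraction is within one voxel of the target by construction). LAC
values are Gaussian per class, default means 0.25/0.45 with SD 0.05 — a
4-SD class separation. Geometry defaults follow mature-OSN nuclear
architecture at the ~100 nm voxel scale of the grid: the shell takes 70% of
the heterochromatin (thickness ≈ 3 voxels) and blobs span 27–42% of the
nucleus radius (7–11 voxels, scaling down for smaller phantoms). Both
length scales sit well above the σ = 1.5 posterior-smoothing kernel of the
segmentation. This is deliberate: Gaussian smoothing followed by a 0.5
threshold erodes convex structures by roughly σ²·(mean curvature), so
structures near the smoothing scale would be lost by geometry alone (a
2-voxel shell loses ~5% of its voxels, small blobs ~7%, costing ~2
percentage points of heterochromatin before any noise enters). With the
default geometry the planted fraction is recoverable to well within ±2
points, and on a noiseless phantom the partition reproduces the truth
exactly before smoothing and to ≥99% after it — the residual flips are the
single-voxel rim where threshold-level smoothing is genuinely ambiguous.

### Coverage tables and focus images

`sim_coverage_table` draws per-gene signal around planted zone means
(truncated at zero, since coverage summaries are nonnegative), emulating a
dorsoventral methylation gradient. `sim_focus_image` paints circular foci
onto a noisy image with a positive baseline: `ring` places peak intensity at
the focus radius (a protein rimming DAPI-dense foci), `core` concentrates it
centrally, and `uniform` adds unstructured signal everywhere — the null
profile of a protein with no focal enrichment.

## Zonal expression statistics

`estimate_log2fc` is intentionally plain: library-size normalization
(samples scaled to the mean depth — counts-per-million up to a constant),
pseudocount 0.5, log2 ratio of group means, per-gene Welch t-test on log2
normalized counts, Benjamini–Hochberg adjustment. It stands in for a full
shrinkage-based DE model so the simulation studies remain self-contained;
its bias terms (pseudocount, composition) are the reason the generator's
defaults are calibrated as described above. Significance calls use the
conventional thresholds padj < 0.05 and |log2FC| > 0.58 (1.5-fold), both
configurable; the same operation parameterized to raw p < 0.2 and
log2FC > 1 reproduces the interactor rule used for co-IP proteomics
screens.

The OR-group shift test is a one-sample t-test of the per-gene OR log2 fold
changes against zero. Whether such a "group t-test" should instead be a
two-sample comparison against non-OR genes is ambiguous; the one-sample
form is the default because the scientific question is whether the OR group
moved from zero while non-OR genes are unperturbed by construction, and the
two-sample form is available via the `reference` argument. Class I
receptors are kept as their own stratum in `zone_stratified_summary` rather
than merged into zone 1.

## Single-cell identity

The chosen OR is the argmax of OR counts per cell; ties are broken to the
lexicographically first gene and flagged, and all-zero cells get no call.
Before identity classification, OR genes are masked. The default mode drops
*every* OR column — stricter than removing only each cell's chosen OR, and
immune to leakage through residual counts of non-chosen ORs; `chosen_only`
is retained for fidelity to the looser protocol. The classifier is a
linear-kernel SVM (C = 1) on standardized log1p counts-per-10k. The kernel,
normalization and protocol are deliberate choices where the field's
convention is just "an SVM": linear is deterministic, fast at a few
thousand cells, and its weights are auditable — the package asserts that no
OR gene appears among the features. Mature-OSN subsetting is accepted as an
input cell list rather than re-deriving maturity from markers. Models are
trained on control cells and applied across conditions; `identity_shift_table`
cross-tabulates experimental (chosen-OR-derived) versus predicted identity,
conserving experimental marginals by construction.

## Chromatin signal

All intervals are 0-based half-open (BED convention); touching intervals do
not overlap. Tracks are binned (100 bp in the examples) rather than
per-base, and normalized to a 10-million-read library. Overlap machinery is
delegated to GenomicRanges/IRanges, with brute-force all-pairs scans as the
independent oracle in tests. TSS windows are strand-aware (start on +, end
on −) with minus-strand profiles reversed to 5′→3′; the promoter default is
TSS ± 1 kb, configurable, and both promoter and gene-body windows are
exposed since either may be the right aggregation unit. Group comparisons
use the Wilcoxon rank-sum test, exact for small tie-free samples. The zonal
gradient statistic is the Spearman correlation between zone index (1–5) and
per-gene signal with a two-sided permutation p-value — rank-based because
the gradient claim is ordinal, not linear.

## Tomogram partitioning

Within the nucleus mask, LAC values are divided by their within-mask mean
("mean normalization"; z-scoring is exposed as an option), and a
two-component Gaussian mixture with unequal variances is fit (via mclust,
initialized on a seeded 2000-voxel subset, deterministic given the seed).
The higher-mean component is heterochromatin — LAC rises with density. The
heterochromatin posterior is mapped into the volume and smoothed with a
Gaussian kernel (default σ = 1.5 voxels) whose support is restricted to the
mask by normalized convolution, so extranuclear voxels never dilute the
posterior; labels are posterior > 0.5. A volume with exactly two distinct
values short-circuits to the exact assignment, since a degenerate mixture
has no finite-variance fit. Near-constant volumes are an error. Nuclei are
gated as mature OSNs when heterochromatin strictly exceeds 37% of nuclear
volume, applied to the final (smoothed) segmentation.

The inner/outer split runs watershed on the Euclidean distance transform of
the heterochromatin mask. Local thickness uses the largest-inscribed-sphere
definition computed by sphere painting over the exact EDT, with diameter
2·EDT − 1 (the −1 accounts for the half-voxel from a voxel centre to the
mask surface on each side; an odd-thickness slab then measures exactly its
thickness). Seed calibration takes the 50th and 90th percentiles of the
local thickness of heterochromatin voxels in a two-voxel border region
along the envelope: voxels with envelope distance at or below P50 form the
outer seed, beyond P90 the inner seed. Envelope distances are measured from
voxel centre to the envelope *surface* (nucleus EDT − 0.5) so that depths
and thickness diameters share a length convention — without the half-voxel
correction a peripheral rim can spuriously seed its own "inner" compartment.
Inner-seed components below 1% of the largest (26-connectivity, the 3D
default used throughout) are removed. The watershed floods from the seeds
in order of decreasing EDT with deterministic FIFO tie-breaking; rare
heterochromatin fragments disconnected from both seeds are assigned to the
compartment with the nearest labelled voxel.

## Image quantification

Radial profiles average pixel intensity in 15 equal bins of normalized
radius r/R out to 1.5·R (defaults; the extension past the focus boundary is
what lets a peripheral ring show up as a peak at r/R ≈ 1). A focus whose
outer circle leaves the image fails individually without aborting the
batch. The peripheral enrichment index — mean intensity at r/R ∈ [0.8, 1.2]
over mean at r/R ∈ [0, 0.5] — summarizes periphery-versus-core localization
as one number. Two correlations are compared with Fisher's Z
(`atanh` transform, normal reference); the package exposes the test as a
primitive on (r, n) pairs since the correlated quantity (typically
per-focus protein-versus-DAPI profile correlations) varies by experiment.
Line profiles sample by bilinear interpolation at a fixed step along a
polyline, as in a basal-to-apical transect of the epithelium.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale by design:
64³ phantoms (≈74,000 nuclear voxels), bulk simulations of 22,182 genes ×
6 samples, and single-cell simulations of up to 2,000 cells × 550 genes.
These sizes keep every recovery experiment comfortably under a minute while
leaving the estimators' operating characteristics unchanged. Permutation
p-values use 1,000 permutations with a fixed seed. The Wilcoxon switches
from exact to the tie-corrected normal approximation above 50 observations
per group. Quantiles are R's default type-7 throughout.

## Known limitations

* The DE estimator is unshrunk; at 3-vs-3 replicates its per-gene fold
  changes are noisy, and only group-level summaries are asserted to
  tolerance. It is a stand-in for count-model DE inference, not a
  replacement.
* The smoothing/threshold segmentation inherits the geometric erosion
  discussed above; on volumes whose structures approach the smoothing
  scale the reported heterochromatin percent is biased low.
* The identity classifier is linear; strongly nonlinear zonal programs
  would require a different kernel, at the cost of determinism of the
  weight audit.
* Generators emulate distributional structure only; no read-level,
  alignment, or batch artifacts.
* The local-thickness seed calibration assumes the peripheral rim is
  thinner than the interior masses are deep; inverted geometries
  (heterochromatin only at depth, none at the rim) correctly raise the
  degenerate-seed error rather than guessing.
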