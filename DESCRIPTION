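Package: orzone
Title: Zonal Olfactory Receptor Expression, Identity and Chromatin Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for studying zonal olfactory receptor (OR)
    regulation. Provides seeded simulators with planted ground truth (bulk
    RNA-seq counts, monoallelic single-cell OR choice, soft X-ray tomography
    nucleus phantoms, zonal coverage tables, fluorescence focus images);
    zone-stratified differential-expression summaries and OR-group shift
    tests; chosen-OR calling, OR-gene masking and linear-SVM dorsoventral
    identity classification for single-cell data; chromatin-signal
    aggregation (FRiP, per-gene coverage, TSS profiles, zonal gradient
    statistics, interval overlap counting); a smoothed Gaussian-mixture
    partition of tomographic nuclei into eu- and heterochromatin with a
    watershed split into inner and outer compartments; and radial/line
    fluorescence intensity profiling with Fisher-Z comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    S4Vectors,
    Rcpp,
    e1071,
    mclust,
    tiff,
    GenomicRanges,
    IRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
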