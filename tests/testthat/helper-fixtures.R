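# Shared miniature fixtures, all built in code.

tiny_zone_table <- function() {
  data.frame(gene_id = c("OrA", "OrB", "OrC", "Gapdh", "Omp"),
             zone = c("z1", "z3", "z5", "nonOR", "nonOR"),
             stringsAsFactors = FALSE)
}

# six-gene DE table with hand-enumerable significance calls:
# down: g1 (padj .01, lfc -1), g4 (padj .04, lfc -0.59)
# up:   g3 (padj .04, lfc 0.59)
# ns:   g2 (padj .2), g5 (padj NA), g6 (|lfc| < 0.58)
toy_de_table <- function() {
  data.frame(gene_id = paste0("g", 1:6),
             log2fc = c(-1, -1, 0.59, -0.59, -2, 0.3),
             pvalue = c(0.001, 0.15, 0.01, 0.01, 0.001, 0.001),
             padj = c(0.01, 0.2, 0.04, 0.04, NA, 0.01),
             stringsAsFactors = FALSE)
}

# brute-force all-pairs interval overlap oracle (0-based half-open)
brute_overlaps_any <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    same <- subject$chrom == query$chrom[i]
    any(same & subject$start < query$end[i] & subject$end > query$start[i])
  }, logical(1))
}

random_intervals <- function(n, seed, max_pos = 1e6, max_len = 500,
                             chroms = c("chr1", "chr2")) {
  set.seed(seed)
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_len, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# small solid-sphere mask for geometry tests
sphere_mask <- function(n, r, center = (n + 1) / 2) {
  ax <- (seq_len(n) - center)^2
  array(outer(outer(ax, ax, "+"), ax, "+") <= r^2, dim = c(n, n, n))
}
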