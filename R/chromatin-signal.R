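# Interval convention throughout: BED-style 0-based half-open [start, end);
# touching intervals do not overlap. Conversion to the 1-based closed
# coordinates of GenomicRanges happens at the boundary of each operation.

as_granges0 <- function(df, what = "intervals") {
  if (!is.data.frame(df) || !all(c("chrom", "start", "end") %in% names(df))) {
    stop_input(what, " must be a data frame with chrom, start, end")
  }
  if (nrow(df) && any(df$start < 0 | df$start >= df$end)) {
    stop_input(what, " must satisfy 0 <= start < end")
  }
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end))
}

#' Construct a binned coverage track
#'
#' @param df data frame with `chrom`, `start`, `end`, `value` (0-based
#'   half-open bins, nonnegative signal).
#' @param bin_size bin width in bp; inferred from the bins when `NULL`.
#' @param normalized `"raw"` or `"per10M"`.
#' @return the data frame, sorted, classed `coverage_track` with `bin_size`
#'   and `normalized` attributes. Overlapping bins are an error; unsorted
#'   input is sorted with a warning.
#' @export
coverage_track <- function(df, bin_size = NULL, normalized = "raw") {
  if (!is.data.frame(df) || !all(c("chrom", "start", "end", "value") %in% names(df))) {
    stop_input("a coverage track needs chrom, start, end, value columns")
  }
  if (any(df$start < 0 | df$start >= df$end)) stop_input("bins must satisfy 0 <= start < end")
  if (any(df$value < 0)) stop_input("coverage values must be >= 0")
  ord <- order(df$chrom, df$start)
  if (!identical(ord, seq_len(nrow(df)))) {
    warning("coverage bins were not sorted; sorting", call. = FALSE)
    df <- df[ord, , drop = FALSE]
    rownames(df) <- NULL
  }
  by_chrom <- split(df, df$chrom)
  if (any(vapply(by_chrom, function(d) any(d$start[-1] < d$end[-nrow(d)]), logical(1)))) {
    stop_input("coverage bins overlap")
  }
  if (is.null(bin_size)) {
    w <- unique(df$end - df$start)
    bin_size <- if (length(w) == 1) w else NA_integer_
  }
  structure(df, class = c("coverage_track", "data.frame"),
            bin_size = bin_size, normalized = normalized)
}

#' Normalize a coverage track to a 10-million-read library
#'
#' Scales every bin by `1e7 / total_reads`, putting tracks from libraries of
#' different depths on a common reads-per-10M scale.
#'
#' @param track a [coverage_track()].
#' @param total_reads library size in reads; must be positive.
#' @return the scaled track, marked `per10M`.
#' @export
normalize_track <- function(track, total_reads) {
  if (!inherits(track, "coverage_track")) stop_input("`track` must be a coverage_track")
  check_positive(total_reads, "total_reads")
  track$value <- track$value * 1e7 / total_reads
  attr(track, "normalized") <- "per10M"
  track
}

#' Fraction of reads in peaks (FRiP)
#'
#' The fraction of read intervals overlapping (by at least 1 bp) any peak —
#' the standard signal-to-noise score for enrichment assays.
#'
#' @param reads,peaks interval data frames (`chrom`, `start`, `end`,
#'   0-based half-open).
#' @return a number in \[0, 1\]; 0 when there are no peaks.
#' @export
frip <- function(reads, peaks) {
  reads_gr <- as_granges0(reads, "reads")
  if (!length(reads_gr)) stop_input("no reads supplied")
  if (!nrow(peaks)) return(0)
  peaks_gr <- as_granges0(peaks, "peaks")
  mean(IRanges::overlapsAny(reads_gr, peaks_gr))
}

#' Count peaks overlapping another peak set
#'
#' Number of intervals in `peaks_a` that overlap (>= 1 bp) at least one
#' interval in `peaks_b`. Touching half-open intervals do not overlap.
#'
#' @param peaks_a,peaks_b interval data frames (0-based half-open).
#' @return integer count.
#' @export
count_peak_overlaps <- function(peaks_a, peaks_b) {
  if (!nrow(peaks_a) || !nrow(peaks_b)) return(0L)
  a <- as_granges0(peaks_a, "peaks_a")
  b <- as_granges0(peaks_b, "peaks_b")
  sum(IRanges::overlapsAny(a, b))
}

# window selection shared by gene_signal and tss_profile
gene_window <- function(genes, window, flank) {
  tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
  if (window == "gene_body") {
    data.frame(chrom = genes$chrom, start = genes$start, end = genes$end)
  } else {
    data.frame(chrom = genes$chrom,
               start = pmax(0L, tss - flank),
               end = tss + flank)
  }
}

#' Per-gene coverage summaries
#'
#' Mean and median of normalized track bin values within each gene's window
#' (gene body, or a strand-aware window around the TSS: transcription starts
#' at `start` on the plus strand and at `end` on the minus strand).
#'
#' @param track a [coverage_track()], normalized (a warning is issued for
#'   raw tracks).
#' @param genes data frame `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open); an optional `zone` column is carried through.
#' @param window `"gene_body"` or `"tss_flank"`.
#' @param flank half-width in bp for `tss_flank` (default 1000).
#' @return data frame `gene_id` (+ `zone`), `mean_cpm`, `median_cpm`;
#'   genes with no covered bin get 0.
#' @export
gene_signal <- function(track, genes, window = c("gene_body", "tss_flank"),
                        flank = 1000) {
  window <- match.arg(window)
  if (!inherits(track, "coverage_track")) stop_input("`track` must be a coverage_track")
  if (!all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes))) {
    stop_input("`genes` needs gene_id, chrom, start, end, strand")
  }
  if (!identical(attr(track, "normalized"), "per10M")) {
    warning("track is not per-10M normalized; summaries are on the raw scale",
            call. = FALSE)
  }
  win <- gene_window(genes, window, flank)
  hits <- GenomicRanges::findOverlaps(as_granges0(win, "gene windows"),
                                      as_granges0(track, "track"))
  vals <- split(track$value[S4Vectors::subjectHits(hits)],
                factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(genes))))
  out <- data.frame(gene_id = genes$gene_id,
                    mean_cpm = vapply(vals, function(v) if (length(v)) mean(v) else 0,
                                      numeric(1)),
                    median_cpm = vapply(vals, function(v) if (length(v)) median(v) else 0,
                                        numeric(1)),
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  if ("zone" %in% names(genes)) out$zone <- genes$zone
  out
}

#' Coverage profile matrix around transcription start sites
#'
#' Builds the genes x bins matrix of mean track signal in fixed-width bins
#' across `tss - flank .. tss + flank`, the input for TSS profile heatmaps.
#' Minus-strand profiles are reversed so every row runs 5' to 3'. Row order
#' follows `genes`.
#'
#' @inheritParams gene_signal
#' @param flank half-width in bp; `2 * flank` must be divisible by the
#'   track's bin size.
#' @return numeric matrix, one row per gene (rownames `gene_id`), one column
#'   per bin; positions with no coverage are 0.
#' @export
tss_profile <- function(track, genes, flank = 2000) {
  if (!inherits(track, "coverage_track")) stop_input("`track` must be a coverage_track")
  bs <- attr(track, "bin_size")
  if (is.null(bs) || is.na(bs)) stop_input("track must have a uniform bin size")
  if ((2 * flank) %% bs != 0) {
    stop_input("2 * flank must be divisible by the track bin size (", bs, ")")
  }
  n_bins <- as.integer(2 * flank / bs)
  tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
  prof <- matrix(0, nrow(genes), n_bins,
                 dimnames = list(genes$gene_id, NULL))
  for (g in seq_len(nrow(genes))) {
    starts <- tss[g] - flank + (seq_len(n_bins) - 1L) * bs
    wins <- data.frame(chrom = genes$chrom[g], start = pmax(0L, starts),
                       end = starts + bs)
    keep <- wins$start < wins$end
    hits <- GenomicRanges::findOverlaps(as_granges0(wins[keep, ], "profile bins"),
                                        as_granges0(track, "track"))
    v <- vapply(split(track$value[S4Vectors::subjectHits(hits)],
                      factor(S4Vectors::queryHits(hits), levels = seq_len(sum(keep)))),
                function(x) if (length(x)) mean(x) else 0, numeric(1))
    prof[g, keep] <- v
    if (genes$strand[g] == "-") prof[g, ] <- rev(prof[g, ])
  }
  prof
}

#' Wilcoxon rank-sum comparison of two signal groups
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test, exact for small tie-free
#' samples and normal-approximated (with continuity and tie correction)
#' otherwise.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @return list with `statistic` (W) and `p_value`.
#' @export
compare_groups_wilcoxon <- function(values_a, values_b) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop_input("each group needs at least 2 values")
  }
  exact <- length(values_a) <= 50 && length(values_b) <= 50 &&
    !anyDuplicated(c(values_a, values_b))
  ht <- suppressWarnings(wilcox.test(values_a, values_b, exact = exact))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Zonal gradient statistic for per-gene signal
#'
#' Tests for a monotone dorsoventral trend: Spearman correlation between the
#' numeric zone index (z1 = 1 ... z5 = 5) and per-gene signal, with a
#' permutation p-value (two-sided). Class I and nonOR genes carry no zone
#' index and are dropped.
#'
#' @param summaries data frame with `zone` and `value` columns (e.g. from
#'   [sim_coverage_table()] or [gene_signal()] with `value = mean_cpm`).
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutations.
#' @return list with `rho`, `p_value`, `n`.
#' @export
zonal_gradient_stat <- function(summaries, n_perm = 1000, seed = 1) {
  if (!is.data.frame(summaries) || !all(c("zone", "value") %in% names(summaries))) {
    stop_input("`summaries` must contain `zone` and `value`")
  }
  zi <- match(summaries$zone, paste0("z", 1:5))
  keep <- !is.na(zi) & !is.na(summaries$value)
  zi <- zi[keep]
  v <- summaries$value[keep]
  if (length(unique(zi)) < 2) stop_input("need genes from at least two zones")
  rho <- cor(zi, v, method = "spearman")
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) cor(zi, sample(v), method = "spearman"),
           numeric(1))
  })
  list(rho = rho,
       p_value = (1 + sum(abs(perm) >= abs(rho))) / (n_perm + 1),
       n = length(v))
}

#' Split signal summaries by expression status
#'
#' Stratifies per-gene chromatin-signal summaries into transcriptionally
#' activated (`up`), repressed (`down`) and unchanged (`ns`) genes according
#' to a differential-expression table and significance thresholds.
#'
#' @param summaries data frame with `gene_id` and signal columns.
#' @param de DE table with `gene_id`, `log2fc` and `padj`.
#' @param alpha,lfc_min thresholds passed to [classify_significant()].
#' @return list of data frames named `down`, `ns`, `up` (empty strata are
#'   dropped); summary genes absent from `de` are excluded with a warning.
#' @export
stratify_activated_repressed <- function(summaries, de, alpha = 0.05,
                                         lfc_min = 0.58) {
  if (!"gene_id" %in% names(summaries)) stop_input("`summaries` needs a gene_id column")
  status <- classify_significant(de, alpha, lfc_min)
  idx <- match(summaries$gene_id, de$gene_id)
  if (anyNA(idx)) {
    warning(sprintf("%d gene(s) in summaries missing from the DE table were excluded",
                    sum(is.na(idx))), call. = FALSE)
  }
  keep <- !is.na(idx)
  summaries <- summaries[keep, , drop = FALSE]
  summaries$status <- as.character(status[idx[keep]])
  out <- split(summaries, summaries$status)
  out[intersect(c("down", "ns", "up"), names(out))]
}
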