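#' Attach zone annotation to a differential-expression table
#'
#' Left-joins a gene-to-zone table onto a DE table. Genes absent from the
#' zone table are labelled `nonOR`, with a single warning reporting how many.
#'
#' @param de data frame with at least a `gene_id` column (typically also
#'   `log2fc`, `pvalue`, `padj`).
#' @param zones zone table validated by [validate_zone_table()].
#' @return `de` with a `zone` column appended.
#' @export
assign_zones <- function(de, zones) {
  if (!is.data.frame(de) || !"gene_id" %in% names(de)) {
    stop_input("`de` must be a data frame with a `gene_id` column")
  }
  zones <- validate_zone_table(zones)
  if (!length(intersect(de$gene_id, zones$gene_id))) {
    stop_input("no genes shared between the DE table and the zone table")
  }
  idx <- match(de$gene_id, zones$gene_id)
  de$zone <- zones$zone[idx]
  n_missing <- sum(is.na(idx))
  if (n_missing > 0) {
    de$zone[is.na(idx)] <- "nonOR"
    warning(sprintf("%d gene(s) absent from the zone table were labelled nonOR",
                    n_missing), call. = FALSE)
  }
  de
}

#' Classify genes as up, down or not significant
#'
#' A gene is `down` when its adjusted p-value is below `alpha` and its log2
#' fold change below `-lfc_min`; `up` symmetrically; otherwise `ns`. Missing
#' p-values give `ns`. Setting `p_col = "pvalue"` with `alpha = 0.2` and
#' `lfc_min = 1` reproduces the raw-p interactor rule used for
#' co-immunoprecipitation proteomics screens.
#'
#' @param de data frame with `log2fc` and the chosen p-value column.
#' @param alpha p-value cutoff, in (0, 1). Default 0.05.
#' @param lfc_min minimum absolute log2 fold change, >= 0. Default 0.58
#'   (i.e. 1.5-fold).
#' @param p_col which p-value column to threshold (`"padj"` or `"pvalue"`).
#' @return factor with levels `down`, `ns`, `up`, one per row of `de`.
#' @examples
#' de <- data.frame(gene_id = c("a", "b"), log2fc = c(-0.6, 0),
#'                  padj = c(0.04, 0.04))
#' classify_significant(de)
#' @export
classify_significant <- function(de, alpha = 0.05, lfc_min = 0.58,
                                 p_col = c("padj", "pvalue")) {
  p_col <- match.arg(p_col)
  if (!is.data.frame(de) || !all(c("log2fc", p_col) %in% names(de))) {
    stop_input("`de` must contain columns `log2fc` and `", p_col, "`")
  }
  if (alpha <= 0 || alpha >= 1) stop_input("`alpha` must be in (0, 1)")
  if (lfc_min < 0) stop_input("`lfc_min` must be >= 0")
  p <- de[[p_col]]
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_input("p-values must lie in [0, 1]")
  lab <- rep("ns", nrow(de))
  sig <- !is.na(p) & p < alpha & !is.na(de$log2fc)
  lab[sig & de$log2fc < -lfc_min] <- "down"
  lab[sig & de$log2fc > lfc_min] <- "up"
  factor(lab, levels = c("down", "ns", "up"))
}

#' Per-gene log2 fold change, t-test p-values and BH adjustment
#'
#' A deliberately simple differential-expression estimator for simulated
#' counts: samples are library-size normalized (scaled to the mean depth, a
#' counts-per-million normalization up to a constant), a pseudocount is added,
#' and the per-gene log2 fold change is the log ratio of group means of
#' normalized counts (second factor level over first). P-values come from a
#' per-gene Welch t-test on log2 normalized counts; adjustment is
#' Benjamini-Hochberg.
#'
#' @param counts integer matrix, genes x samples.
#' @param group factor (or coercible) of length `ncol(counts)` with exactly
#'   two levels and at least two samples per level; the fold change is
#'   level 2 over level 1.
#' @param pseudocount added to normalized group means (and to normalized
#'   counts before the log t-test). Default 0.5.
#' @return data frame (`gene_id`, `log2fc`, `pvalue`, `padj`). Genes with
#'   zero variance in both groups get `NA` p-values.
#' @export
estimate_log2fc <- function(counts, group, pseudocount = 0.5) {
  if (!is.matrix(counts) || is.null(rownames(counts))) {
    stop_input("`counts` must be a matrix with gene ids as rownames")
  }
  group <- as.factor(group)
  if (nlevels(group) != 2 || length(group) != ncol(counts)) {
    stop_input("`group` must have exactly two levels, one entry per sample")
  }
  if (any(table(group) < 2)) stop_input("each group needs at least 2 samples")
  if (pseudocount <= 0) stop_input("`pseudocount` must be positive")

  libsize <- colSums(counts)
  if (any(libsize == 0)) stop_input("a sample has zero total counts")
  norm <- sweep(counts, 2, libsize / mean(libsize), "/")

  a <- group == levels(group)[1]
  b <- !a
  ma <- rowMeans(norm[, a, drop = FALSE])
  mb <- rowMeans(norm[, b, drop = FALSE])
  log2fc <- log2((mb + pseudocount) / (ma + pseudocount))

  ln <- log2(norm + pseudocount)
  na <- sum(a); nb <- sum(b)
  mean_a <- rowMeans(ln[, a, drop = FALSE])
  mean_b <- rowMeans(ln[, b, drop = FALSE])
  var_a <- rowSums((ln[, a, drop = FALSE] - mean_a)^2) / (na - 1)
  var_b <- rowSums((ln[, b, drop = FALSE] - mean_b)^2) / (nb - 1)
  se2 <- var_a / na + var_b / nb
  tt <- (mean_b - mean_a) / sqrt(se2)
  df <- se2^2 / ((var_a / na)^2 / (na - 1) + (var_b / nb)^2 / (nb - 1))
  pvalue <- 2 * pt(-abs(tt), df)
  pvalue[se2 == 0] <- NA_real_
  data.frame(gene_id = rownames(counts),
             log2fc = log2fc,
             pvalue = pvalue,
             padj = p.adjust(pvalue, method = "BH"),
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Test a gene group for a global expression shift
#'
#' One-sample t-test of a group's per-gene log2 fold changes against zero
#' (the default), asking whether the group as a whole is shifted. With a
#' `reference` vector (e.g. non-OR log2 fold changes), a Welch two-sample
#' t-test of group versus reference is performed instead.
#'
#' @param log2fc numeric vector of per-gene log2 fold changes (n >= 2,
#'   nonzero variance).
#' @param reference optional second vector for the two-sample form.
#' @param group label stored in the result.
#' @return object of class `group_shift`: list with `group`, `n`,
#'   `mean_log2fc`, `t_stat`, `df`, `p_value` and `type`.
#' @examples
#' group_shift_test(c(-0.5, -1.0, -1.5))
#' @export
group_shift_test <- function(log2fc, reference = NULL, group = "OR") {
  log2fc <- log2fc[!is.na(log2fc)]
  if (length(log2fc) < 2) stop_input("need at least 2 finite log2fc values")
  if (sd(log2fc) == 0) stop_input("zero variance in log2fc; t statistic undefined")
  ht <- if (is.null(reference)) {
    t.test(log2fc, mu = 0)
  } else {
    reference <- reference[!is.na(reference)]
    if (length(reference) < 2) stop_input("reference needs at least 2 values")
    t.test(log2fc, reference)
  }
  structure(list(group = group,
                 n = length(log2fc),
                 mean_log2fc = mean(log2fc),
                 t_stat = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value,
                 type = if (is.null(reference)) "one_sample" else "two_sample"),
            class = "group_shift")
}

#' @export
print.group_shift <- function(x, ...) {
  cat(sprintf("Group shift test (%s) for group '%s'\n", x$type, x$group))
  cat(sprintf("  n = %d, mean log2FC = %.4f\n", x$n, x$mean_log2fc))
  cat(sprintf("  t = %.4f (df = %.1f), p = %.4g\n", x$t_stat, x$df, x$p_value))
  invisible(x)
}

#' Zone-stratified summaries of log2 fold changes
#'
#' Computes per-zone boxplot statistics (n, mean, median, quartiles) of the
#' `log2fc` column of a zone-annotated DE table. Zones present in the level
#' set but without genes are reported with `n = 0` and `NA` summaries.
#'
#' @param de data frame with `log2fc` and `zone` columns (see
#'   [assign_zones()]).
#' @param zones which zone labels to report; defaults to the OR zones plus
#'   `nonOR`.
#' @return data frame with one row per zone.
#' @export
zone_stratified_summary <- function(de, zones = zone_levels(or_only = FALSE)) {
  if (!is.data.frame(de) || !all(c("log2fc", "zone") %in% names(de))) {
    stop_input("`de` must contain `log2fc` and `zone` columns")
  }
  out <- lapply(zones, function(z) {
    v <- de$log2fc[de$zone == z & !is.na(de$log2fc)]
    if (!length(v)) {
      data.frame(zone = z, n = 0L, mean = NA_real_, median = NA_real_,
                 q1 = NA_real_, q3 = NA_real_)
    } else {
      q <- unname(quantile(v, c(0.25, 0.5, 0.75)))
      data.frame(zone = z, n = length(v), mean = mean(v), median = q[2],
                 q1 = q[1], q3 = q[3])
    }
  })
  do.call(rbind, out)
}

#' Convert FPKM to TPM
#'
#' `tpm_i = fpkm_i / sum(fpkm) * 1e6`; the output always sums to one million.
#'
#' @param fpkm nonnegative numeric vector with positive sum.
#' @return TPM vector of the same length (names preserved).
#' @examples
#' fpkm_to_tpm(c(10, 30))
#' @export
fpkm_to_tpm <- function(fpkm) {
  if (!is.numeric(fpkm) || any(is.na(fpkm)) || any(fpkm < 0)) {
    stop_input("`fpkm` must be nonnegative and free of NA")
  }
  s <- sum(fpkm)
  if (s <= 0) stop_input("`fpkm` must have a positive sum")
  fpkm / s * 1e6
}

#' Compare positive-cell fractions between two conditions
#'
#' Two-sided test for a difference in the proportion of marker-positive cells
#' (e.g. the fraction of Mor28-positive neurons in control versus mutant
#' tissue), via `prop.test`.
#'
#' @param pos_a,n_a positives and total cells in condition A.
#' @param pos_b,n_b positives and total cells in condition B.
#' @return list with the two fractions, their difference (A - B) and the
#'   two-sided p-value.
#' @export
positive_cell_fraction_test <- function(pos_a, n_a, pos_b, n_b) {
  for (v in list(pos_a, n_a, pos_b, n_b)) {
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v != round(v)) {
      stop_input("all arguments must be single nonnegative integers")
    }
  }
  if (n_a == 0 || n_b == 0) stop_input("cell totals must be positive")
  if (pos_a > n_a || pos_b > n_b) stop_input("positives cannot exceed totals")
  ht <- suppressWarnings(prop.test(c(pos_a, pos_b), c(n_a, n_b)))
  list(fraction_a = pos_a / n_a,
       fraction_b = pos_b / n_b,
       difference = pos_a / n_a - pos_b / n_b,
       p_value = ht$p.value)
}
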