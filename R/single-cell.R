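#' Call the chosen OR of each cell
#'
#' A mature olfactory sensory neuron expresses a single dominant OR; the
#' chosen OR is called per cell as the OR gene with the highest count. Ties
#' at the maximum are resolved to the lexicographically first OR gene and
#' flagged `ambiguous`; cells with all-zero OR counts get no call.
#'
#' @param m cells x genes count matrix (rownames cell ids, colnames gene
#'   ids); base or sparse `Matrix`.
#' @param zones zone table; OR genes are those with zone other than `nonOR`.
#' @return data frame of class `chosen_or`: `cell_id`, `or_gene` (`NA` when
#'   no OR read), `zone`, `max_count`, `ambiguous`.
#' @export
call_chosen_or <- function(m, zones) {
  m <- validate_count_matrix(m)
  zones <- validate_zone_table(zones)
  or_genes <- sort(intersect(zones$gene_id[zones$zone != "nonOR"], colnames(m)))
  if (!length(or_genes)) stop_input("matrix contains no OR genes")
  or_m <- as.matrix(m[, or_genes, drop = FALSE])

  max_count <- apply(or_m, 1, max)
  pick <- apply(or_m, 1, which.max)  # first max = lexicographic (columns sorted)
  n_at_max <- rowSums(or_m == max_count)
  or_gene <- or_genes[pick]
  or_gene[max_count == 0] <- NA_character_
  zone <- zones$zone[match(or_gene, zones$gene_id)]
  out <- data.frame(cell_id = rownames(m),
                    or_gene = or_gene,
                    zone = zone,
                    max_count = as.numeric(max_count),
                    ambiguous = max_count > 0 & n_at_max >= 2,
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("chosen_or", "data.frame")
  out
}

#' Per-zone fractions of chosen-OR calls
#'
#' Summarizes chosen-OR calls into the fraction of called cells whose chosen
#' OR belongs to each zone (the stacked-bar statistic). Uncalled and
#' ambiguous cells are reported separately and excluded from the fractions.
#'
#' @param calls output of [call_chosen_or()].
#' @param drop_ambiguous exclude ambiguous calls from the fractions
#'   (default `FALSE`).
#' @return list with `fractions` (named vector over `zone_levels()`, summing
#'   to 1), `n_called`, `n_none`, `n_ambiguous`.
#' @export
zonal_choice_fractions <- function(calls, drop_ambiguous = FALSE) {
  if (!inherits(calls, "chosen_or")) stop_input("`calls` must come from call_chosen_or()")
  keep <- !is.na(calls$or_gene)
  if (drop_ambiguous) keep <- keep & !calls$ambiguous
  n_called <- sum(keep)
  if (n_called == 0) stop_input("no called cells to summarize")
  tab <- table(factor(calls$zone[keep], levels = ZONE_LEVELS))
  list(fractions = stats::setNames(as.numeric(tab) / n_called, ZONE_LEVELS),
       n_called = n_called,
       n_none = sum(is.na(calls$or_gene)),
       n_ambiguous = sum(calls$ambiguous, na.rm = TRUE))
}

#' Mask OR genes out of a count matrix
#'
#' Before classifying zonal identity, OR information is removed so the
#' classifier cannot simply read the chosen OR. `all_or` drops every OR gene
#' column (the stricter default, immune to leakage through non-chosen OR
#' counts); `chosen_only` zeroes only each cell's called OR, keeping the OR
#' columns.
#'
#' @param m cells x genes count matrix.
#' @param zones zone table identifying OR genes.
#' @param mode `"all_or"` or `"chosen_only"`.
#' @param calls chosen-OR calls (required for `chosen_only`; computed from
#'   `m` if omitted).
#' @return masked matrix with ids preserved.
#' @export
mask_or_genes <- function(m, zones, mode = c("all_or", "chosen_only"),
                          calls = NULL) {
  mode <- match.arg(mode)
  m <- validate_count_matrix(m)
  zones <- validate_zone_table(zones)
  or_genes <- intersect(zones$gene_id[zones$zone != "nonOR"], colnames(m))
  if (mode == "all_or") {
    return(m[, setdiff(colnames(m), or_genes), drop = FALSE])
  }
  if (is.null(calls)) calls <- call_chosen_or(m, zones)
  hit <- !is.na(calls$or_gene)
  m[cbind(match(calls$cell_id[hit], rownames(m)),
          match(calls$or_gene[hit], colnames(m)))] <- 0
  m
}

# log1p counts-per-10k feature transform shared by training and prediction
sc_features <- function(m) {
  m <- as.matrix(m)
  depth <- rowSums(m)
  depth[depth == 0] <- 1
  log1p(m / depth * 1e4)
}

#' Train a linear SVM for dorsal/ventral zonal identity
#'
#' Fits a linear support vector machine separating dorsal (Class I + zones
#' 1-3) from ventral (zones 4-5) cells on standardized log1p counts-per-10k
#' features. The matrix should already be OR-masked (see [mask_or_genes()]);
#' if `zones` is supplied, any remaining OR genes are dropped and reported,
#' so OR identity can never leak into the model.
#'
#' @param m cells x genes count matrix (OR-masked).
#' @param labels factor/character of `"dorsal"`/`"ventral"` per cell; both
#'   classes need >= 10 cells.
#' @param zones optional zone table used to audit and drop OR features.
#' @param cost SVM cost parameter C (default 1).
#' @param seed integer seed (stored; the linear fit itself is deterministic).
#' @return object of class `identity_model`: the fitted SVM plus feature
#'   names and per-gene centring/scaling parameters.
#' @export
train_identity_svm <- function(m, labels, zones = NULL, cost = 1, seed = 1) {
  m <- validate_count_matrix(m)
  labels <- factor(as.character(labels), levels = c("dorsal", "ventral"))
  if (length(labels) != nrow(m)) stop_input("one label per cell required")
  if (any(is.na(labels))) stop_input("labels must be 'dorsal' or 'ventral'")
  if (nlevels(droplevels(labels)) < 2) stop_input("both classes must be present")
  if (any(table(labels) < 10)) stop_input("each class needs at least 10 cells")
  if (!is.null(zones)) {
    zones <- validate_zone_table(zones)
    or_genes <- intersect(zones$gene_id[zones$zone != "nonOR"], colnames(m))
    if (length(or_genes)) {
      warning(sprintf("dropping %d OR gene(s) still present in the feature matrix",
                      length(or_genes)), call. = FALSE)
      m <- m[, setdiff(colnames(m), or_genes), drop = FALSE]
    }
  }
  x <- sc_features(m)
  center <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  keep <- scale_ > 0
  if (!any(keep)) stop_input("no informative features (all genes constant)")
  x <- scale(x[, keep, drop = FALSE], center[keep], scale_[keep])
  fit <- with_seed(seed, e1071::svm(x, labels, kernel = "linear", cost = cost,
                                    scale = FALSE))
  structure(list(svm = fit,
                 features = colnames(x),
                 center = center[keep],
                 scale = scale_[keep],
                 classes = levels(labels),
                 cost = cost,
                 seed = seed),
            class = "identity_model")
}

#' @export
print.identity_model <- function(x, ...) {
  cat(sprintf("Linear SVM zonal-identity model: %d features, C = %g\n",
              length(x$features), x$cost))
  cat(sprintf("  classes: %s\n", paste(x$classes, collapse = " vs ")))
  invisible(x)
}

#' Feature weights of a zonal-identity model
#'
#' @param object an `identity_model`.
#' @param ... unused.
#' @return named numeric vector of linear weights (one per feature gene).
#' @export
coef.identity_model <- function(object, ...) {
  w <- crossprod(object$svm$coefs, object$svm$SV)
  stats::setNames(as.numeric(w), colnames(object$svm$SV))
}

#' Predict dorsal/ventral identity for new cells
#'
#' Applies a trained [train_identity_svm()] model. Genes absent from the new
#' matrix are treated as zero counts (then centred/scaled with the training
#' parameters).
#'
#' @param object an `identity_model`.
#' @param m cells x genes count matrix (same masking as in training).
#' @param ... unused.
#' @return data frame `cell_id`, `predicted` (factor dorsal/ventral),
#'   `margin` (signed decision value).
#' @export
predict.identity_model <- function(object, m, ...) {
  m <- validate_count_matrix(m)
  x <- sc_features(m)
  miss <- setdiff(object$features, colnames(x))
  if (length(miss)) {
    x <- cbind(x, matrix(0, nrow(x), length(miss),
                         dimnames = list(rownames(x), miss)))
  }
  x <- scale(x[, object$features, drop = FALSE], object$center, object$scale)
  pred <- stats::predict(object$svm, x, decision.values = TRUE)
  data.frame(cell_id = rownames(m),
             predicted = factor(as.character(pred), levels = object$classes),
             margin = as.numeric(attr(pred, "decision.values")),
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' @rdname predict.identity_model
#' @param model an `identity_model`.
#' @export
predict_identity <- function(model, m) predict(model, m)

#' Cross-validated accuracy of the zonal-identity SVM
#'
#' Stratified k-fold cross-validation of [train_identity_svm()] on a masked
#' matrix; folds are drawn with the given seed, so results are reproducible.
#'
#' @inheritParams train_identity_svm
#' @param folds number of folds (default 5).
#' @return mean held-out accuracy across folds.
#' @export
cv_identity_accuracy <- function(m, labels, folds = 5, cost = 1, seed = 1) {
  m <- validate_count_matrix(m)
  labels <- factor(as.character(labels), levels = c("dorsal", "ventral"))
  fold_id <- with_seed(seed, {
    id <- integer(length(labels))
    for (cl in levels(labels)) {
      i <- which(labels == cl)
      id[i] <- sample(rep_len(seq_len(folds), length(i)))
    }
    id
  })
  acc <- vapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    fit <- train_identity_svm(m[tr, , drop = FALSE], labels[tr],
                              cost = cost, seed = seed)
    pr <- predict(fit, m[!tr, , drop = FALSE])
    mean(pr$predicted == labels[!tr])
  }, numeric(1))
  mean(acc)
}

#' Cross-tabulate experimental versus predicted zonal identity
#'
#' Builds the 2x2 table of experimentally assigned identity (from the chosen
#' OR's zone) against SVM-predicted identity. Row sums equal the experimental
#' class counts by construction.
#'
#' @param experimental factor/character dorsal/ventral per cell (e.g.
#'   `zone_to_dv(calls$zone)`).
#' @param predictions prediction table from [predict_identity()], or a
#'   factor of predicted classes.
#' @return 2x2 contingency table (experimental rows, predicted columns).
#' @export
identity_shift_table <- function(experimental, predictions) {
  pred <- if (is.data.frame(predictions)) predictions$predicted else predictions
  experimental <- factor(as.character(experimental), levels = c("dorsal", "ventral"))
  pred <- factor(as.character(pred), levels = c("dorsal", "ventral"))
  if (length(experimental) != length(pred)) {
    stop_input("experimental labels and predictions must have the same length")
  }
  table(experimental = experimental, predicted = pred)
}

#' Rank zonal marker genes
#'
#' Welch t-statistics on log1p counts-per-10k between dorsal and ventral
#' cells, with Benjamini-Hochberg control; returns the `k` genes with the
#' strongest separation (the matrix should be OR-masked first).
#'
#' @param m cells x genes count matrix.
#' @param labels dorsal/ventral label per cell.
#' @param k number of top genes to return; values above the gene count rank
#'   every gene.
#' @return data frame `gene_id`, `t_stat`, `pvalue`, `padj`, ordered by
#'   decreasing |t|.
#' @export
select_zonal_markers <- function(m, labels, k = 50) {
  m <- validate_count_matrix(m)
  labels <- factor(as.character(labels), levels = c("dorsal", "ventral"))
  if (nlevels(droplevels(labels)) < 2) stop_input("both classes must be present")
  k <- min(check_count(k, "k"), ncol(m))
  x <- sc_features(m)
  a <- labels == "dorsal"
  na <- sum(a); nb <- sum(!a)
  if (na < 2 || nb < 2) stop_input("each class needs at least 2 cells")
  ma <- colMeans(x[a, , drop = FALSE])
  mb <- colMeans(x[!a, , drop = FALSE])
  va <- apply(x[a, , drop = FALSE], 2, var)
  vb <- apply(x[!a, , drop = FALSE], 2, var)
  se2 <- va / na + vb / nb
  tt <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(tt), df)
  p[se2 == 0] <- NA_real_
  out <- data.frame(gene_id = colnames(m),
                    t_stat = tt,
                    pvalue = p,
                    padj = p.adjust(p, "BH"),
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$t_stat)), ]
  head(out, k)
}

#' Count co-expressed ORs per cell
#'
#' Tallies, per cell, how many OR genes reach at least `min_count` reads —
#' a monoallelic-expression diagnostic (nearly all mature cells should tally
#' one at a stringent threshold).
#'
#' @param m cells x genes count matrix.
#' @param zones zone table identifying OR genes.
#' @param min_count minimum count for an OR to be scored as expressed;
#'   `min_count = 0` degenerately counts every OR gene and warns.
#' @return list with `tally` (integer per cell) and `histogram` (table of
#'   tally values).
#' @export
coexpression_tally <- function(m, zones, min_count = 5) {
  m <- validate_count_matrix(m)
  zones <- validate_zone_table(zones)
  if (min_count < 0) stop_input("`min_count` must be >= 0")
  if (min_count == 0) {
    warning("min_count = 0 counts every OR gene in every cell", call. = FALSE)
  }
  or_genes <- intersect(zones$gene_id[zones$zone != "nonOR"], colnames(m))
  if (!length(or_genes)) stop_input("matrix contains no OR genes")
  or_m <- as.matrix(m[, or_genes, drop = FALSE])
  tally <- as.integer(rowSums(or_m >= min_count))
  names(tally) <- rownames(m)
  list(tally = tally, histogram = table(tally))
}
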