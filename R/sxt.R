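# 3D chromatin partitioning of soft X-ray tomograms. The linear absorption
# coefficient (LAC) is a density proxy: compact heterochromatin absorbs more,
# so the higher-mean mixture component is heterochromatin.

check_volume <- function(x, name, logical = FALSE) {
  if (!is.array(x) || length(dim(x)) != 3) stop_input("`", name, "` must be a 3D array")
  if (any(dim(x) < 8)) stop_input("`", name, "` must be at least 8 voxels per axis")
  if (logical && !is.logical(x)) stop_input("`", name, "` must be logical")
  if (!logical && !all(is.finite(x))) stop_input("`", name, "` must be finite")
  x
}

#' Separable 3D Gaussian smoothing
#'
#' Convolves a 3D array with an isotropic Gaussian kernel (truncated at
#' 3 sigma), axis by axis, with zero padding beyond the array edges (values
#' within a kernel radius of an edge are attenuated; the partition code
#' compensates by normalizing against a smoothed mask). Used to smooth
#' posterior-probability volumes.
#'
#' @param arr 3D numeric array.
#' @param sigma kernel SD in voxels.
#' @return smoothed array of the same shape.
#' @export
gaussian_smooth3d <- function(arr, sigma) {
  check_volume(arr, "arr")
  check_positive(sigma, "sigma")
  r <- max(1L, ceiling(3 * sigma))
  w <- dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  d <- dim(arr)
  kmat <- function(n) {
    K <- matrix(0, n, n)
    for (o in -r:r) {
      i <- seq_len(n)
      j <- i + o
      ok <- j >= 1 & j <= n
      K[cbind(i[ok], j[ok])] <- w[o + r + 1]
    }
    K
  }
  x <- matrix(kmat(d[1]) %*% matrix(arr, d[1], d[2] * d[3]), d[1], d[2] * d[3])
  arr <- array(x, d)
  arr <- aperm(arr, c(2, 1, 3))
  x <- matrix(kmat(d[2]) %*% matrix(arr, d[2], d[1] * d[3]), d[2], d[1] * d[3])
  arr <- aperm(array(x, d[c(2, 1, 3)]), c(2, 1, 3))
  x <- matrix(arr, d[1] * d[2], d[3]) %*% t(kmat(d[3]))
  array(x, d)
}

#' Partition a nucleus into eu- and heterochromatin
#'
#' The tomogram's LAC values inside the nucleus mask are divided by their
#' within-mask mean, a two-component Gaussian mixture is fit, the
#' heterochromatin (higher-mean component) posterior is mapped back into the
#' volume, Gaussian-smoothed with support restricted to the mask (normalized
#' convolution, so voxels outside the nucleus never dilute the posterior),
#' and thresholded at 0.5.
#'
#' @param tomogram 3D numeric array of LAC values.
#' @param mask logical 3D nucleus mask of the same shape with >= 100 voxels.
#' @param sigma posterior smoothing SD in voxels (default 1.5).
#' @param seed integer seed for the mixture initialization subset.
#' @param normalize `"mean"` (divide by within-mask mean, the default) or
#'   `"zscore"`.
#' @return object of class `chromatin_partition`: `het` (logical array,
#'   smoothed-posterior > 0.5 within the mask), `posterior` and
#'   `smoothed_posterior` arrays, mixture `means`/`sds`/`weights` (eu, het),
#'   `fractions` (percent of nuclear volume) and bookkeeping fields.
#' @export
fit_gmm_partition <- function(tomogram, mask, sigma = 1.5, seed = 1,
                              normalize = c("mean", "zscore")) {
  normalize <- match.arg(normalize)
  check_volume(tomogram, "tomogram")
  check_volume(mask, "mask", logical = TRUE)
  if (!identical(dim(tomogram), dim(mask))) stop_input("tomogram and mask shapes differ")
  n_vox <- sum(mask)
  if (n_vox < 100) stop_input("mask must contain at least 100 voxels")
  vals <- tomogram[mask]
  if (var(vals) < 1e-12 * mean(vals)^2) {
    stop_input("LAC is (near-)constant within the mask; mixture fit is degenerate")
  }
  x <- if (normalize == "mean") vals / mean(vals) else (vals - mean(vals)) / sd(vals)

  uq <- unique(x)
  if (length(uq) == 2) {
    # noiseless two-valued volume: the mixture solution is exact
    hi <- max(uq)
    p_het <- as.numeric(x == hi)
    means <- sort(uq)
    sds <- c(0, 0)
    weights <- c(mean(x != hi), mean(x == hi))
  } else {
    sub <- with_seed(seed, sample.int(length(x), min(2000L, length(x))))
    fit <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE,
                          initialization = list(subset = sub))
    if (is.null(fit)) stop_input("Gaussian mixture fit failed")
    mu <- fit$parameters$mean
    if (abs(diff(mu)) < 1e-12) stop_input("mixture components have equal means")
    het_comp <- which.max(mu)
    p_het <- fit$z[, het_comp]
    ord <- order(mu)
    means <- mu[ord]
    sds <- sqrt(fit$parameters$variance$sigmasq)[ord]
    weights <- fit$parameters$pro[ord]
  }

  post <- array(0, dim(tomogram))
  post[mask] <- p_het
  mnum <- array(0, dim(tomogram))
  mnum[mask] <- 1
  sm_num <- gaussian_smooth3d(post, sigma)
  sm_den <- gaussian_smooth3d(mnum, sigma)
  smoothed <- array(0, dim(tomogram))
  smoothed[mask] <- sm_num[mask] / sm_den[mask]

  het <- smoothed > 0.5 & mask
  het_pct <- 100 * sum(het) / n_vox
  structure(list(het = het,
                 mask = mask,
                 posterior = post,
                 smoothed_posterior = smoothed,
                 means = unname(means),
                 sds = unname(sds),
                 weights = unname(weights),
                 fractions = c(eu = 100 - het_pct, het = het_pct),
                 sigma = sigma,
                 normalize = normalize,
                 n_voxels = n_vox),
            class = "chromatin_partition")
}

#' @export
print.chromatin_partition <- function(x, ...) {
  cat(sprintf("Chromatin partition of %d nuclear voxels\n", x$n_voxels))
  cat(sprintf("  euchromatin %.1f%%, heterochromatin %.1f%% of nuclear volume\n",
              x$fractions["eu"], x$fractions["het"]))
  cat(sprintf("  mixture means (normalized LAC): eu %.3f, het %.3f\n",
              x$means[1], x$means[2]))
  invisible(x)
}

#' Eu-/heterochromatin volume fractions
#'
#' @param partition a [fit_gmm_partition()] result.
#' @return named vector `c(eu, het)` in percent of nuclear volume (sums
#'   to 100).
#' @export
chromatin_fractions <- function(partition) {
  if (!inherits(partition, "chromatin_partition")) {
    stop_input("`partition` must come from fit_gmm_partition()")
  }
  partition$fractions
}

#' Maturity gate on heterochromatin content
#'
#' A nucleus is scored as a mature olfactory sensory neuron when its
#' heterochromatin exceeds 37\% of the nuclear volume (strict inequality).
#'
#' @param x a `chromatin_partition` or a numeric heterochromatin fraction
#'   in \[0, 1\].
#' @param threshold gate value as a fraction (default 0.37).
#' @return logical.
#' @export
gate_mature <- function(x, threshold = 0.37) {
  frac <- if (inherits(x, "chromatin_partition")) {
    unname(x$fractions["het"]) / 100
  } else if (is.numeric(x)) {
    x
  } else {
    stop_input("`x` must be a chromatin_partition or numeric fraction(s)")
  }
  if (any(frac < 0 | frac > 1)) stop_input("fractions must lie in [0, 1]")
  frac > threshold
}

#' Local thickness of a binary 3D mask
#'
#' Largest-inscribed-sphere thickness: the value at a voxel is the diameter
#' (in voxels) of the largest sphere fully inside the mask that contains it,
#' computed by sphere painting on the exact Euclidean distance transform.
#'
#' @param mask logical 3D array.
#' @return numeric array of thickness values (0 outside the mask).
#' @export
local_thickness <- function(mask) {
  check_volume(mask, "mask", logical = TRUE)
  if (!any(mask)) stop_input("mask is empty")
  edt <- cpp_edt3d(as.integer(mask), dim(mask))
  array(cpp_local_thickness(edt, dim(mask)), dim(mask))
}

#' Local thickness of peripheral heterochromatin at the nuclear border
#'
#' Computes the local thickness of the heterochromatin mask and returns the
#' values of heterochromatin voxels lying in a thin border region (by
#' default the two voxel layers just inside the nuclear envelope). These
#' values characterize the peripheral heterochromatin shell and calibrate
#' the watershed seeds.
#'
#' @param het logical 3D heterochromatin mask.
#' @param nucleus_mask logical 3D nucleus mask (same shape); ignored when
#'   `envelope_border` is given.
#' @param envelope_border optional explicit logical border-region mask.
#' @param border_width border thickness in voxels (default 2).
#' @return list with `values` (thickness of border het voxels), `thickness`
#'   (full thickness array) and `border` (the border mask used).
#' @export
border_local_thickness <- function(het, nucleus_mask = NULL,
                                   envelope_border = NULL, border_width = 2) {
  check_volume(het, "het", logical = TRUE)
  if (!any(het)) stop_input("heterochromatin mask is empty")
  if (is.null(envelope_border)) {
    if (is.null(nucleus_mask)) stop_input("supply `nucleus_mask` or `envelope_border`")
    check_volume(nucleus_mask, "nucleus_mask", logical = TRUE)
    dist_env <- array(cpp_edt3d(as.integer(nucleus_mask), dim(nucleus_mask)),
                      dim(nucleus_mask))
    envelope_border <- nucleus_mask & dist_env <= border_width
  }
  th <- local_thickness(het)
  sel <- het & envelope_border
  if (!any(sel)) stop_input("no heterochromatin voxels in the border region")
  list(values = th[sel], thickness = th, border = envelope_border)
}

#' Watershed seeds for the inner/outer heterochromatin split
#'
#' Outer seed: heterochromatin voxels whose distance to the nuclear envelope
#' is at most the 50th percentile of the border local thickness. Inner seed:
#' voxels farther than the 90th percentile. Inner-seed connected components
#' (26-connectivity) smaller than `min_region_frac` of the largest are
#' removed.
#'
#' @param het logical heterochromatin mask.
#' @param dist_to_envelope numeric array of distances from each voxel centre
#'   to the nuclear envelope surface. The envelope surface lies half a voxel
#'   beyond the outermost nuclear voxel centre, so this is the nucleus-mask
#'   EDT minus 0.5 — the convention that makes envelope depths directly
#'   comparable to inscribed-sphere thickness values.
#' @param thickness_values border local thickness sample (from
#'   [border_local_thickness()]).
#' @param min_region_frac small-region removal threshold (default 0.01).
#' @return list with logical arrays `outer` and `inner` and the two distance
#'   cutoffs; an empty seed after filtering is an error.
#' @export
make_watershed_seeds <- function(het, dist_to_envelope, thickness_values,
                                 min_region_frac = 0.01) {
  check_volume(het, "het", logical = TRUE)
  if (!identical(dim(het), dim(dist_to_envelope))) {
    stop_input("het and dist_to_envelope shapes differ")
  }
  if (!length(thickness_values)) stop_input("no thickness values supplied")
  p50 <- unname(quantile(thickness_values, 0.5))
  p90 <- unname(quantile(thickness_values, 0.9))
  outer <- het & dist_to_envelope <= p50
  inner <- het & dist_to_envelope > p90
  if (any(inner)) {
    lab <- array(cpp_label_components(as.integer(inner), dim(het)), dim(het))
    sizes <- tabulate(lab[inner])
    drop <- which(sizes < min_region_frac * max(sizes))
    if (length(drop)) inner[lab %in% drop] <- FALSE
  }
  if (!any(outer)) {
    stop_input("outer seed is empty (no het voxels within the P50 thickness ",
               "of the envelope)")
  }
  if (!any(inner)) {
    stop_input("inner seed is empty after filtering: heterochromatin has no ",
               "interior deeper than the P90 border thickness (", round(p90, 2),
               " voxels)")
  }
  list(outer = outer, inner = inner, p50 = p50, p90 = p90)
}

#' Watershed split of heterochromatin into inner and outer compartments
#'
#' Marker-based watershed on the Euclidean distance transform of the
#' heterochromatin mask: the inner and outer seeds flood the mask in order
#' of decreasing distance to the euchromatin boundary, assigning every
#' heterochromatin voxel to exactly one compartment.
#'
#' @param het logical heterochromatin mask.
#' @param seeds seed list from [make_watershed_seeds()].
#' @return object of class `compartment_labels`: `labels` (integer array,
#'   0 background / 1 outer / 2 inner), voxel `counts` and percent of
#'   heterochromatin per compartment.
#' @export
split_inner_outer <- function(het, seeds) {
  check_volume(het, "het", logical = TRUE)
  if (!is.list(seeds) || !all(c("outer", "inner") %in% names(seeds))) {
    stop_input("`seeds` must come from make_watershed_seeds()")
  }
  seed_lab <- array(0L, dim(het))
  seed_lab[seeds$outer] <- 1L
  seed_lab[seeds$inner] <- 2L
  edt <- cpp_edt3d(as.integer(het), dim(het))
  lab <- array(cpp_watershed(edt, as.integer(het), as.integer(seed_lab), dim(het)),
               dim(het))
  orphan <- het & lab == 0L
  if (any(orphan)) {
    # het components unreachable from any seed (e.g. isolated fragments):
    # assign to the compartment with the nearest labelled voxel
    d_outer <- cpp_edt3d(as.integer(lab != 1L), dim(het))
    d_inner <- cpp_edt3d(as.integer(lab != 2L), dim(het))
    lab[orphan] <- ifelse(d_outer[orphan] <= d_inner[orphan], 1L, 2L)
  }
  counts <- c(outer = sum(lab == 1L), inner = sum(lab == 2L))
  if (sum(counts) != sum(het)) {
    stop_input("watershed failed to label every heterochromatin voxel")
  }
  structure(list(labels = lab,
                 counts = counts,
                 percent_of_het = 100 * counts / sum(het)),
            class = "compartment_labels")
}

#' @export
print.compartment_labels <- function(x, ...) {
  cat(sprintf("Heterochromatin compartments: outer %d voxels (%.1f%%), inner %d voxels (%.1f%%)\n",
              x$counts["outer"], x$percent_of_het["outer"],
              x$counts["inner"], x$percent_of_het["inner"]))
  invisible(x)
}

#' Full inner/outer heterochromatin pipeline
#'
#' Convenience wrapper chaining [border_local_thickness()],
#' [make_watershed_seeds()] and [split_inner_outer()] for a heterochromatin
#' mask inside a nucleus mask.
#'
#' @inheritParams border_local_thickness
#' @inheritParams make_watershed_seeds
#' @return a `compartment_labels` object with the seeds attached as
#'   attribute `seeds`.
#' @export
sxt_inner_outer <- function(het, nucleus_mask, border_width = 2,
                            min_region_frac = 0.01) {
  blt <- border_local_thickness(het, nucleus_mask, border_width = border_width)
  dist_env <- array(cpp_edt3d(as.integer(nucleus_mask), dim(nucleus_mask)),
                    dim(nucleus_mask)) - 0.5
  seeds <- make_watershed_seeds(het, dist_env, blt$values, min_region_frac)
  out <- split_inner_outer(het, seeds)
  attr(out, "seeds") <- seeds
  out
}
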