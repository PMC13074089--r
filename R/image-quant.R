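# 2D fluorescence quantification. Images are matrices with rows indexing y
# (pixel centres at integer coordinates); focus ROIs are circles (x, y, r).

check_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image)) stop_input("`image` must be a numeric matrix")
  image
}

#' Radial intensity profiles around circular foci
#'
#' For each focus, pixel intensities are averaged in `n_bins` equal bins of
#' normalized radius `r/R` from 0 to `max_radius_factor` (so bin 1 is the
#' focus core and the bin at `r/R = 1` sits on the focus boundary). A focus
#' whose `max_radius_factor * R` disk leaves the image is reported as a
#' per-focus error while the remaining foci proceed.
#'
#' @param image numeric matrix.
#' @param foci data frame with `x`, `y`, `r`.
#' @param max_radius_factor outer edge of the profile in units of the focus
#'   radius (default 1.5).
#' @param n_bins number of radial bins (default 15).
#' @return object of class `radial_profile`: `profiles` (foci x bins matrix,
#'   `NA` rows for failed foci), `bin_mid` (normalized-radius bin centres),
#'   `mean_profile` (across valid foci) and `errors` (per-focus messages).
#' @export
radial_profile <- function(image, foci, max_radius_factor = 1.5, n_bins = 15) {
  check_image(image)
  if (!is.data.frame(foci) || !all(c("x", "y", "r") %in% names(foci))) {
    stop_input("`foci` must have columns x, y, r")
  }
  if (any(foci$r <= 0)) stop_input("focus radii must be positive")
  check_positive(max_radius_factor, "max_radius_factor")
  n_bins <- check_count(n_bins, "n_bins")
  h <- nrow(image); w <- ncol(image)
  bw <- max_radius_factor / n_bins
  profiles <- matrix(NA_real_, nrow(foci), n_bins)
  errors <- character(nrow(foci))
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  ys <- matrix(seq_len(h), h, w)
  for (i in seq_len(nrow(foci))) {
    R <- foci$r[i]; x0 <- foci$x[i]; y0 <- foci$y[i]
    outer_r <- max_radius_factor * R
    if (x0 - outer_r < 1 || x0 + outer_r > w || y0 - outer_r < 1 || y0 + outer_r > h) {
      errors[i] <- "focus too near the image edge for the requested outer radius"
      next
    }
    rn <- sqrt((xs - x0)^2 + (ys - y0)^2) / R
    bin <- floor(rn / bw) + 1L
    sel <- bin >= 1L & bin <= n_bins
    sums <- tabulate(bin[sel], n_bins)
    profiles[i, ] <- vapply(seq_len(n_bins), function(b) {
      v <- image[sel & bin == b]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
  }
  ok <- errors == ""
  if (!any(ok)) stop_input("no focus could be profiled: ", errors[which(!ok)[1]])
  structure(list(profiles = profiles,
                 bin_mid = (seq_len(n_bins) - 0.5) * bw,
                 mean_profile = colMeans(profiles[ok, , drop = FALSE]),
                 errors = errors),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("Radial profiles for %d focus/foci (%d bins to r/R = %.2f)\n",
              nrow(x$profiles), length(x$bin_mid), max(x$bin_mid) + diff(x$bin_mid[1:2]) / 2))
  n_err <- sum(x$errors != "")
  if (n_err) cat(sprintf("  %d focus/foci failed\n", n_err))
  invisible(x)
}

#' Peripheral enrichment index of a radial profile
#'
#' Mean intensity in the periphery (`r/R` in \[0.8, 1.2\]) divided by the
#' mean in the core (`r/R` in \[0, 0.5\]). Values above 1 indicate a
#' periphery-enriched (ring-like) signal around the focus.
#'
#' @param profile a `radial_profile` object or a numeric profile vector.
#' @param bin_mid normalized-radius bin centres (taken from the object when
#'   a `radial_profile` is given).
#' @return numeric index (one per focus for a `radial_profile` object,
#'   plus attribute `mean_index`).
#' @export
peripheral_enrichment_index <- function(profile, bin_mid = NULL) {
  if (inherits(profile, "radial_profile")) {
    bin_mid <- profile$bin_mid
    mat <- profile$profiles
  } else {
    if (is.null(bin_mid)) stop_input("`bin_mid` required for a plain profile vector")
    mat <- matrix(profile, nrow = 1)
  }
  core <- bin_mid <= 0.5
  peri <- bin_mid >= 0.8 & bin_mid <= 1.2
  if (!any(core) || !any(peri)) stop_input("profile bins do not cover the core and periphery windows")
  idx <- apply(mat, 1, function(p) {
    den <- mean(p[core], na.rm = TRUE)
    if (!is.finite(den) || den == 0) stop_input("core intensity is zero; index undefined")
    mean(p[peri], na.rm = TRUE) / den
  })
  attr(idx, "mean_index") <- mean(idx, na.rm = TRUE)
  idx
}

#' Fisher Z comparison of two correlations
#'
#' Tests whether two independent Pearson correlations differ:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-sided normal p-value.
#'
#' @param r1,r2 sample correlations, strictly inside (-1, 1).
#' @param n1,n2 sample sizes, each > 3.
#' @return list with `z` and `p_value`.
#' @examples
#' fisher_z_compare(0.5, 50, 0.2, 50)
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop_input("correlations must lie strictly in (-1, 1)")
  if (n1 <= 3 || n2 <= 3) stop_input("sample sizes must exceed 3")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p_value = 2 * pnorm(-abs(z)))
}

#' Intensity profile along a polyline
#'
#' Samples gray values by bilinear interpolation at fixed steps along a
#' polyline (e.g. a basal-to-apical line through the epithelium). The number
#' of samples is `ceiling(length / step)`.
#'
#' @param image numeric matrix.
#' @param polyline data frame with `x`, `y` vertices (>= 2 rows); the whole
#'   line must lie inside the image.
#' @param step sampling step in pixels (default 1).
#' @return data frame `distance`, `value`, classed `line_profile`.
#' @export
line_intensity_profile <- function(image, polyline, step = 1) {
  check_image(image)
  if (!is.data.frame(polyline) || !all(c("x", "y") %in% names(polyline)) ||
      nrow(polyline) < 2) {
    stop_input("`polyline` must have columns x, y and at least 2 vertices")
  }
  check_positive(step, "step")
  h <- nrow(image); w <- ncol(image)
  if (any(polyline$x < 1 | polyline$x > w | polyline$y < 1 | polyline$y > h)) {
    stop_input("polyline lies (partly) outside the image")
  }
  seg <- sqrt(diff(polyline$x)^2 + diff(polyline$y)^2)
  total <- sum(seg)
  if (total == 0) stop_input("polyline has zero length")
  n <- ceiling(total / step)
  dists <- (seq_len(n) - 1) * step
  cum <- c(0, cumsum(seg))
  pts <- t(vapply(dists, function(d) {
    s <- max(which(cum <= d + 1e-9))
    s <- min(s, length(seg))
    f <- (d - cum[s]) / seg[s]
    c(polyline$x[s] + f * (polyline$x[s + 1] - polyline$x[s]),
      polyline$y[s] + f * (polyline$y[s + 1] - polyline$y[s]))
  }, numeric(2)))
  val <- vapply(seq_len(n), function(i) {
    x <- pts[i, 1]; y <- pts[i, 2]
    x0 <- floor(x); y0 <- floor(y)
    x1 <- min(x0 + 1, w); y1 <- min(y0 + 1, h)
    fx <- x - x0; fy <- y - y0
    image[y0, x0] * (1 - fx) * (1 - fy) + image[y0, x1] * fx * (1 - fy) +
      image[y1, x0] * (1 - fx) * fy + image[y1, x1] * fx * fy
  }, numeric(1))
  out <- data.frame(distance = dists, value = val)
  class(out) <- c("line_profile", "data.frame")
  out
}
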