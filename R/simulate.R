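#' Simulate bulk RNA-seq counts with a planted OR-group shift
#'
#' Generates a gene-by-sample negative-binomial count table emulating bulk
#' RNA-seq of olfactory epithelium from a control and a perturbed genotype.
#' OR genes are annotated into the five dorsoventral zones plus Class I, and
#' their expected counts in the perturbed group are scaled by a planted log2
#' fold change, either globally (`or_group_log2fc`) or per zone
#' (`per_zone_log2fc`). Non-OR genes are unperturbed. A truth table recording
#' every planted per-gene effect is returned alongside the counts, so
#' downstream estimators can be scored against known ground truth.
#'
#' OR genes are simulated at a lower baseline than non-OR genes: in whole
#' epithelium each OR is expressed in only the small subset of neurons that
#' chose it, so its bulk abundance is well below that of a typical gene.
#'
#' @param n_or_genes number of OR genes (the study's annotation has 1194).
#' @param n_nonor_genes number of non-OR genes (20988 in the study).
#' @param n_replicates_per_group biological replicates per genotype (>= 2).
#' @param baseline_mean expected control-group count of an average OR gene.
#' @param nonor_baseline_mean expected count of an average non-OR gene.
#' @param dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); must be > 0.
#' @param or_group_log2fc planted mean log2 fold change applied to all OR
#'   genes in the perturbed group.
#' @param per_zone_log2fc optional named numeric vector (names in
#'   `zone_levels()`) overriding `or_group_log2fc` for specific zones.
#' @param baseline_sdlog gene-level spread (SD of log baseline) around the
#'   class baseline means.
#' @param seed required integer seed; fixed seed gives identical output.
#' @return list of class `bulk_sim` with elements `counts` (integer matrix,
#'   genes x samples), `group` (factor `control`/`perturbed` per sample),
#'   `zones` (gene-to-zone table), and `truth` (per-gene planted log2fc).
#' @examples
#' sim <- sim_bulk_counts(n_or_genes = 60, n_nonor_genes = 200,
#'                        or_group_log2fc = -1, seed = 1)
#' head(sim$truth)
#' @export
sim_bulk_counts <- function(n_or_genes = 1194,
                            n_nonor_genes = 20988,
                            n_replicates_per_group = 3,
                            baseline_mean = 100,
                            nonor_baseline_mean = 400,
                            dispersion = 0.1,
                            or_group_log2fc = 0,
                            per_zone_log2fc = NULL,
                            baseline_sdlog = 0.5,
                            seed) {
  n_or <- check_count(n_or_genes, "n_or_genes")
  n_non <- check_count(n_nonor_genes, "n_nonor_genes", min = 0L)
  n_rep <- check_count(n_replicates_per_group, "n_replicates_per_group", min = 2L)
  check_positive(baseline_mean, "baseline_mean")
  check_positive(nonor_baseline_mean, "nonor_baseline_mean")
  check_positive(dispersion, "dispersion")
  if (!is.null(per_zone_log2fc)) {
    if (is.null(names(per_zone_log2fc)) ||
        !all(names(per_zone_log2fc) %in% ZONE_LEVELS)) {
      stop_input("`per_zone_log2fc` must be named with zone labels from zone_levels()")
    }
  }

  with_seed(seed, {
    or_ids <- sprintf("Olfr%04d", seq_len(n_or))
    non_ids <- if (n_non > 0) sprintf("Gene%05d", seq_len(n_non)) else character(0)
    zone <- rep(ZONE_LEVELS, length.out = n_or)

    lfc <- rep(or_group_log2fc, n_or)
    if (!is.null(per_zone_log2fc)) {
      for (z in names(per_zone_log2fc)) lfc[zone == z] <- per_zone_log2fc[[z]]
    }

    gene_ids <- c(or_ids, non_ids)
    planted <- c(lfc, rep(0, n_non))
    zones <- data.frame(gene_id = gene_ids,
                        zone = c(zone, rep("nonOR", n_non)),
                        stringsAsFactors = FALSE)

    # log-normal gene-level baselines centred on the class means
    base_mu <- c(rep(baseline_mean, n_or), rep(nonor_baseline_mean, n_non))
    mu0 <- base_mu * exp(rnorm(length(base_mu), -baseline_sdlog^2 / 2, baseline_sdlog))

    n_samp <- 2L * n_rep
    group <- factor(rep(c("control", "perturbed"), each = n_rep),
                    levels = c("control", "perturbed"))
    mu <- matrix(mu0, nrow = length(mu0), ncol = n_samp)
    mu[, group == "perturbed"] <- mu[, group == "perturbed"] * 2^planted
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                     nrow = nrow(mu),
                     dimnames = list(gene_ids,
                                     paste0(rep(c("ctrl", "pert"), each = n_rep),
                                            "_", seq_len(n_rep))))
    structure(list(counts = counts,
                   group = group,
                   zones = zones,
                   truth = data.frame(gene_id = gene_ids,
                                      zone = zones$zone,
                                      planted_log2fc = planted,
                                      baseline_mean = mu0,
                                      stringsAsFactors = FALSE)),
              class = "bulk_sim")
  })
}

#' Simulate single-cell counts with monoallelic OR choice
#'
#' Emulates scRNA-seq of mature olfactory sensory neurons: each cell picks one
#' zone according to `zone_choice_probs`, then one OR uniformly within that
#' zone, and expresses it at `chosen_or_mean` while all other ORs stay at
#' `background_or_mean`. Dorsal (Class I + zones 1-3) and ventral (zones 4-5)
#' cells are separated by `marker_effect` log2 units on a panel of marker
#' genes; additional background genes carry no class signal. Optionally a
#' fraction of ventral-zone cells can be "shifted": they adopt the dorsal
#' marker profile and choose a dorsal OR, emulating a loss of ventral identity.
#'
#' @param n_cells number of cells.
#' @param zone_choice_probs named probability vector over
#'   `zone_levels()` (`classI`, `z1`..`z5`); must sum to 1.
#' @param or_genes_per_zone OR genes annotated per zone.
#' @param chosen_or_mean expected count of the chosen OR (Poisson).
#' @param background_or_mean expected count of every non-chosen OR; must be
#'   smaller than `chosen_or_mean`. The default (0.05) emulates the ambient
#'   contamination level of droplet scRNA-seq, keeping cells monoallelic.
#' @param n_marker_genes number of zonal marker genes (half dorsal-high,
#'   half ventral-high).
#' @param marker_effect log2 separation of marker means between dorsal and
#'   ventral cells.
#' @param n_background_genes non-marker, non-OR genes with identical means in
#'   both classes.
#' @param marker_base_mean,background_mean expected counts of marker and
#'   background genes.
#' @param shift_ventral_frac fraction of ventral-drawn cells converted to a
#'   dorsal transcriptional program (dorsal markers and dorsal chosen OR);
#'   flagged in the truth table.
#' @param seed required integer seed.
#' @return list of class `sc_sim` with `counts` (cells x genes integer
#'   matrix), `zones` (gene annotation) and `truth` (per cell: drawn zone,
#'   chosen OR, dorsal/ventral label, shifted flag).
#' @examples
#' sim <- sim_sc_counts(n_cells = 50, seed = 1)
#' table(sim$truth$zone)
#' @export
sim_sc_counts <- function(n_cells = 1000,
                          zone_choice_probs = c(classI = 0.04, z1 = 0.20, z2 = 0.20,
                                                z3 = 0.20, z4 = 0.18, z5 = 0.18),
                          or_genes_per_zone = 50,
                          chosen_or_mean = 50,
                          background_or_mean = 0.05,
                          n_marker_genes = 50,
                          marker_effect = 2,
                          n_background_genes = 200,
                          marker_base_mean = 20,
                          background_mean = 10,
                          shift_ventral_frac = 0,
                          seed) {
  n_cells <- check_count(n_cells, "n_cells")
  or_per_zone <- check_count(or_genes_per_zone, "or_genes_per_zone")
  n_marker <- check_count(n_marker_genes, "n_marker_genes", min = 0L)
  n_bg <- check_count(n_background_genes, "n_background_genes", min = 0L)
  check_positive(chosen_or_mean, "chosen_or_mean")
  if (background_or_mean < 0) stop_input("`background_or_mean` must be >= 0")
  if (chosen_or_mean <= background_or_mean) {
    stop_input("`chosen_or_mean` must exceed `background_or_mean`")
  }
  if (is.null(names(zone_choice_probs)) ||
      !setequal(names(zone_choice_probs), ZONE_LEVELS)) {
    stop_input("`zone_choice_probs` must be named with exactly: ",
               paste(ZONE_LEVELS, collapse = ", "))
  }
  zone_choice_probs <- zone_choice_probs[ZONE_LEVELS]
  if (any(zone_choice_probs < 0) || abs(sum(zone_choice_probs) - 1) > 1e-9) {
    stop_input("`zone_choice_probs` must be nonnegative and sum to 1 (tol 1e-9)")
  }
  if (shift_ventral_frac < 0 || shift_ventral_frac > 1) {
    stop_input("`shift_ventral_frac` must be in [0, 1]")
  }

  with_seed(seed, {
    or_zone <- rep(ZONE_LEVELS, each = or_per_zone)
    or_ids <- sprintf("Olfr_%s_%02d", or_zone, sequence(rep(or_per_zone, 6)))
    marker_ids <- if (n_marker > 0) sprintf("Marker%03d", seq_len(n_marker)) else character(0)
    bg_ids <- if (n_bg > 0) sprintf("Bg%04d", seq_len(n_bg)) else character(0)
    gene_ids <- c(or_ids, marker_ids, bg_ids)
    zones <- data.frame(gene_id = gene_ids,
                        zone = c(or_zone, rep("nonOR", n_marker + n_bg)),
                        stringsAsFactors = FALSE)

    cell_zone <- sample(ZONE_LEVELS, n_cells, replace = TRUE,
                        prob = zone_choice_probs)
    shifted <- rep(FALSE, n_cells)
    ventral <- which(cell_zone %in% VENTRAL_ZONES)
    if (shift_ventral_frac > 0 && length(ventral)) {
      n_shift <- round(shift_ventral_frac * length(ventral))
      shifted[sample(ventral, n_shift)] <- TRUE
    }
    original_zone <- cell_zone
    if (any(shifted)) {
      # shifted cells choose a dorsal OR and carry the dorsal program
      p_dorsal <- zone_choice_probs[DORSAL_ZONES]
      if (sum(p_dorsal) == 0) p_dorsal[] <- 1
      cell_zone[shifted] <- sample(DORSAL_ZONES, sum(shifted), replace = TRUE,
                                   prob = p_dorsal / sum(p_dorsal))
    }
    chosen <- vapply(cell_zone, function(z) {
      sample(or_ids[or_zone == z], 1L)
    }, character(1))
    dv <- ifelse(cell_zone %in% DORSAL_ZONES, "dorsal", "ventral")

    n_genes <- length(gene_ids)
    mu <- matrix(0, n_cells, n_genes, dimnames = list(sprintf("cell%05d", seq_len(n_cells)),
                                                      gene_ids))
    mu[, or_ids] <- background_or_mean
    mu[cbind(seq_len(n_cells), match(chosen, gene_ids))] <- chosen_or_mean
    if (n_marker > 0) {
      dorsal_markers <- marker_ids[seq_len(ceiling(n_marker / 2))]
      ventral_markers <- setdiff(marker_ids, dorsal_markers)
      up <- 2^(marker_effect / 2)
      is_d <- dv == "dorsal"
      mu[, dorsal_markers] <- marker_base_mean * ifelse(is_d, up, 1 / up)
      if (length(ventral_markers)) {
        mu[, ventral_markers] <- marker_base_mean * ifelse(is_d, 1 / up, up)
      }
    }
    if (n_bg > 0) mu[, bg_ids] <- background_mean

    counts <- matrix(rpois(length(mu), mu), nrow = n_cells,
                     dimnames = dimnames(mu))
    truth <- data.frame(cell_id = rownames(counts),
                        zone = cell_zone,
                        original_zone = original_zone,
                        chosen_or = chosen,
                        dv = dv,
                        shifted = shifted,
                        stringsAsFactors = FALSE)
    structure(list(counts = counts, zones = zones, truth = truth,
                   marker_ids = marker_ids),
              class = "sc_sim")
  })
}

#' Simulate a soft X-ray tomography nucleus phantom
#'
#' Builds a spherical nucleus on a 3D voxel grid and plants heterochromatin as
#' a peripheral shell plus random interior blobs at an exact target volume
#' fraction. Per-voxel linear absorption coefficient (LAC) values are drawn
#' from class-specific Gaussians (heterochromatin denser, hence higher LAC).
#' The exact truth labelling is returned for scoring segmentation output.
#'
#' The shell is formed from the voxels closest to the nuclear envelope, with
#' its voxel count solved from `shell_share`; blobs are random spheres that
#' must not touch the shell, with the final blob trimmed from its rim inward
#' to hit the target heterochromatin voxel count exactly (so the realised
#' fraction is within one voxel of the target). Default geometry emulates a
#' mature olfactory neuron nucleus: a peripheral heterochromatin rim about
#' three voxels thick plus a few large chromocenter-like interior masses.
#' Both are kept well above the posterior-smoothing scale of the
#' segmentation (sigma 1.5 voxels), so planted fractions are recoverable;
#' shrinking structures toward the smoothing scale erodes them.
#'
#' @param grid_shape integer vector of 3 voxel dimensions.
#' @param nucleus_radius nucleus radius in voxels; must fit inside the grid.
#' @param het_fraction target heterochromatin fraction of nuclear volume,
#'   in (0, 1).
#' @param shell_share fraction of heterochromatin placed as the peripheral
#'   shell (the rest becomes interior blobs), in \[0, 1\].
#' @param lac_means length-2 vector `c(eu, het)` of class LAC means; het must
#'   exceed eu.
#' @param lac_sd within-class Gaussian noise SD (0 gives a noiseless
#'   two-valued phantom).
#' @param blob_radius_range radii (voxels) from which interior blob spheres
#'   are drawn; defaults to 27-42\% of the nucleus radius (7-11 voxels for
#'   the default 26-voxel nucleus), scaling the chromocenter-like masses
#'   with the nucleus.
#' @param seed required integer seed.
#' @return list of class `nucleus_phantom` with `lac` (3D numeric array),
#'   `mask` (logical nucleus mask), `truth` (integer array: 0 outside,
#'   1 euchromatin, 2 heterochromatin) and `het_fraction_realized`.
#' @examples
#' ph <- sim_nucleus_phantom(grid_shape = c(32, 32, 32), nucleus_radius = 12,
#'                           seed = 1)
#' ph$het_fraction_realized
#' @export
sim_nucleus_phantom <- function(grid_shape = c(64, 64, 64),
                                nucleus_radius = 26,
                                het_fraction = 0.43,
                                shell_share = 0.7,
                                lac_means = c(eu = 0.25, het = 0.45),
                                lac_sd = 0.05,
                                blob_radius_range = NULL,
                                seed) {
  if (length(grid_shape) != 3 || any(grid_shape < 8)) {
    stop_input("`grid_shape` must give three dimensions, each >= 8")
  }
  grid_shape <- as.integer(grid_shape)
  check_positive(nucleus_radius, "nucleus_radius")
  if (het_fraction <= 0 || het_fraction >= 1) {
    stop_input("`het_fraction` must be in (0, 1)")
  }
  if (shell_share < 0 || shell_share > 1) stop_input("`shell_share` must be in [0, 1]")
  if (length(lac_means) != 2 || lac_means[2] <= lac_means[1]) {
    stop_input("`lac_means` must be c(eu, het) with het > eu")
  }
  if (lac_sd < 0) stop_input("`lac_sd` must be >= 0")
  if (is.null(blob_radius_range)) {
    blob_radius_range <- c(max(2, 0.27 * nucleus_radius),
                           max(3, 0.42 * nucleus_radius))
  }
  ctr <- (grid_shape + 1) / 2
  if (nucleus_radius >= min(grid_shape) / 2 - 1) {
    stop_input("nucleus does not fit in the grid (needs radius < min(dim)/2 - 1)")
  }

  with_seed(seed, {
    ax <- lapply(1:3, function(k) (seq_len(grid_shape[k]) - ctr[k])^2)
    d2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
    mask <- array(d2 <= nucleus_radius^2, dim = grid_shape)
    n_nuc <- sum(mask)

    het_target <- round(het_fraction * n_nuc)
    shell_target <- round(shell_share * het_target)
    blob_target <- het_target - shell_target

    # distance of each nucleus voxel to the envelope (exterior)
    dist_env <- array(cpp_edt3d(as.integer(mask), grid_shape), dim = grid_shape)
    truth <- array(0L, dim = grid_shape)
    truth[mask] <- 1L

    idx_nuc <- which(mask)
    if (shell_target > 0) {
      ord <- order(dist_env[idx_nuc], idx_nuc)  # innermost distances last
      shell_idx <- idx_nuc[ord[seq_len(shell_target)]]
      truth[shell_idx] <- 2L
    }
    shell_depth <- if (shell_target > 0) max(dist_env[truth == 2L]) else 0

    if (blob_target > 0) {
      rmin <- blob_radius_range[1]; rmax <- blob_radius_range[2]
      interior <- which(mask & dist_env > shell_depth + rmax + 1)
      if (!length(interior)) {
        stop_input("`het_fraction`/`shell_share` infeasible: no interior room for blobs")
      }
      placed <- 0L
      guard <- 0L
      coords <- arrayInd(interior, grid_shape)
      while (placed < blob_target) {
        guard <- guard + 1L
        if (guard > 10000L) {
          stop_input("could not reach the target heterochromatin fraction with blobs")
        }
        c0 <- coords[sample.int(nrow(coords), 1L), ]
        r <- runif(1, rmin, min(rmax, dist_env[matrix(c0, 1)] - shell_depth - 1))
        lo <- pmax(c0 - ceiling(r), 1L); hi <- pmin(c0 + ceiling(r), grid_shape)
        sub <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
        inside <- rowSums((t(t(sub) - c0))^2) <= r^2
        vox <- sub[inside, , drop = FALSE]
        vidx <- vox[, 1] + (vox[, 2] - 1L) * grid_shape[1] +
          (vox[, 3] - 1L) * grid_shape[1] * grid_shape[2]
        vidx <- vidx[mask[vidx] & truth[vidx] != 2L & dist_env[vidx] > shell_depth]
        if (!length(vidx)) next
        if (placed + length(vidx) > blob_target) {
          # trim the final blob from its rim inward so it stays connected
          vc <- arrayInd(vidx, grid_shape)
          d2c <- rowSums((t(t(vc) - c0))^2)
          vidx <- vidx[order(d2c, vidx)][seq_len(blob_target - placed)]
        }
        truth[vidx] <- 2L
        placed <- placed + length(vidx)
      }
    }

    lac <- array(rnorm(prod(grid_shape), lac_means[1] * 0.4, lac_sd),
                 dim = grid_shape)
    lac[truth == 1L] <- rnorm(sum(truth == 1L), lac_means[1], lac_sd)
    lac[truth == 2L] <- rnorm(sum(truth == 2L), lac_means[2], lac_sd)

    structure(list(lac = lac, mask = mask, truth = truth,
                   het_fraction_realized = sum(truth == 2L) / n_nuc,
                   lac_means = lac_means, lac_sd = lac_sd),
              class = "nucleus_phantom")
  })
}

#' Simulate a per-gene zonal chromatin-signal table
#'
#' Draws per-gene signal values (e.g. promoter H3K9me3 levels) around planted
#' zone means, emulating a dorsoventral methylation gradient over OR genes.
#'
#' @param per_zone_signal_means named numeric vector of mean signal per zone
#'   (names from `zone_levels()`, typically `z1`..`z5`); all >= 0.
#' @param n_genes_per_zone genes simulated per zone.
#' @param noise_sd Gaussian noise SD; values are truncated at 0 to respect
#'   the nonnegativity of coverage summaries.
#' @param seed required integer seed.
#' @return data frame with `gene_id`, `zone`, `value` and the planted mean.
#' @export
sim_coverage_table <- function(per_zone_signal_means = c(z1 = 10, z2 = 8, z3 = 6,
                                                         z4 = 4, z5 = 2),
                               n_genes_per_zone = 50,
                               noise_sd = 1,
                               seed) {
  if (is.null(names(per_zone_signal_means)) ||
      !all(names(per_zone_signal_means) %in% ZONE_LEVELS)) {
    stop_input("`per_zone_signal_means` must be named with zone labels")
  }
  if (any(per_zone_signal_means < 0)) stop_input("zone signal means must be >= 0")
  if (noise_sd < 0) stop_input("`noise_sd` must be >= 0")
  n <- check_count(n_genes_per_zone, "n_genes_per_zone")
  with_seed(seed, {
    zone <- rep(names(per_zone_signal_means), each = n)
    mu <- rep(unname(per_zone_signal_means), each = n)
    data.frame(gene_id = sprintf("Olfr_%s_%03d", zone, sequence(rep(n, length(per_zone_signal_means)))),
               zone = zone,
               value = pmax(0, rnorm(length(mu), mu, noise_sd)),
               planted_mean = mu,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a 2D fluorescence image with nuclear foci
#'
#' Paints circular foci onto a noisy background with a positive baseline.
#' `ring` mode places peak intensity on the circle of the focus radius (a
#' periphery-enriched signal, like a protein rimming DAPI-dense foci),
#' `core` concentrates signal at the focus centre, and `uniform` adds the
#' signal everywhere — the null condition of a protein with no focal
#' enrichment, giving a flat radial profile.
#'
#' @param image_shape `c(height, width)` in pixels.
#' @param foci data frame with columns `x`, `y`, `r` (pixels); each disk must
#'   lie fully inside the image.
#' @param mode one of `"ring"`, `"uniform"`, `"core"`.
#' @param ring_width Gaussian width of the ring (pixels).
#' @param intensity peak added intensity (arbitrary units).
#' @param background baseline intensity added everywhere.
#' @param noise_sd background Gaussian noise SD.
#' @param seed required integer seed.
#' @return list of class `focus_image` with `image` (matrix, rows = y) and
#'   `foci` (the ROI table).
#' @export
sim_focus_image <- function(image_shape = c(128, 128),
                            foci = data.frame(x = 64, y = 64, r = 20),
                            mode = c("ring", "uniform", "core"),
                            ring_width = 3,
                            intensity = 100,
                            background = 10,
                            noise_sd = 2,
                            seed) {
  mode <- match.arg(mode)
  if (length(image_shape) != 2 || any(image_shape < 8)) {
    stop_input("`image_shape` must be c(height, width), each >= 8")
  }
  if (!is.data.frame(foci) || !all(c("x", "y", "r") %in% names(foci))) {
    stop_input("`foci` must have columns x, y, r")
  }
  if (any(foci$r <= 0)) stop_input("focus radii must be positive")
  h <- image_shape[1]; w <- image_shape[2]
  if (any(foci$x - foci$r < 1 | foci$x + foci$r > w |
          foci$y - foci$r < 1 | foci$y + foci$r > h)) {
    stop_input("all foci must lie fully inside the image")
  }
  with_seed(seed, {
    img <- matrix(rnorm(h * w, background, noise_sd), h, w)
    if (mode == "uniform") img <- img + intensity
    xs <- matrix(seq_len(w), h, w, byrow = TRUE)
    ys <- matrix(seq_len(h), h, w)
    if (mode != "uniform") {
      for (i in seq_len(nrow(foci))) {
        d <- sqrt((xs - foci$x[i])^2 + (ys - foci$y[i])^2)
        add <- switch(mode,
          ring = intensity * exp(-((d - foci$r[i])^2) / (2 * ring_width^2)),
          core = intensity * exp(-(d^2) / (2 * (foci$r[i] / 3)^2)))
        img <- img + add
      }
    }
    structure(list(image = img, foci = foci, mode = mode),
              class = "focus_image")
  })
}
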