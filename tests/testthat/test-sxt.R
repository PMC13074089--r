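# closed-form Bayes-optimal two-Gaussian classifier used as the oracle
bayes_het <- function(x, means, sds, weights) {
  log_h <- log(weights[2]) + dnorm(x, means[2], sds[2], log = TRUE)
  log_e <- log(weights[1]) + dnorm(x, means[1], sds[1], log = TRUE)
  log_h > log_e
}

test_that("noiseless phantoms are partitioned exactly before smoothing", {
  ph <- sim_nucleus_phantom(lac_sd = 0, seed = 1)
  p <- fit_gmm_partition(ph$lac, ph$mask, sigma = 1.5, seed = 1)
  truth_het <- (ph$truth == 2L)[ph$mask]
  expect_identical(p$posterior[ph$mask] > 0.5, truth_het)
  # smoothing may flip a thin rim of boundary voxels but nothing more
  expect_gte(mean(p$het[ph$mask] == truth_het), 0.99)
  expect_equal(sum(p$fractions), 100, tolerance = 1e-9)
})

test_that("partition labels agree with the Bayes-optimal classifier", {
  # overlapping classes at a 3-sigma mean separation, 10 seeded phantoms
  agree <- vapply(1:10, function(s) {
    ph <- sim_nucleus_phantom(grid_shape = c(48, 48, 48), nucleus_radius = 18,
                              lac_means = c(eu = 0.30, het = 0.45),
                              lac_sd = 0.05, seed = s)
    p <- fit_gmm_partition(ph$lac, ph$mask, sigma = 1.5, seed = 1)
    x <- ph$lac[ph$mask] / mean(ph$lac[ph$mask])
    scale <- mean(ph$lac[ph$mask])
    n_nuc <- sum(ph$mask)
    w_het <- sum(ph$truth == 2L) / n_nuc
    oracle <- bayes_het(x, c(0.30, 0.45) / scale, c(0.05, 0.05) / scale,
                        c(1 - w_het, w_het))
    mean((p$posterior[ph$mask] > 0.5) == oracle)
  }, numeric(1))
  expect_true(all(agree >= 0.99))
})

test_that("degenerate volumes are rejected", {
  flat <- array(1, c(16, 16, 16))
  mask <- array(TRUE, c(16, 16, 16))
  expect_error(fit_gmm_partition(flat, mask, seed = 1), "constant")
  small <- array(FALSE, c(16, 16, 16)); small[1:3, 1:3, 1:3] <- TRUE
  expect_error(fit_gmm_partition(array(rnorm(16^3), c(16, 16, 16)), small,
                                 seed = 1), "100")
})

test_that("partition is deterministic under a fixed seed", {
  ph <- sim_nucleus_phantom(grid_shape = c(32, 32, 32), nucleus_radius = 12,
                            seed = 5)
  p1 <- fit_gmm_partition(ph$lac, ph$mask, seed = 3)
  p2 <- fit_gmm_partition(ph$lac, ph$mask, seed = 3)
  expect_identical(p1$het, p2$het)
  expect_identical(p1$fractions, p2$fractions)
})

test_that("chromatin fractions recover planted values and always sum to 100", {
  for (s in 1:3) {
    ph <- sim_nucleus_phantom(seed = s)  # 64^3, het 0.43, 4-sigma classes
    fr <- chromatin_fractions(fit_gmm_partition(ph$lac, ph$mask, seed = 1))
    expect_equal(sum(fr), 100, tolerance = 1e-9)
    expect_lt(abs(fr["het"] - 43), 2)
  }
})

test_that("smoothing does not create isolated single-voxel islands", {
  ph <- sim_nucleus_phantom(grid_shape = c(48, 48, 48), nucleus_radius = 18,
                            lac_means = c(eu = 0.30, het = 0.45), seed = 7)
  islands <- vapply(c(0.5, 1, 1.5, 2), function(sg) {
    p <- fit_gmm_partition(ph$lac, ph$mask, sigma = sg, seed = 1)
    lab <- array(orzone:::cpp_label_components(as.integer(p$het), dim(p$het)),
                 dim(p$het))
    sum(tabulate(lab[p$het]) == 1)
  }, numeric(1))
  expect_true(all(diff(islands) <= 0))
})

test_that("maturity gate uses a strict 37 percent threshold", {
  expect_true(gate_mature(0.38))
  expect_false(gate_mature(0.37))
  expect_equal(gate_mature(c(0.36, 0.38, 0.50)), c(FALSE, TRUE, TRUE))
  ph <- sim_nucleus_phantom(het_fraction = 0.43, seed = 1)
  expect_true(gate_mature(fit_gmm_partition(ph$lac, ph$mask, seed = 1)))
  expect_error(gate_mature(1.2), "\\[0, 1\\]")
})

test_that("local thickness matches slab and sphere geometry", {
  # slab of odd thickness d: thickness d away from the edges
  slab <- array(FALSE, c(24, 24, 24)); slab[, , 8:16] <- TRUE
  th <- local_thickness(slab)
  expect_equal(th[12, 12, 12], 9)
  expect_true(all(th[8:16, 8:16, 8:16][slab[8:16, 8:16, 8:16]] == 9))

  # solid sphere of radius 10: centre thickness = diameter within one voxel
  sph <- sphere_mask(31, 10)
  expect_lt(abs(local_thickness(sph)[16, 16, 16] - 20), 1.2)

  expect_error(local_thickness(array(FALSE, c(8, 8, 8))), "empty")
})

test_that("border thickness characterizes the peripheral shell", {
  ph <- sim_nucleus_phantom(grid_shape = c(48, 48, 48), nucleus_radius = 18,
                            het_fraction = 0.3, shell_share = 1, seed = 3)
  blt <- border_local_thickness(ph$truth == 2L, ph$mask)
  # shell-only phantom: border thickness ~ shell thickness (a few voxels)
  expect_true(all(blt$values > 0))
  expect_lt(unname(quantile(blt$values, 0.9)), 8)
  expect_error(border_local_thickness(array(FALSE, c(8, 8, 8)),
                                      array(TRUE, c(8, 8, 8))), "empty")
})

test_that("watershed seeds separate shell from deep blobs and filter crumbs", {
  ph <- sim_nucleus_phantom(seed = 2)
  het <- ph$truth == 2L
  dist_env <- array(orzone:::cpp_edt3d(as.integer(ph$mask), dim(ph$mask)),
                    dim(ph$mask)) - 0.5
  blt <- border_local_thickness(het, ph$mask)
  seeds <- make_watershed_seeds(het, dist_env, blt$values)
  expect_false(any(seeds$outer & seeds$inner))
  # deep blob voxels (far from the envelope) are inner seeds
  deep <- het & dist_env > seeds$p90 + 2
  expect_true(all(seeds$inner[deep] | !deep[deep]))

  # shell-only heterochromatin has no interior -> inner seed empty -> error
  shell_only <- sim_nucleus_phantom(grid_shape = c(40, 40, 40),
                                    nucleus_radius = 15, het_fraction = 0.3,
                                    shell_share = 1, seed = 4)
  het1 <- shell_only$truth == 2L
  d1 <- array(orzone:::cpp_edt3d(as.integer(shell_only$mask),
                                 dim(shell_only$mask)),
              dim(shell_only$mask)) - 0.5
  b1 <- border_local_thickness(het1, shell_only$mask)
  expect_error(make_watershed_seeds(het1, d1, b1$values), "inner seed is empty")

  # a tiny second blob below 1% of the largest is removed from the inner seed
  big <- sphere_mask(40, 8, center = 20)
  tiny <- sphere_mask(40, 1.1, center = 33)
  hets <- big | tiny
  hets[, , 2] <- TRUE                    # shallow plate seeds the outer basin
  dist_fake <- array(10, c(40, 40, 40))  # blobs are "deep"
  dist_fake[, , 2] <- 0.5
  s2 <- make_watershed_seeds(hets, dist_fake, thickness_values = c(1, 1, 1))
  expect_true(all(!s2$inner[tiny]))
  expect_true(any(s2$inner[big]))
  expect_true(all(s2$outer[, , 2]))
})

test_that("inner/outer watershed split recovers construction and conserves voxels", {
  ph <- sim_nucleus_phantom(lac_sd = 0, seed = 6)
  het <- ph$truth == 2L
  io <- sxt_inner_outer(het, ph$mask)
  # conservation is exact
  expect_equal(sum(io$counts), sum(het))
  expect_false(any(io$labels[!het] != 0))

  # construction truth: the planted shell is the het voxel set closest to
  # the envelope, the blobs are the rest
  dist_env <- array(orzone:::cpp_edt3d(as.integer(ph$mask), dim(ph$mask)),
                    dim(ph$mask))
  idx <- which(het)
  ord <- order(dist_env[idx], idx)
  n_shell <- round(0.7 * sum(het))
  truth_lab <- array(0L, dim(het))
  truth_lab[idx] <- 2L
  truth_lab[idx[ord[seq_len(n_shell)]]] <- 1L
  expect_gte(mean(io$labels[het] == truth_lab[het]), 0.95)

  # single seed family claims everything
  seeds1 <- list(outer = het, inner = array(FALSE, dim(het)))
  one <- split_inner_outer(het, seeds1)
  expect_equal(unname(one$counts["outer"]), sum(het))
})

test_that("watershed output is deterministic", {
  ph <- sim_nucleus_phantom(grid_shape = c(48, 48, 48), nucleus_radius = 18,
                            seed = 8)
  het <- ph$truth == 2L
  expect_identical(sxt_inner_outer(het, ph$mask)$labels,
                   sxt_inner_outer(het, ph$mask)$labels)
})

test_that("gaussian smoothing preserves constants and mass location", {
  arr <- array(5, c(20, 20, 20))
  # zero padding attenuates within a kernel radius (5 voxels) of the edges;
  # the interior is preserved exactly
  sm <- gaussian_smooth3d(arr, 1.5)
  expect_equal(sm[6:15, 6:15, 6:15], arr[6:15, 6:15, 6:15], tolerance = 1e-12)
  spike <- array(0, c(17, 17, 17)); spike[9, 9, 9] <- 1
  sm <- gaussian_smooth3d(spike, 1)
  expect_equal(which.max(sm), which.max(spike))
  expect_equal(sum(sm), 1, tolerance = 1e-9)
})
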