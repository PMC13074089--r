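test_that("call_chosen_or follows the argmax rule with ties and zero rows", {
  m <- rbind(cell1 = c(OrA = 10, OrB = 3, Gapdh = 100),
             cell2 = c(OrA = 5, OrB = 5, Gapdh = 2),
             cell3 = c(OrA = 0, OrB = 0, Gapdh = 50))
  zones <- data.frame(gene_id = c("OrA", "OrB", "Gapdh"),
                      zone = c("z1", "z5", "nonOR"))
  calls <- call_chosen_or(m, zones)
  expect_equal(calls$or_gene, c("OrA", "OrA", NA))   # tie -> lexicographic first
  expect_equal(calls$ambiguous, c(FALSE, TRUE, FALSE))
  expect_equal(calls$zone, c("z1", "z1", NA))
  expect_equal(calls$max_count, c(10, 5, 0))

  expect_error(call_chosen_or(m[, "Gapdh", drop = FALSE], zones), "no OR")
})

test_that("call_chosen_or is invariant to non-OR column permutation", {
  sim <- sim_sc_counts(n_cells = 60, seed = 9)
  calls <- call_chosen_or(sim$counts, sim$zones)
  non_or <- sim$zones$gene_id[sim$zones$zone == "nonOR"]
  perm <- c(setdiff(colnames(sim$counts), non_or), sample(non_or))
  calls2 <- call_chosen_or(sim$counts[, perm], sim$zones)
  expect_identical(calls, calls2)
})

test_that("chosen-OR calls recover simulation truth at high signal ratio", {
  sim <- sim_sc_counts(n_cells = 500, chosen_or_mean = 50,
                       background_or_mean = 1, seed = 3)
  calls <- call_chosen_or(sim$counts, sim$zones)
  expect_gte(mean(calls$or_gene == sim$truth$chosen_or, na.rm = TRUE), 0.99)
})

test_that("zonal choice fractions sum to one and recover planted skew", {
  probs <- c(classI = 0.02, z1 = 0.40, z2 = 0.30, z3 = 0.14,
             z4 = 0.07, z5 = 0.07)
  sim <- sim_sc_counts(n_cells = 2000, zone_choice_probs = probs, seed = 5)
  zf <- zonal_choice_fractions(call_chosen_or(sim$counts, sim$zones))
  expect_equal(sum(zf$fractions), 1, tolerance = 1e-9)
  se <- sqrt(probs * (1 - probs) / 2000)
  expect_true(all(abs(zf$fractions - probs) < 4 * se + 0.01))

  empty <- structure(data.frame(cell_id = "c", or_gene = NA_character_,
                                zone = NA_character_, max_count = 0,
                                ambiguous = FALSE),
                     class = c("chosen_or", "data.frame"))
  expect_error(zonal_choice_fractions(empty), "no called")
})

test_that("mask_or_genes removes OR information as requested", {
  sim <- sim_sc_counts(n_cells = 30, seed = 2)
  or_genes <- sim$zones$gene_id[sim$zones$zone != "nonOR"]

  all_masked <- mask_or_genes(sim$counts, sim$zones)
  expect_length(intersect(colnames(all_masked), or_genes), 0)
  expect_equal(ncol(all_masked), ncol(sim$counts) - length(or_genes))
  expect_equal(rownames(all_masked), rownames(sim$counts))

  calls <- call_chosen_or(sim$counts, sim$zones)
  chosen_masked <- mask_or_genes(sim$counts, sim$zones, "chosen_only", calls)
  expect_equal(ncol(chosen_masked), ncol(sim$counts))
  hit <- cbind(match(calls$cell_id, rownames(sim$counts)),
               match(calls$or_gene, colnames(sim$counts)))
  expect_true(all(chosen_masked[hit] == 0))
  untouched <- sim$counts
  untouched[hit] <- 0
  expect_equal(unname(as.matrix(chosen_masked)), unname(untouched),
               ignore_attr = TRUE)
})

test_that("identity SVM separates planted classes and stays at chance on none", {
  sim <- sim_sc_counts(n_cells = 400, marker_effect = 4, seed = 1)
  masked <- mask_or_genes(sim$counts, sim$zones)
  expect_equal(cv_identity_accuracy(masked, sim$truth$dv, seed = 1), 1)

  sim0 <- sim_sc_counts(n_cells = 400, marker_effect = 0, seed = 2)
  masked0 <- mask_or_genes(sim0$counts, sim0$zones)
  acc0 <- cv_identity_accuracy(masked0, sim0$truth$dv, seed = 1)
  expect_gte(acc0, 0.4)
  expect_lte(acc0, 0.6)

  expect_error(train_identity_svm(masked, rep("dorsal", nrow(masked))),
               "both classes")
})

test_that("no OR gene can leak into the identity model", {
  sim <- sim_sc_counts(n_cells = 120, marker_effect = 3, seed = 6)
  masked <- mask_or_genes(sim$counts, sim$zones)
  model <- train_identity_svm(masked, sim$truth$dv, zones = sim$zones, seed = 1)
  or_genes <- sim$zones$gene_id[sim$zones$zone != "nonOR"]
  expect_length(intersect(model$features, or_genes), 0)
  expect_length(intersect(names(coef(model)), or_genes), 0)
  expect_true(all(is.finite(coef(model))))

  # unmasked input with zones supplied is audited and stripped
  expect_warning(m2 <- train_identity_svm(sim$counts, sim$truth$dv,
                                          zones = sim$zones, seed = 1),
                 "OR gene")
  expect_length(intersect(m2$features, or_genes), 0)
})

test_that("predictions are deterministic and the shift table conserves margins", {
  sim <- sim_sc_counts(n_cells = 300, marker_effect = 4, seed = 4)
  masked <- mask_or_genes(sim$counts, sim$zones)
  model <- train_identity_svm(masked, sim$truth$dv, seed = 1)
  p1 <- predict_identity(model, masked)
  p2 <- predict_identity(model, masked)
  expect_identical(p1, p2)

  # on separable training data the table is diagonal
  tab <- identity_shift_table(sim$truth$dv, p1)
  expect_equal(sum(tab[1, 2], tab[2, 1]), 0)
  expect_equal(unname(rowSums(tab)), unname(table(sim$truth$dv)),
               ignore_attr = TRUE)
})

test_that("swap-like cells are predicted dorsal by a control-trained model", {
  ctrl <- sim_sc_counts(n_cells = 800, marker_effect = 4, seed = 21)
  model <- train_identity_svm(mask_or_genes(ctrl$counts, ctrl$zones),
                              ctrl$truth$dv, seed = 1)
  swap <- sim_sc_counts(n_cells = 800, marker_effect = 4,
                        shift_ventral_frac = 0.8, seed = 22)
  pr <- predict_identity(model, mask_or_genes(swap$counts, swap$zones))
  shifted <- swap$truth$shifted
  expect_gte(mean(pr$predicted[shifted] == "dorsal"), 0.95)
})

test_that("marker selection recovers planted markers and controls the null", {
  sim <- sim_sc_counts(n_cells = 400, marker_effect = 2, n_marker_genes = 50,
                       seed = 8)
  masked <- mask_or_genes(sim$counts, sim$zones)
  mk <- select_zonal_markers(masked, sim$truth$dv, k = 50)
  expect_gte(mean(mk$gene_id %in% sim$marker_ids), 0.9)

  sim0 <- sim_sc_counts(n_cells = 200, marker_effect = 0, seed = 9)
  mk0 <- select_zonal_markers(mask_or_genes(sim0$counts, sim0$zones),
                              sim0$truth$dv, k = 1000)
  expect_equal(sum(mk0$padj < 0.05, na.rm = TRUE), 0)
  # k above the gene count ranks everything
  expect_equal(nrow(mk0), ncol(mask_or_genes(sim0$counts, sim0$zones)))
})

test_that("coexpression tally flags monoallelic expression", {
  sim <- sim_sc_counts(n_cells = 300, seed = 10)
  tl <- coexpression_tally(sim$counts, sim$zones, min_count = 5)
  expect_gte(mean(tl$tally == 1), 0.95)

  zeros <- matrix(0L, 2, 3,
                  dimnames = list(c("c1", "c2"), c("OrA", "OrB", "Gapdh")))
  zt <- data.frame(gene_id = c("OrA", "OrB", "Gapdh"),
                   zone = c("z1", "z2", "nonOR"))
  expect_equal(unname(coexpression_tally(zeros, zt, min_count = 1)$tally),
               c(0L, 0L))
  expect_warning(deg <- coexpression_tally(zeros, zt, min_count = 0), "every OR")
  expect_equal(unname(deg$tally), c(2L, 2L))
})
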