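make_track <- function(values, bin = 100, chrom = "chr1", normalized = "per10M") {
  n <- length(values)
  coverage_track(data.frame(chrom = chrom, start = seq(0, by = bin, length.out = n),
                            end = seq(bin, by = bin, length.out = n),
                            value = values),
                 normalized = normalized)
}

test_that("normalize_track scales to a 10M-read library and is linear", {
  tr <- make_track(1:10, normalized = "raw")
  expect_equal(normalize_track(tr, 1e7)$value, as.numeric(1:10))
  expect_equal(normalize_track(tr, 5e6)$value, 2 * (1:10))
  expect_error(normalize_track(tr, 0), "positive")

  # linearity: normalize(a * track) = a * normalize(track)
  tr3 <- tr; tr3$value <- 3 * tr3$value
  expect_equal(normalize_track(tr3, 4e6)$value,
               3 * normalize_track(tr, 4e6)$value)
})

test_that("frip counts read-in-peak fractions with half-open semantics", {
  # hand-enumerated: 6 reads, 2 peaks at [10,20) and [30,40)
  reads <- data.frame(chrom = "chr1",
                      start = c(0, 8, 19, 20, 35, 50),
                      end = c(5, 12, 25, 30, 36, 60))
  peaks <- data.frame(chrom = "chr1", start = c(10, 30), end = c(20, 40))
  # in: [8,12) [19,25) [35,36); out: [0,5), [20,30) (touching), [50,60)
  expect_equal(frip(reads, peaks), 3 / 6)
  expect_equal(frip(reads, peaks[0, ]), 0)

  # 1245 of 10000 reads inside the single peak
  many <- data.frame(chrom = "chr1",
                     start = seq(0, by = 10, length.out = 10000))
  many$end <- many$start + 5
  peak1 <- data.frame(chrom = "chr1", start = 0, end = 1245 * 10 - 4)
  expect_equal(frip(many, peak1), 0.1245)
})

test_that("interval operations agree with a brute-force all-pairs scan", {
  reads <- random_intervals(10000, seed = 41)
  peaks <- random_intervals(300, seed = 42, max_len = 2000)
  expect_equal(frip(reads, peaks), mean(brute_overlaps_any(reads, peaks)))
  expect_equal(count_peak_overlaps(peaks, reads),
               sum(brute_overlaps_any(peaks, reads)))
})

test_that("count_peak_overlaps handles disjoint, identical and touching sets", {
  a <- data.frame(chrom = "chr1", start = c(0, 100), end = c(50, 150))
  b <- data.frame(chrom = "chr1", start = c(200, 300), end = c(250, 350))
  expect_equal(count_peak_overlaps(a, b), 0L)
  expect_equal(count_peak_overlaps(a, a), 2L)
  # touching half-open intervals do not overlap; nesting counts once
  c1 <- data.frame(chrom = "chr1", start = c(50, 120), end = c(100, 130))
  expect_equal(count_peak_overlaps(a, c1), 1L)
})

test_that("gene_signal summarizes windows with strand-aware TSS", {
  tr <- make_track(1:10)
  genes <- data.frame(gene_id = c("a", "b"),
                      chrom = "chr1", start = c(0, 500), end = c(300, 800),
                      strand = c("+", "-"))
  gs <- gene_signal(tr, genes)
  expect_equal(gs$mean_cpm, c(mean(1:3), mean(6:8)))
  expect_equal(gs$median_cpm, c(2, 7))

  # constant track: every gene gets the constant
  gc <- gene_signal(make_track(rep(4, 10)), genes)
  expect_true(all(gc$mean_cpm == 4) && all(gc$median_cpm == 4))

  # single nonzero bin inside one gene only
  v <- rep(0, 10); v[2] <- 5
  g1 <- gene_signal(make_track(v), genes)
  expect_gt(g1$mean_cpm[1], 0)
  expect_equal(g1$mean_cpm[2], 0)

  # TSS windows: plus-strand gene anchors at start, minus-strand at end
  ts <- gene_signal(tr, genes, window = "tss_flank", flank = 100)
  expect_equal(ts$mean_cpm[1], 1)           # window clipped to [0,100): bin 1
  expect_equal(ts$mean_cpm[2], mean(7:9))   # tss at 799 -> [699,899): bins 7-9
})

test_that("tss_profile is strand-mirrored and validates bin divisibility", {
  vals <- c(0, 1, 5, 9, 9, 5, 1, 0, 0, 0)  # symmetric about position 400
  tr <- make_track(vals)
  genes <- data.frame(gene_id = c("plus", "minus"), chrom = "chr1",
                      start = c(400, 0), end = c(600, 401), strand = c("+", "-"))
  prof <- tss_profile(tr, genes, flank = 300)
  expect_equal(dim(prof), c(2, 6))
  # both genes have their tss at position 400 on a symmetric peak: the
  # minus-strand row is reversed to 5'->3', so the rows coincide
  expect_equal(prof["plus", ], prof["minus", ])
  expect_equal(prof["plus", ], rev(prof["plus", ]), tolerance = 1e-12)

  flat <- tss_profile(make_track(rep(2, 10)), genes, flank = 300)
  expect_true(all(flat == 2))

  expect_error(tss_profile(tr, genes, flank = 230), "divisible")
})

test_that("wilcoxon comparison is exact for small samples", {
  w <- compare_groups_wilcoxon(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$p_value, 0.1, tolerance = 1e-10)

  # enumeration oracle for n = m = 3..4 without ties
  set.seed(1)
  for (n in 3:4) {
    x <- sample(100, 2 * n)
    a <- x[1:n]; b <- x[(n + 1):(2 * n)]
    Wobs <- sum(rank(c(a, b))[1:n]) - n * (n + 1) / 2
    combs <- combn(2 * n, n)
    Wall <- apply(combs, 2, function(i) {
      sum(rank(c(x[i], x[-i]))[1:n]) - n * (n + 1) / 2
    })
    mu <- n * n / 2
    p_exact <- mean(abs(Wall - mu) >= abs(Wobs - mu))
    expect_equal(compare_groups_wilcoxon(a, b)$p_value, p_exact,
                 tolerance = 1e-10)
  }

  same <- c(1, 5, 9, 12)
  expect_equal(compare_groups_wilcoxon(same, same)$p_value, 1)
  expect_error(compare_groups_wilcoxon(1, c(1, 2)), "at least 2")
})

test_that("zonal gradient statistic detects planted trends and nulls", {
  tab <- sim_coverage_table(seed = 1)  # strictly decreasing z1..z5 means
  g <- zonal_gradient_stat(tab, seed = 1)
  expect_lt(g$rho, 0)
  expect_lt(g$p_value, 0.01)

  flat <- sim_coverage_table(per_zone_signal_means =
                               c(z1 = 5, z2 = 5, z3 = 5, z4 = 5, z5 = 5),
                             seed = 2)
  g0 <- zonal_gradient_stat(flat, seed = 1)
  expect_lt(abs(g0$rho), 0.15)
  expect_gt(g0$p_value, 0.05)

  single <- data.frame(zone = rep("z1", 10), value = rnorm(10))
  expect_error(zonal_gradient_stat(single), "two zones")
})

test_that("activated/repressed stratification follows the DE calls", {
  de <- toy_de_table()
  summaries <- data.frame(gene_id = paste0("g", 1:6), value = 1:6)
  strata <- stratify_activated_repressed(summaries, de)
  expect_setequal(strata$down$gene_id, c("g1", "g4"))
  expect_setequal(strata$up$gene_id, "g3")
  expect_setequal(strata$ns$gene_id, c("g2", "g5", "g6"))

  # all-ns table collapses to a single stratum
  ns_de <- data.frame(gene_id = paste0("g", 1:3), log2fc = 0, padj = 1)
  s1 <- stratify_activated_repressed(data.frame(gene_id = paste0("g", 1:3),
                                                value = 1:3), ns_de)
  expect_equal(names(s1), "ns")

  extra <- rbind(summaries, data.frame(gene_id = "gX", value = 0))
  expect_warning(stratify_activated_repressed(extra, de), "excluded")
})

test_that("planted activated ORs lose more signal than repressed ones", {
  # paired design: per-gene H3K9me3 drop is larger for activated genes
  set.seed(3)
  n <- 40
  status <- rep(c("act", "rep"), each = n)
  drop <- ifelse(status == "act", 4, 1)
  before <- rnorm(2 * n, 10, 0.5)
  after <- before - drop + rnorm(2 * n, 0, 0.5)
  de <- data.frame(gene_id = paste0("g", seq_len(2 * n)),
                   log2fc = ifelse(status == "act", 2, -2),
                   padj = 0.001)
  summ <- data.frame(gene_id = de$gene_id, value = before - after)
  strata <- stratify_activated_repressed(summ, de)
  expect_gt(mean(strata$up$value) - mean(strata$down$value), 0)
})
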