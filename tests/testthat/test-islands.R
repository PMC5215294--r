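# Island calling, M-A normalization and the differential test.

test_that("window eligibility follows the exact Poisson upper tail", {
  # k = 10 observed vs lambda = 1: tail ~ 1.1e-7, well under 1e-5
  expect_lt(oracle_pois_upper(10, 1), 1e-5)
  expect_equal(oracle_pois_upper(10, 1),
               ppois(9, 1, lower.tail = FALSE), tolerance = 1e-6)
})

test_that("uniform background yields no islands at p=1e-5", {
  set.seed(31)
  # lambda = 5 per 200 bp window over 1000 windows: expected false
  # eligible windows = 1000 * P(tail) < 0.05
  tags <- random_tags(5 * 1000, 200 * 1000)
  isl <- call_islands(tags, c(chr1 = 200000), window = 200, gap = 400,
                      p_threshold = 1e-5)
  expect_equal(nrow(isl), 0)
  # zero tags: empty result, not an error
  expect_equal(nrow(call_islands(tags[0, ], c(chr1 = 200000))), 0)
})

test_that("a planted region at 10x background is called as one island", {
  cfg <- sim_config(seed = 41, n_chromosomes = 1, chrom_length = 1e6,
                    n_genes = 1,
                    class_fractions = c(constitutive = 0, poised_TEM = 1,
                                        poised_naive = 0, poised_both = 0,
                                        silent = 0))
  sim <- simulate_genome(cfg)
  planted <- sim$truth$planted_islands
  tags <- simulate_chip_tags(sim$truth, cfg, "TEM")
  isl <- call_islands(tags, c(chr1 = 1e6, chrX = 1e6))
  hit <- isl[isl$chrom == planted$chrom, ]
  expect_equal(nrow(hit), 1)
  ov <- min(hit$end, planted$end) - max(hit$start, planted$start)
  expect_gte(ov / (planted$end - planted$start), 0.8)
})

test_that("call_islands equals exhaustive window enumeration on toys", {
  set.seed(43)
  for (rep in 1:5) {
    L <- c(chr1 = 60000, chr2 = 40000)
    tags <- rbind(random_tags(400, L[1], "chr1"),
                  random_tags(150, L[2], "chr2"))
    # plant two dense clusters so islands exist
    extra1 <- random_tags(80, 2000, "chr1"); extra1$start <- extra1$start + 10000L
    extra1$end <- extra1$start + 36L
    extra2 <- random_tags(60, 1500, "chr1"); extra2$start <- extra2$start + 30000L
    extra2$end <- extra2$start + 36L
    tags <- rbind(tags, extra1, extra2)
    got <- call_islands(tags, L, window = 200, gap = 400, p_threshold = 1e-4)
    want <- oracle_call_islands(tags, L, 200, 400, 1e-4, 150)
    expect_equal(got[, c("chrom", "start", "end", "count")], want,
                 ignore_attr = TRUE)
    expect_true(all(got$pvalue > 0 & got$pvalue <= 1))
  }
})

test_that("exact proportional depths normalize to M_adjusted = 0", {
  count_a <- c(20, 40, 80, 160, 320, 25, 50, 100, 200, 400, 30, 60)
  count_b <- 2 * count_a
  norm <- ma_normalize(count_a, count_b, rep(TRUE, 12))
  expect_equal(norm$M, rep(1, 12))
  expect_equal(norm$M_adjusted, rep(0, 12), tolerance = 1e-12)
  # identical samples: nothing passes
  norm_id <- ma_normalize(count_a, count_a, rep(TRUE, 12))
  res <- differential_test(count_a, count_a, norm_id$M_adjusted,
                           norm_id$M_fitted)
  expect_true(all(!res$passes))
  expect_true(all(res$direction == "unchanged"))
  expect_error(ma_normalize(1:5, 1:5, rep(TRUE, 5)), "common islands")
})

test_that("M-A normalization is invariant to rescaling one sample", {
  set.seed(47)
  a <- rpois(60, 100) + 1
  b <- rpois(60, 100) + 1
  common <- rep(c(TRUE, FALSE), c(50, 10))
  n1 <- ma_normalize(a, b, common)
  n2 <- ma_normalize(a, round(b * 7), common)
  expect_equal(n1$M_adjusted, n2$M_adjusted, tolerance = 0.05)
  # pure scaling with no rounding error: exact within 1e-9
  n3 <- ma_normalize(a * 4, b, common)
  n4 <- ma_normalize(a, b, common)
  expect_equal(n3$M_adjusted, n4$M_adjusted, tolerance = 1e-9)
})

test_that("differential criteria follow the p/fold/reads thresholds", {
  # low counts fail the 15-read filter regardless of fold
  r <- differential_test(10, 10, 0)
  expect_false(r$passes)
  r2 <- differential_test(2, 14, log2(7))
  expect_false(r2$passes)
  # equal large counts: unchanged
  r3 <- differential_test(100, 100, 0)
  expect_false(r3$passes)
  # normalized (64, 16) with M_adjusted = 2: passes as gained
  want_p <- binom.test(16, 80, 0.5)$p.value
  r4 <- differential_test(64, 16, -2)
  expect_equal(r4$pvalue, want_p)
  expect_true(r4$passes)
  expect_equal(r4$direction, "lost")
  r5 <- differential_test(16, 64, 2)
  expect_true(r5$passes)
  expect_equal(r5$direction, "gained")
})

test_that("differential direction is antisymmetric under sample swap", {
  cfg <- sim_config(seed = 51, n_chromosomes = 1, chrom_length = 2e6,
                    n_genes = 40)
  sim <- simulate_genome(cfg)
  ta <- simulate_chip_tags(sim$truth, cfg, "Naive")
  tb <- simulate_chip_tags(sim$truth, cfg, "TEM")
  L <- c(chr1 = 2e6, chrX = 2e6)
  ia <- call_islands(ta, L); ib <- call_islands(tb, L)
  fwd <- differential_islands(ta, tb, ia, ib)
  rev <- differential_islands(tb, ta, ib, ia)
  expect_equal(fwd$M_adjusted, -rev$M_adjusted, tolerance = 1e-9)
  swap <- c(gained = "lost", lost = "gained", unchanged = "unchanged")
  expect_equal(unname(swap[fwd$direction]), rev$direction)
})

test_that("3:1 depth imbalance: commons centered, differences detected", {
  cfg <- sim_config(seed = 53, n_chromosomes = 2, chrom_length = 4e6,
                    n_genes = 120,
                    class_fractions = c(constitutive = 5 / 6,
                                        poised_TEM = 1 / 6,
                                        poised_naive = 0, poised_both = 0,
                                        silent = 0))
  sim <- simulate_genome(cfg)
  natural <- expected_tag_count(sim$truth, cfg, "Naive")
  ta <- simulate_chip_tags(sim$truth, cfg, "Naive", 1)
  tb <- simulate_chip_tags(sim$truth, cfg, "TEM", 1, depth = natural / 3)
  L <- setNames(rep(4e6, 3), c("chr1", "chr2", "chrX"))
  d <- differential_islands(ta, tb, call_islands(ta, L),
                            call_islands(tb, L))
  # constitutive (common) islands stay near the diagonal
  truth_tem <- sim$truth$planted_islands[
    sim$truth$planted_islands$cells == "TEM", ]
  is_true_diff <- vapply(seq_len(nrow(d)), function(i)
    any(truth_tem$chrom == d$chrom[i] & truth_tem$start < d$end[i] &
          truth_tem$end > d$start[i]), logical(1))
  expect_gte(mean(abs(d$M_adjusted[d$common & !is_true_diff]) < 0.5), 0.98)
  # at least 90% of the truly TEM-only islands stand out
  expect_gte(mean(abs(d$M_adjusted[is_true_diff]) > 1), 0.9)
})
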