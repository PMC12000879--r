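test_that("the enzyme-low gate is the strict control-median rule", {
  # self-gating a large population sits at ~0.5 (binomial error)
  x <- simulate_if_intensities(2e4, 0, 0, 3, sigma = 0.4, seed = 1)
  y <- simulate_if_intensities(2e4, 0, 0, 3, sigma = 0.4, seed = 2)
  expect_equal(enzyme_low_fraction(x, y), 0.5, tolerance = 0.02)

  # full knockout: everything below the control minimum
  ctrl <- tibble::tibble(intensity = c(10, 12, 15))
  ko <- tibble::tibble(intensity = c(1, 2, 3))
  expect_equal(enzyme_low_fraction(ko, ctrl), 1)

  # strictly-below rule: values equal to the median do not count as low
  eq <- tibble::tibble(intensity = c(12, 12, 12))
  expect_equal(enzyme_low_fraction(eq, ctrl), 0)

  expect_error(enzyme_low_fraction(tibble::tibble(intensity = numeric()), ctrl),
               "non-empty")
})

test_that("clone KO scoring uses a closed mean +- k*SD gate", {
  ref <- c(-1, 1)  # mean 0, sd sqrt(2)
  s <- sd(ref)
  expect_true(score_clone_ko(0, ref)$is_ko)
  expect_false(score_clone_ko(2.5 * s, ref)$is_ko)
  expect_true(score_clone_ko(2 * s, ref)$is_ko)   # boundary is "within"
  expect_true(score_clone_ko(-2 * s, ref)$is_ko)
  expect_false(score_clone_ko(2 * s + 1e-9, ref)$is_ko)

  # vectorized over clones, k configurable
  res <- score_clone_ko(c(0, 3 * s), ref, k = 3, clone_id = c("c1", "c2"))
  expect_equal(res$is_ko, c(TRUE, TRUE))

  expect_warning(score_clone_ko(0, c(5, 5)), "SD is 0")
  expect_error(score_clone_ko(0, 5), ">= 2 cells")
})

test_that("growth-rate comparison fits slopes inside the closed window", {
  tp <- c(0, 12, 24, 36, 48, 60)
  curves <- simulate_growth_curves(c(fast = 0.05, slow = 0.03), tp,
                                   noise_sd = 0, n_replicates = 3)
  res <- growth_rate_test(curves, window = c(24, 48))
  expect_equal(res$slope_a, 0.05)
  expect_equal(res$slope_b, 0.03)
  expect_true(res$degenerate)           # zero replicate variance
  expect_true(is.na(res$p_value))

  # outside-window points must not influence the slope: corrupt them
  bent <- dplyr::mutate(curves, signal = ifelse(time < 24, signal * 100, signal))
  res_bent <- growth_rate_test(bent, window = c(24, 48))
  expect_equal(res_bent$slope_a, 0.05)

  expect_error(growth_rate_test(dplyr::filter(curves, time %in% c(0, 36))),
               "window")
})

test_that("slope-test P values are uniform under the null", {
  withr::with_seed(13, {
    tp <- seq(24, 48, by = 6)
    ps <- replicate(400, {
      curves <- simulate_growth_curves(c(a = 0.04, b = 0.04), tp,
                                       noise_sd = 0.05, n_replicates = 6)
      growth_rate_test(curves)$p_value
    })
    expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  })
})

test_that("consensus peaks require fold >= 5 support in every replicate", {
  r1 <- tibble::tibble(chrom = "chr1", start = c(100L, 500L, 900L),
                       end = c(200L, 600L, 1000L), fold_change = c(8, 5, 9))
  r2 <- tibble::tibble(chrom = "chr1", start = c(150L, 540L),
                       end = c(250L, 620L), fold_change = c(6, 5))
  r3 <- tibble::tibble(chrom = "chr1", start = c(120L, 560L, 905L),
                       end = c(260L, 640L, 950L), fold_change = c(7, 5, 4.9))
  cons <- consensus_peaks(list(r1, r2, r3))

  # region 900-1000 fails: absent from r2, sub-threshold in r3
  expect_equal(nrow(cons), 2)
  # consensus interval = union of the overlapping replicate intervals
  expect_equal(cons$start, c(100L, 500L))
  expect_equal(cons$end, c(260L, 640L))
  expect_true(all(cons$n_replicates == 3))

  # fold exactly 5 in all replicates is retained (inclusive rule)
  expect_true(any(cons$start == 500))

  # matches the brute-force all-pairs oracle
  oracle <- consensus_oracle(list(r1, r2, r3))
  expect_equal(cons$start, oracle$start)
  expect_equal(cons$end, oracle$end)

  # order-invariance over replicate labelling and idempotence
  perm <- consensus_peaks(list(r3, r1, r2))
  expect_equal(perm, cons)
  again <- consensus_peaks(list(cons, cons, cons), min_fold = 0)
  expect_equal(again[, c("chrom", "start", "end")],
               cons[, c("chrom", "start", "end")])
})

test_that("a peak present in only two of three replicates is excluded", {
  r1 <- tibble::tibble(chrom = "chr2", start = 10L, end = 50L, fold_change = 10)
  r2 <- tibble::tibble(chrom = "chr2", start = 30L, end = 70L, fold_change = 10)
  r3 <- tibble::tibble(chrom = "chr2", start = 500L, end = 550L, fold_change = 10)
  expect_equal(nrow(consensus_peaks(list(r1, r2, r3))), 0)
})

test_that("randomized peak trios agree with the brute-force oracle", {
  withr::with_seed(31, {
    for (i in 1:10) {
      reps <- lapply(1:3, function(r) {
        n <- sample(3:8, 1)
        start <- sort(sample.int(500, n)) * 10L
        tibble::tibble(chrom = "chr1", start = start,
                       end = start + sample(20:80, n, replace = TRUE),
                       fold_change = runif(n, 3, 10))
      })
      cons <- consensus_peaks(reps)
      oracle <- consensus_oracle(lapply(reps, as.data.frame))
      expect_equal(cons$start, oracle$start)
      expect_equal(cons$end, oracle$end)
    }
  })
})

test_that("invalid intervals are rejected", {
  bad <- tibble::tibble(chrom = "chr1", start = 100L, end = 100L, fold_change = 9)
  expect_error(consensus_peaks(list(bad)), "start must be < end")
})

test_that("differential peaks apply retention and dual thresholds", {
  null_tab <- tibble::tibble(log2_conc = rep(6, 10), log2_fc = 0, fdr = 0.5)
  expect_equal(differential_peaks(null_tab)$unaffected_fraction, 1.0)

  # inclusive |log2FC| >= 1, strict FDR < 1e-4
  edge <- tibble::tibble(
    log2_conc = 6,
    log2_fc = c(1, -1, 1, 0.99),
    fdr = c(1e-5, 1e-5, 1e-4, 1e-6)
  )
  res <- differential_peaks(edge)
  expect_equal(res$peaks$differential, c(TRUE, TRUE, FALSE, FALSE))

  # retention: log2 concentration >= 5 in at least one condition
  two_cond <- tibble::tibble(
    log2_conc_a = c(6, 4, 4), log2_conc_b = c(4, 5, 4.9),
    log2_fc = 2, fdr = 1e-9
  )
  res2 <- differential_peaks(two_cond)
  expect_equal(res2$peaks$retained, c(TRUE, TRUE, FALSE))

  # toy table: 40 retained peaks, exactly 1 differential -> 0.975 unaffected
  toy <- tibble::tibble(
    log2_conc = rep(6, 40),
    log2_fc = c(1.5, rep(0.2, 39)),
    fdr = c(1e-6, rep(0.3, 39))
  )
  res3 <- differential_peaks(toy)
  expect_equal(res3$unaffected_fraction, 0.975)

  # row-order invariance
  shuffled <- toy[withr::with_seed(5, sample(nrow(toy))), ]
  expect_equal(differential_peaks(shuffled)$unaffected_fraction, 0.975)

  # BH fallback only on request
  noFdr <- tibble::tibble(log2_conc = 6, log2_fc = 2, p_value = 1e-9)
  expect_error(differential_peaks(noFdr), "fdr")
  expect_equal(differential_peaks(noFdr, compute_fdr = TRUE)$n_differential, 1)
})
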