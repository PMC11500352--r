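test_that("editing ratio is the mismatch fraction of coverage", {
  expect_equal(editing_ratio(3, 10), 0.3)
  expect_equal(editing_ratio(0, 10), 0)
  expect_equal(editing_ratio(10, 10), 1)
  expect_error(editing_ratio(11, 10), "0 <= m <= c")
  expect_error(editing_ratio(1, 0), "positive")
})

test_that("a site failing coverage in one sample is dropped for all", {
  cov <- matrix(c(12, 15, 11, 40,
                  12, 9, 11, 40), nrow = 2, byrow = TRUE)
  sc <- manual_counts(2L, cov, ag = 0L)
  elig <- site_eligibility(sc, "AG", run_config(min_coverage = 10))
  expect_equal(elig, c(TRUE, FALSE))
  # non-matching reference base is ineligible regardless of coverage
  sc2 <- manual_counts(1L, matrix(50, 1, 4), 0L, ref = "C")
  expect_false(site_eligibility(sc2, "AG", run_config()))
  expect_true(site_eligibility(sc2, "CT", run_config()))
})

test_that("mismatch counts are absent (NA), not zero, off the reference base", {
  sc <- manual_counts(2L, matrix(10, 2, 4), matrix(3, 2, 4),
                      ref = c("A", "C"))
  m <- mismatch_count(sc, "a1", "AG")
  expect_equal(m[1], 3L)
  expect_true(is.na(m[2]))
  expect_error(mismatch_count(sc, "a1", "AA"), "mismatch class")
})

test_that("window signals sum eligible ratios and deltas difference set means", {
  # 3 positions in one window; per-sample A->G ratios chosen by hand
  cov <- matrix(10L, 3, 4)
  ag <- cbind(c(1L, 2L, 0L), c(3L, 0L, 0L), c(5L, 0L, 0L), c(2L, 2L, 2L))
  sc <- manual_counts(3L, cov, ag)
  cfg <- run_config(window_size = 51, min_coverage = 10)
  ds <- build_delta_sets(sc, tile_windows(fixture_regions(len = 3L), 51), cfg)
  ag_tab <- ds[["AG"]]
  expect_equal(nrow(ag_tab), 1L)
  expect_equal(ag_tab$n_sites, 3L)
  e <- attr(ag_tab, "signals")
  expect_equal(as.vector(e), c(0.3, 0.3, 0.5, 0.6))
  expect_equal(ag_tab$z1, 0.3)             # mean of {0.3, 0.3}
  expect_equal(ag_tab$z2, 0.55)            # mean of {0.5, 0.6}
  expect_equal(ag_tab$delta, 0.25)
})

test_that("swapping the sample sets negates every delta", {
  set.seed(71)
  for (rep in 1:5) {
    sc <- random_site_counts(n_windows = 4L, window_size = 8L)
    swapped <- site_counts(sc$sites, sc$counts, set1 = sc$set2,
                           set2 = sc$set1)
    cfg <- run_config(window_size = 8, min_coverage = 5)
    win <- tile_windows(fixture_regions(len = 32L), 8)
    d1 <- build_delta_sets(sc, win, cfg)
    d2 <- build_delta_sets(swapped, win, cfg)
    for (cl in mismatch_classes()) {
      expect_equal(d1[[cl]]$window_id, d2[[cl]]$window_id)
      expect_equal(d1[[cl]]$delta, -d2[[cl]]$delta)
    }
  }
})

test_that("identical count tables in both sets give zero deltas everywhere", {
  set.seed(72)
  base <- random_site_counts(n_windows = 3L, window_size = 10L, n1 = 2L,
                             n2 = 2L)
  # mirror set1's counts into set2
  arr <- base$counts
  arr[, , base$set2] <- arr[, , base$set1]
  sc <- site_counts(base$sites, arr, base$set1, base$set2)
  ds <- build_delta_sets(sc, tile_windows(fixture_regions(), 10),
                         run_config(window_size = 10, min_coverage = 3))
  for (cl in mismatch_classes())
    expect_true(all(ds[[cl]]$delta == 0))
})

test_that("a constant variant signal shared by all samples cancels in delta", {
  # homozygous-SNP construction: add the same mismatch fraction at one site
  # to every sample of both sets; window deltas must not move
  cov <- matrix(100L, 4, 4)
  ag <- matrix(c(10L, 12L, 30L, 35L), 4, 4, byrow = TRUE)
  sc <- manual_counts(4L, cov, ag)
  cfg <- run_config(window_size = 10, min_coverage = 10)
  win <- tile_windows(fixture_regions(len = 4L), 10)
  d_before <- build_delta_sets(sc, win, cfg)[["AG"]]$delta

  arr <- sc$counts
  arr[2, "A", ] <- arr[2, "A", ] - 40L   # same 0.4 fraction, every sample
  arr[2, "G", ] <- arr[2, "G", ] + 40L
  sc_snp <- site_counts(sc$sites, arr, sc$set1, sc$set2)
  d_after <- build_delta_sets(sc_snp, win, cfg)[["AG"]]$delta
  expect_equal(d_after, d_before, tolerance = 1e-12)
})

test_that("delta sets match the brute-force reference on random tables", {
  set.seed(99)
  for (rep in 1:10) {
    sc <- random_site_counts(n_windows = sample(2:5, 1),
                             window_size = 6L,
                             n1 = sample(1:3, 1), n2 = sample(1:3, 1))
    len <- max(sc$sites$pos) + 1L
    cfg <- run_config(window_size = 6, min_coverage = sample(0:6, 1),
                      snp_filter = sample(c(TRUE, FALSE), 1))
    win <- tile_windows(fixture_regions(len = len), 6)
    got <- build_delta_sets(sc, win, cfg)
    want <- oracle_delta_sets(sc, win, cfg)
    for (cl in mismatch_classes()) {
      expect_equal(got[[cl]]$window_id, want[[cl]]$window_id)
      expect_equal(got[[cl]]$n_sites, want[[cl]]$n_sites)
      expect_identical(got[[cl]]$delta, want[[cl]]$delta)
      expect_identical(got[[cl]]$z1, want[[cl]]$z1)
      expect_identical(got[[cl]]$z2, want[[cl]]$z2)
    }
  }
})
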