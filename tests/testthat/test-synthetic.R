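test_that("identical parameters and seed give identical count tables", {
  a <- simulate_editing_counts(n_regions = 3L, region_length = 60L, seed = 5)
  b <- simulate_editing_counts(n_regions = 3L, region_length = 60L, seed = 5)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)
  c <- simulate_editing_counts(n_regions = 3L, region_length = 60L, seed = 6)
  expect_false(identical(a$counts$counts, c$counts$counts))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(77)
  x1 <- runif(3)
  set.seed(77)
  invisible(simulate_editing_counts(n_regions = 1L, region_length = 20L,
                                    seed = 9))
  x2 <- runif(3)
  expect_identical(x1, x2)
})

test_that("the noise-free null shows only reference bases and zero deltas", {
  sim <- simulate_editing_counts(n_set1 = 2L, n_set2 = 2L, n_regions = 2L,
                                 region_length = 102L, error_rate = 0,
                                 editing_site_density = 0, seed = 8)
  sc <- sim$counts
  for (s in sc$samples) {
    obs <- sc$counts[, , s]
    nonref <- obs[cbind(seq_len(nrow(obs)),
                        match(sc$sites$ref, colnames(obs)))] != rowSums(obs)
    expect_false(any(nonref))
  }
  ds <- build_delta_sets(sc, sim$windows, run_config(min_coverage = 10))
  expect_true(all(ds[["AG"]]$delta == 0))
  expect_true(all(vapply(ds, function(d) all(d$delta == 0), TRUE)))
})

test_that("planted windows carry their closed-form expected delta", {
  plant <- data.frame(window = c(3L, 8L), delta_level = 0.2)
  sim <- simulate_editing_counts(n_set1 = 3L, n_set2 = 3L, n_regions = 1L,
                                 region_length = 510L, coverage_mean = 400,
                                 coverage_dispersion = 50,
                                 error_rate = 0.001,
                                 editing_site_density = 0.05,
                                 planted_windows = plant, seed = 21)
  tw <- sim$truth$windows
  expect_equal(which(tw$planted), c(3L, 8L))
  # expected delta = sum over the window's edited sites of (level2 - level1)
  sites <- sim$truth$sites
  widx <- widee:::assign_windows(sites, sim$windows)
  for (w in c(3L, 8L)) {
    manual <- sum((sites$level_set2 - sites$level_set1)[widx == w])
    expect_equal(tw$expected_delta[w], manual)
    expect_gt(manual, 0)
  }
  # at high coverage the realized delta concentrates near the expectation
  ds <- build_delta_sets(sim$counts, sim$windows,
                         run_config(min_coverage = 10))[["AG"]]
  for (w in c(3L, 8L)) {
    row <- match(sim$windows$window_id[w], ds$window_id)
    expect_lt(abs(ds$delta[row] - tw$expected_delta[w]),
              0.25 * tw$expected_delta[w] + 0.1)
  }
  # unplanted windows have zero expectation
  expect_true(all(tw$expected_delta[!tw$planted] == 0))
})

test_that("SNP sites move reference mass to the alternative base", {
  snp <- data.frame(chrom = "sim001", pos = 10L, alt = "G", frac = 1.0,
                    scope = "both")
  sim <- simulate_editing_counts(n_set1 = 2L, n_set2 = 2L, n_regions = 1L,
                                 region_length = 51L, coverage_mean = 60,
                                 error_rate = 0, editing_site_density = 0,
                                 snp_sites = snp, seed = 13)
  sc <- sim$counts
  ref <- sc$sites$ref[11]
  alt_counts <- sc$counts[11, "G", ]
  cov <- site_coverage(sc)[11, ]
  if (ref != "G") expect_equal(unname(alt_counts), unname(cov))
  # with the filter on, the homozygous site is excluded for its class
  if (ref == "A") {
    cfg_on <- run_config(snp_filter = TRUE, min_coverage = 10)
    expect_false(site_eligibility(sc, "AG", cfg_on)[11])
  }
  expect_error(simulate_editing_counts(
    snp_sites = data.frame(chrom = "sim001", pos = 9999L, alt = "G",
                           frac = 0.5), n_regions = 1L,
    region_length = 51L, seed = 1), "outside")
})

test_that("a class-specific error skew breaks noise symmetry measurably", {
  base <- simulate_editing_counts(n_regions = 4L, region_length = 255L,
                                  error_rate = 0.02,
                                  editing_site_density = 0, seed = 55)
  skew <- simulate_editing_counts(n_regions = 4L, region_length = 255L,
                                  error_rate = 0.02,
                                  editing_site_density = 0,
                                  error_skew = c(CT = 5), seed = 55)
  ct_base <- sum(base$counts$counts[base$counts$sites$ref == "C", "T", ])
  ct_skew <- sum(skew$counts$counts[skew$counts$sites$ref == "C", "T", ])
  expect_gt(ct_skew, ct_base * 2)
})
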