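test_that("tail counts follow the sign-dependent extremity rule", {
  v <- c(-3, -2, -1, 1, 2)
  expect_equal(tail_count(v, -2), 2L)      # values <= -2
  expect_equal(tail_count(v, 1.5), 1L)     # values >= 1.5
  expect_equal(tail_count(v, -10), 0L)
  expect_equal(tail_count(v, 10), 0L)
  expect_equal(tail_count(v, 0), 5L)       # zero is maximally non-extreme
  # vectorized path agrees with the scalar definition
  set.seed(5)
  vals <- round(rnorm(40), 2)
  d0 <- c(round(rnorm(25), 2), 0, vals[1:5])
  expect_equal(widee:::tail_count_vec(sort(vals), d0),
               vapply(d0, function(x) tail_count(vals, x), 0L))
})

test_that("per-decoy q estimates are capped tail-count ratios", {
  foc <- c(-3, -2, -1, 1, 2)
  dec <- c(-1, -0.5, 0.5)
  expect_equal(empirical_q(-2, foc, dec), 0)        # 0 / 2
  expect_equal(empirical_q(-1, foc, dec), 1 / 3)    # 1 / 3
  # decoy identical to focal gives 1 for every member
  for (d0 in foc) expect_equal(empirical_q(d0, foc, foc), 1)
  # noisier decoy than focal is capped at 1
  expect_equal(empirical_q(-3, foc, c(-5, -4, -3.5)), 1)
  expect_true(is.na(empirical_q(-2, foc, numeric(0))))
  # size normalization rescales the decoy count by the set-size ratio
  expect_equal(empirical_q(-1, foc, dec, size_normalize = TRUE),
               (1 * 5 / 3) / 3)
})

test_that("the decoy aggregate is the median of available estimates", {
  expect_equal(aggregate_decoys(rep(0, 11)), 0)
  expect_equal(aggregate_decoys(c(0, 0.5, 1)), 0.5)
  expect_equal(aggregate_decoys(c(0.1, 0.2, 0.3, 0.4)), 0.25)
  expect_equal(aggregate_decoys(c(0.3, NA, 0.7)), 0.5)
  expect_error(aggregate_decoys(c(NA_real_, NA_real_)), "no decoy")
})

test_that("monotonization is a running minimum within each sign tail", {
  # spec sequence by growing |delta| in one tail
  d <- c(-1, -2, -3, -4)
  expect_equal(monotonize_q(d, c(0.5, 0.3, 0.4, 0.1)), c(0.5, 0.3, 0.3, 0.1))
  # an already non-increasing sequence is a fixed point
  expect_equal(monotonize_q(d, c(0.8, 0.5, 0.2, 0.1)), c(0.8, 0.5, 0.2, 0.1))
  expect_equal(monotonize_q(-1, 0.7), 0.7)
  # tails are monotonized independently; zero deltas keep their raw q
  d <- c(-1, -2, 1, 2, 0)
  q <- monotonize_q(d, c(0.2, 0.6, 0.9, 0.3, 0.4))
  expect_equal(q, c(0.2, 0.2, 0.9, 0.3, 0.4))
  # identical deltas get identical q regardless of input order
  q <- monotonize_q(c(-1, -1, -2), c(0.5, 0.2, 0.8))
  expect_equal(q[1], q[2])
  expect_equal(q, c(0.2, 0.2, 0.2))
})

test_that("monotonized q matches the quadratic-time definition on random input", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(1:40, 1)
    d <- round(rnorm(n), 1)              # induces ties and zeros
    q_raw <- round(runif(n), 2)
    got <- monotonize_q(d, q_raw)
    want <- pmin(q_raw, 1)
    for (i in seq_len(n)) {
      if (d[i] == 0) next
      sel <- sign(d) == sign(d[i]) & abs(d) <= abs(d[i])
      want[i] <- min(q_raw[sel])
    }
    expect_equal(got, want)
    # tail monotonicity holds by construction
    for (side in c(-1, 1)) {
      t <- which(sign(d) == side)
      o <- t[order(abs(d[t]))]
      expect_true(all(diff(got[o]) <= 1e-15))
    }
  }
})

test_that("focal q values are decoy-order invariant and oracle-exact", {
  set.seed(23)
  cfg <- run_config(window_size = 6, min_coverage = 4)
  for (rep in 1:10) {
    sc <- random_site_counts(n_windows = 5L, window_size = 6L)
    win <- tile_windows(fixture_regions(len = 30L), 6)
    ds <- build_delta_sets(sc, win, cfg)
    res <- qvalues_for_focal(ds, cfg)
    want <- oracle_qvalues(lapply(ds, function(d) list(delta = d$delta)),
                           "AG")
    expect_equal(res$q_raw, want$q_raw)
    expect_equal(res$q, want$q_final)
    # permuting the decoy classes cannot change the median
    perm <- c("AG", sample(setdiff(names(ds), "AG")))
    res2 <- qvalues_for_focal(ds[perm], cfg)
    expect_equal(res2$q_raw, res$q_raw)
    expect_equal(res2$q, res$q)
  }
})

test_that("identical delta sets for all twelve classes give q = 1 everywhere", {
  set.seed(31)
  sc <- random_site_counts(n_windows = 5L, window_size = 6L)
  win <- tile_windows(fixture_regions(len = 30L), 6)
  cfg <- run_config(window_size = 6, min_coverage = 4)
  focal_tab <- build_delta_sets(sc, win, cfg)[["AG"]]
  ds <- setNames(rep(list(focal_tab), 12L), mismatch_classes())
  class(ds) <- "delta_sets"
  res <- qvalues_for_focal(ds, cfg)
  qhat <- as.matrix(res[, grep("^qhat\\.", names(res))])
  expect_true(all(qhat == 1))             # before aggregation
  expect_true(all(res$q_raw == 1))
  expect_true(all(res$q == 1))            # and after monotonization
})

test_that("well-separated focal tails get q near zero", {
  ds <- list(AG = data.frame(delta = c(-9, -8, -7, 0.01, -0.02)))
  for (cl in setdiff(mismatch_classes(), "AG"))
    ds[[cl]] <- data.frame(delta = runif(30, -0.05, 0.05))
  cfg <- run_config()
  res <- qvalues_for_focal(ds, cfg)
  expect_equal(res$q[1:3], c(0, 0, 0))
  # empty focal set warns and returns an empty frame
  ds$AG <- data.frame(delta = numeric(0))
  expect_warning(res0 <- qvalues_for_focal(ds, cfg), "no windows")
  expect_equal(nrow(res0), 0L)
})
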