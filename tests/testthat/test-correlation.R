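test_that("segmented intensity correlations equal the brute-force oracle", {
  set <- toy_set()
  for (tau in 1:5) {
    for (ch in list(c("acceptor", "acceptor"), c("donor", "donor"),
                    c("donor", "acceptor"), c("sum", "sum"))) {
      got <- intensity_correlation(set, ch[1], ch[2], max_lag = 5)
      want <- oracle_intensity_correlation(set, ch[1], ch[2], tau)
      expect_equal(got$value[got$lag == tau], want, tolerance = 1e-12)
    }
  }
  # lags beyond every burst are undefined
  g <- intensity_correlation(set, "sum", "sum", max_lag = 10)
  expect_true(is.na(g$value[g$lag == 9]))
  expect_equal(g$n_pairs[g$lag == 9], 0L)
})

test_that("constant intensity gives zero correlation at every lag", {
  set <- burst_set(list(toy_burst("c1", rep(10, 30), rep(15, 30)),
                        toy_burst("c2", rep(10, 20), rep(15, 20))))
  for (ch in c("donor", "acceptor", "sum")) {
    g <- intensity_correlation(set, ch, ch, max_lag = 10)
    expect_equal(g$value, rep(0, 10), tolerance = 1e-12)
  }
})

test_that("PR autocorrelation matches the oracle in both normalizations", {
  set <- toy_set()
  g_pl <- pr_autocorrelation(set, max_lag = 5, normalization = "per_lag")
  g_gl <- pr_autocorrelation(set, max_lag = 5, normalization = "global")
  for (tau in 1:5) {
    expect_equal(g_pl$value[g_pl$lag == tau],
                 oracle_pr_autocorr_perlag(set, tau), tolerance = 1e-12)
    expect_equal(g_gl$value[g_gl$lag == tau],
                 oracle_pr_autocorr_global(set, tau), tolerance = 1e-12)
  }
  # pair bookkeeping: bin 2 is invalid (corrected total -2), so every pair
  # touching it is dropped
  set2 <- burst_set(list(toy_burst("inv2", donor = c(5, 1, 6, 7, 8),
                                   acceptor = c(5, 1, 6, 7, 8),
                                   bg_d = 2, bg_a = 2)))
  g2 <- pr_autocorrelation(set2, max_lag = 2)
  expect_equal(g2$n_pairs[g2$lag == 1], 2L)
  expect_equal(g2$n_pairs[g2$lag == 2], 2L)
})

test_that("g(0) = 1 and |g| <= 1 (per-lag Pearson bounds)", {
  set <- simulate_burst_ensemble(quick_config(n_bursts = 60, seed = 20))
  g <- pr_autocorrelation(set, max_lag = 40)
  expect_identical(g$value[g$lag == 0], 1)
  expect_true(all(abs(g$value) <= 1 + 1e-12, na.rm = TRUE))
  gg <- pr_autocorrelation(set, max_lag = 5, normalization = "global")
  expect_identical(gg$value[gg$lag == 0], 1)
})

test_that("additive pair statistics reproduce the per-lag Pearson estimator exactly", {
  # the fast bootstrap path aggregates per-burst sufficient statistics;
  # with every burst counted once it must equal the reference estimator
  set <- simulate_burst_ensemble(quick_config(n_bursts = 25, seed = 60))
  lags <- 0:20
  st <- fretburst:::pr_pair_stats(set, lags)
  ones <- rep(1, length(set$bursts))
  vals <- fretburst:::pearson_from_stats(
    st$n %*% ones, st$sx %*% ones, st$sy %*% ones,
    st$sxy %*% ones, st$sxx %*% ones, st$syy %*% ones)
  ref <- pr_autocorrelation(set, lags = lags)
  expect_equal(as.numeric(vals), ref$value, tolerance = 1e-12)
  # and doubling a burst's weight equals duplicating that burst
  w <- ones; w[3] <- 2
  vals2 <- fretburst:::pearson_from_stats(
    st$n %*% w, st$sx %*% w, st$sy %*% w,
    st$sxy %*% w, st$sxx %*% w, st$syy %*% w)
  dup <- burst_set(c(set$bursts, set$bursts[3]), validate = FALSE)
  ref2 <- pr_autocorrelation(dup, lags = lags)
  expect_equal(as.numeric(vals2), ref2$value, tolerance = 1e-12)
})

test_that("time-reversal symmetry: G_xy(tau) equals G_yx(tau) on reversed bursts", {
  set <- toy_set()
  rev_set <- burst_set(lapply(set$bursts, function(b)
    binned_burst(b$id, rev(b$donor), rev(b$acceptor), b$bg_donor,
                 b$bg_acceptor, b$condition, b$bin_width)))
  g_xy <- intensity_correlation(set, "donor", "acceptor", max_lag = 4)
  g_yx_rev <- intensity_correlation(rev_set, "acceptor", "donor", max_lag = 4)
  expect_equal(g_xy$value, g_yx_rev$value, tolerance = 1e-12)
})

test_that("donor and acceptor are anticorrelated for FRET-switching molecules at constant brightness", {
  set <- simulate_burst_ensemble(quick_config(
    state_prs = c(0.3, 0.8), rates = c(10, 10), brightness = 30,
    bg_donor = 5, bg_acceptor = 5, n_bursts = 300, seed = 22))
  g <- intensity_correlation(set, "donor", "acceptor", max_lag = 5)
  expect_true(all(g$value < 0))
})

test_that("zero-variance PR series yields NA with per-lag normalization and errors globally", {
  set <- burst_set(list(toy_burst("z", donor = rep(5, 20), acceptor = rep(5, 20))))
  g <- pr_autocorrelation(set, max_lag = 3)
  expect_true(all(is.na(g$value[g$lag >= 1])))
  expect_error(pr_autocorrelation(set, max_lag = 3, normalization = "global"),
               "zero PR variance")
})
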