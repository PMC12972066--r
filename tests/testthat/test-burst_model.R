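test_that("burst and set constructors enforce the data invariants", {
  expect_error(toy_burst("x", donor = c(1, 2), acceptor = c(1, 2, 3)),
               "equal length")
  expect_error(toy_burst("x", donor = c(1, -2), acceptor = c(1, 2)),
               "non-negative")
  expect_error(toy_burst("x", donor = c(1.5, 2), acceptor = c(1, 2)),
               "non-negative integers")
  expect_error(toy_burst("x", donor = 1, acceptor = 1, bg_d = -1),
               "background")
  b <- toy_burst("x", donor = 0:3, acceptor = c(5, 5, 5, 5), bin_width = 1)
  expect_equal(n_bins(b), 4L)
  expect_equal(burst_duration(b), 4)
  expect_error(burst_set(list(b, b)), "duplicate burst id")
  b2 <- toy_burst("y", donor = 1, acceptor = 1, bin_width = 2)
  expect_error(burst_set(list(b, b2)), "bin_width")
})

test_that("background correction subtracts per-channel rates and keeps negatives", {
  b <- toy_burst("x", donor = c(15, 8, 10), acceptor = c(25, 18, 20),
                 bg_d = 10, bg_a = 20)
  corr <- correct_background(b)
  expect_equal(corr$donor, c(5, -2, 0))
  expect_equal(corr$acceptor, c(5, -2, 0))
  # zero background is the identity
  b0 <- toy_burst("y", donor = c(3, 4), acceptor = c(5, 6))
  expect_equal(correct_background(b0), list(donor = c(3, 4), acceptor = c(5, 6)))
})

test_that("bin-wise and burst-wise PR follow I_A/(I_D+I_A) with invalid-bin masking", {
  b <- toy_burst("x", donor = c(10, 0, 5, 3), acceptor = c(10, 10, 5, 7))
  s <- compute_bin_pr(b)
  expect_equal(s$pr[1], 0.5)
  expect_equal(s$pr[2], 1.0)
  expect_true(all(s$valid))
  # burst_pr over the last two bins: (5+7+10+10)... full-burst ratio
  expect_equal(s$burst_pr, sum(b$acceptor) / sum(b$donor + b$acceptor))
  # corrected bins D=[5,3], A=[5,7] -> burst_pr = 12/20
  b2 <- toy_burst("y", donor = c(5, 3), acceptor = c(5, 7))
  expect_equal(compute_bin_pr(b2)$burst_pr, 0.6)
  # a bin with corrected total <= 0 is invalid and PR is NA there
  b3 <- toy_burst("z", donor = c(10, 8), acceptor = c(20, 18),
                  bg_d = 10, bg_a = 20)
  s3 <- compute_bin_pr(b3)
  expect_equal(s3$valid, c(FALSE, FALSE))
  expect_true(all(is.na(s3$pr)))
  expect_true(attr(s3, "excluded"))
  expect_true(is.na(s3$burst_pr))
})

test_that("PR lies in [0,1] whenever both corrected intensities are non-negative, and burst_pr is the intensity-weighted mean of bin PRs", {
  with_seed(11, {
    for (rep in 1:20) {
      nb <- sample(5:50, 1)
      b <- toy_burst(paste0("r", rep),
                     donor = rpois(nb, 20), acceptor = rpois(nb, 25),
                     bg_d = 0, bg_a = 0)
      s <- compute_bin_pr(b)
      corr <- correct_background(b)
      nonneg <- corr$donor >= 0 & corr$acceptor >= 0 & s$valid
      expect_true(all(s$pr[nonneg] >= 0 & s$pr[nonneg] <= 1))
      # with no invalid bins, burst_pr == weighted mean of bin PRs
      if (all(s$valid)) {
        w <- corr$donor + corr$acceptor
        expect_equal(s$burst_pr, sum(w * s$pr) / sum(w))
      }
    }
  })
})

test_that("duration/intensity filtering matches the selection rules and is idempotent", {
  mk <- function(id, nb, level) {
    toy_burst(id, donor = rep(level, nb), acceptor = rep(level, nb))
  }
  set <- burst_set(list(
    mk("short", 99, 10),       # 99 ms -> removed (shorter than 100 ms)
    mk("edge", 100, 10),       # exactly 100 ms -> retained
    mk("bright", 150, 23),     # mean total 46 > 40 -> removed
    mk("ok", 150, 13)))        # 150 ms at 26 -> retained
  out <- filter_bursts(set)
  expect_setequal(burst_ids(out), c("edge", "ok"))
  expect_equal(attr(out, "removed"), c(short = 1L, bright = 1L))
  # idempotent; output is a subset of the input
  out2 <- filter_bursts(out)
  expect_equal(burst_ids(out2), burst_ids(out))
  expect_true(all(burst_ids(out) %in% burst_ids(set)))
})

test_that("filtering a synthetic ensemble removes exactly the sub-100-ms bursts", {
  set <- simulate_burst_ensemble(quick_config(
    duration_model = list(kind = "uniform", min = 40, max = 400),
    n_bursts = 120, seed = 21))
  durs <- vapply(set$bursts, burst_duration, numeric(1))
  out <- filter_bursts(set, max_mean_intensity = Inf)
  expect_equal(length(out$bursts), sum(durs >= 100))
  expect_setequal(burst_ids(out), burst_ids(set)[durs >= 100])
})

test_that("threshold burst detection recovers an injected burst and rejects degenerate input", {
  expect_error(detect_bursts(numeric(0), numeric(0), 10, 5, 5), ">= 1 bin")
  expect_error(detect_bursts(1:5, 1:5, 0, 0, 0), "rise_threshold")
  with_seed(31, {
    n <- 1000
    bg_d <- 12; bg_a <- 22
    donor <- rpois(n, bg_d); acceptor <- rpois(n, bg_a)
    # flat background-only trace: no bursts
    flat <- detect_bursts(donor, acceptor, 25, bg_d, bg_a)
    expect_equal(length(flat$bursts), 0L)
    # inject one 200-ms burst at +30 counts/ms split between the channels
    win <- 401:600
    donor[win] <- donor[win] + rpois(200, 12)
    acceptor[win] <- acceptor[win] + rpois(200, 18)
    det <- detect_bursts(donor, acceptor, 12, bg_d, bg_a)
    expect_equal(length(det$bursts), 1L)
    nb <- n_bins(det$bursts[[1]])
    expect_gt(nb, 150)   # overlaps most of the injected window
    expect_lt(nb, 260)
  })
})

test_that("Chung-Kennedy smoothing preserves steps and has the stated closed forms", {
  const <- rep(3.7, 25)
  expect_equal(chung_kennedy_smooth(const, window = 5, exponent = 10), const)
  # noiseless step preserved exactly, unlike a plain moving average
  step <- c(rep(0, 15), rep(1, 15))
  ck <- chung_kennedy_smooth(step, window = 5, exponent = 10)
  expect_equal(ck, step, tolerance = 1e-10)
  ma <- stats::filter(step, rep(1 / 5, 5), sides = 2)
  expect_gt(max(abs(ma[3:28] - step[3:28])), 0.3)
  # exponent 0: symmetric average of forward and backward running means
  with_seed(41, {
    x <- rnorm(40)
    K <- 7
    fwd <- vapply(seq_along(x), function(t) mean(x[max(1, t - K + 1):t]), 0)
    bwd <- vapply(seq_along(x), function(t) mean(x[t:min(length(x), t + K - 1)]), 0)
    expect_equal(chung_kennedy_smooth(x, window = K, exponent = 0),
                 (fwd + bwd) / 2)
  })
})
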