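test_that("the median split uses strict inequalities and leaves ties unlabeled", {
  # bin PRs 0.1, 0.3, 0.5, 0.7, 0.9 -> median 0.5; the 0.5 bin is neither
  set <- burst_set(list(toy_burst("m", donor = c(9, 7, 5, 3, 1),
                                  acceptor = c(1, 3, 5, 7, 9))))
  ms <- median_split(set)
  expect_equal(ms$median_pr, 0.5)
  expect_equal(ms$labels[[1]], c(-1L, -1L, NA, 1L, 1L))
  # all bins equal: everything ties, nothing is labeled
  same <- burst_set(list(toy_burst("s", rep(5, 10), rep(5, 10))))
  expect_true(all(is.na(median_split(same)$labels[[1]])))
})

test_that("conditional probabilities match brute-force pair enumeration", {
  with_seed(23, {
    for (rep in 1:5) {
      bursts <- lapply(1:4, function(i) {
        nb <- sample(6:15, 1)
        toy_burst(paste0("r", i), donor = rpois(nb, 10), acceptor = rpois(nb, 12))
      })
      set <- burst_set(bursts)
      rr <- recurrence_curves(set, taus = 1:4)
      for (tau in 1:4) {
        o <- oracle_recurrence(set, tau)
        row <- rr$curves[rr$curves$tau == tau, ]
        expect_identical(row$n_start_hf, as.numeric(o$n_hf))
        expect_identical(row$n_hf_hf, as.numeric(o$hf_hf))
        expect_identical(row$n_start_lf, as.numeric(o$n_lf))
        expect_equal(row$p_hf_given_hf, o$hf_hf / o$n_hf)
        expect_equal(row$p_hf_given_lf, o$lf_hf / o$n_lf)
      }
    }
  })
})

test_that("a 4-bin toy burst gives the enumerated conditionals", {
  # labels HF, HF, LF, HF by construction around median
  set <- burst_set(list(
    toy_burst("t", donor = c(2, 3, 8, 1), acceptor = c(8, 7, 2, 9)),
    toy_burst("pad", donor = c(5, 5, 5, 9), acceptor = c(5, 5, 5, 1))))
  ms <- median_split(set)
  lab <- ms$labels[[1]]
  expect_equal(lab, c(1L, 1L, -1L, 1L))
  rr <- recurrence_curves(set, taus = 1)
  # enumerated by hand: HF starts {bin1 -> HF, bin2 -> LF} plus the pad
  # burst's LF -> HF pair: p(HF|HF) = 1/2, p(HF|LF) = 2/2 = 1
  expect_equal(rr$curves$p_hf_given_hf[1], 1 / 2)
  expect_equal(rr$curves$p_hf_given_lf[1], 1)
  o <- oracle_recurrence(set, 1)
  expect_equal(rr$curves$p_hf_given_hf[1], o$hf_hf / o$n_hf)
  expect_equal(rr$curves$p_hf_given_lf[1], o$lf_hf / o$n_lf)
})

test_that("law of total probability holds exactly on pair counts", {
  set <- simulate_burst_ensemble(quick_config(n_bursts = 40, seed = 24))
  rr <- recurrence_curves(set, taus = c(1, 5, 20))
  cv <- rr$curves
  # P(HF at t | labeled start) as the weighted mix of the two conditionals
  p_mix <- (cv$n_hf_hf + cv$n_lf_hf) / (cv$n_start_hf + cv$n_start_lf)
  p_check <- (cv$p_hf_given_hf * cv$n_start_hf +
                cv$p_hf_given_lf * cv$n_start_lf) /
    (cv$n_start_hf + cv$n_start_lf)
  expect_equal(p_mix, p_check, tolerance = 1e-12)
})

test_that("fast-switching curves converge to the unconditional P(HF) at long delays", {
  cfg <- quick_config(state_prs = c(0.35, 0.75), rates = c(50, 50),
                      brightness = 40, bg_donor = 2, bg_acceptor = 2,
                      duration_model = list(kind = "uniform", min = 200, max = 400),
                      n_bursts = 300, seed = 25)
  set <- simulate_burst_ensemble(cfg)   # relaxation time 10 ms
  rr <- recurrence_curves(set, taus = c(1, 100, 150))
  cv <- rr$curves
  long <- cv$tau >= 100
  p_uncond <- (cv$n_hf_hf + cv$n_lf_hf) / (cv$n_start_hf + cv$n_start_lf)
  # 3-SE band on the conditionals at long delay
  se <- sqrt(0.25 / cv$n_start_hf[long])
  expect_true(all(abs(cv$p_hf_given_hf[long] - p_uncond[long]) < 3 * se + 0.01))
  expect_true(all(abs(cv$p_hf_given_lf[long] - p_uncond[long]) < 3 * se + 0.01))
  # and memory is visible at tau = 1 ms
  expect_gt(cv$p_hf_given_hf[1], cv$p_hf_given_lf[1] + 0.05)
})

test_that("conditional PR histograms relax to the unconditional distribution in the ergodic limit", {
  cfg <- quick_config(state_prs = c(0.35, 0.75), rates = c(50, 50),
                      brightness = 40, bg_donor = 2, bg_acceptor = 2,
                      duration_model = list(kind = "uniform", min = 200, max = 400),
                      n_bursts = 150, seed = 26)
  set <- simulate_burst_ensemble(cfg)
  h <- conditional_pr_histograms(set, taus = c(1, 150), n_bins = 25)
  # at tau = 150 >> relaxation time, conditional ~ unconditional (coarse L1)
  l1_long_hf <- sum(abs(h$conditional$tau_150$start_hf - h$unconditional))
  l1_short_hf <- sum(abs(h$conditional$tau_1$start_hf - h$unconditional))
  expect_lt(l1_long_hf, 0.12)
  expect_gt(l1_short_hf, l1_long_hf)
  # empty condition set warns and returns an all-zero histogram
  tiny <- burst_set(list(toy_burst("t", donor = c(4, 6, 5), acceptor = c(6, 4, 5))))
  expect_warning(h0 <- conditional_pr_histograms(tiny, taus = 2, n_bins = 5),
                 "empty conditional")
})

test_that("static-heterogeneity re-coloring leaves conditional histograms separated at long delays", {
  src <- simulate_burst_ensemble(quick_config(
    state_prs = c(0.3, 0.8), rates = c(0, 0),
    duration_model = list(kind = "uniform", min = 250, max = 450),
    n_bursts = 200, seed = 27))
  rec <- recolor_bursts(src, "static_heterogeneity", seed = 28)
  h <- conditional_pr_histograms(rec, taus = c(1, 200), n_bins = 25)
  # means of the two conditional distributions stay apart at tau = 200 ms
  m_hf <- sum(h$mids * h$conditional$tau_200$start_hf)
  m_lf <- sum(h$mids * h$conditional$tau_200$start_lf)
  expect_gt(m_hf - m_lf, 0.2)
})
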