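# Concatenate per-burst series into one vector separated by >= gap NAs, so a
# lagged pair (t, t+tau) with tau <= gap can never straddle two bursts. This
# turns every burst-edge-aware per-lag estimator into two vectorized slices.
pad_series <- function(series_list, gap) {
  pad <- rep(NA_real_, gap)
  n <- length(series_list)
  out <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    out[[2L * i - 1L]] <- series_list[[i]]
    out[[2L * i]] <- pad
  }
  unlist(out, use.names = FALSE)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

# Default lag grid for recurrence curves: log-spaced integers 1..max_tau.
log_tau_grid <- function(max_tau = 300, n = 25) {
  unique(pmax(1L, as.integer(round(10^seq(0, log10(max_tau), length.out = n)))))
}
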