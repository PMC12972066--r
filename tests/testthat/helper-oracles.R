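# Independent brute-force oracles: naive double loops over every burst and
# start time, written without reference to the package's vectorized
# estimators.

oracle_channel <- function(burst, channel) {
  d <- burst$donor - burst$bg_donor
  a <- burst$acceptor - burst$bg_acceptor
  switch(channel, donor = d, acceptor = a, sum = d + a)
}

# Segmented intensity correlation: sums restricted to bursts longer than tau.
oracle_intensity_correlation <- function(set, x, y, tau) {
  num <- 0; sx <- 0; sy <- 0; npair <- 0
  for (b in set$bursts) {
    xv <- oracle_channel(b, x); yv <- oracle_channel(b, y)
    Tk <- length(xv)
    if (Tk > tau) {
      for (t in 0:(Tk - tau - 1)) {
        num <- num + xv[t + 1] * yv[t + tau + 1]
        sx <- sx + xv[t + 1]
        sy <- sy + yv[t + tau + 1]
        npair <- npair + 1
      }
    }
  }
  num * npair / (sx * sy) - 1
}

oracle_bin_pr <- function(burst) {
  d <- burst$donor - burst$bg_donor
  a <- burst$acceptor - burst$bg_acceptor
  ifelse(d + a > 0, a / (d + a), NA_real_)
}

# Paired PR samples at one lag (both bins valid, same burst).
oracle_pr_pairs <- function(set, tau) {
  a <- numeric(0); b <- numeric(0)
  for (burst in set$bursts) {
    p <- oracle_bin_pr(burst)
    n <- length(p)
    if (n > tau) for (t in seq_len(n - tau)) {
      if (!is.na(p[t]) && !is.na(p[t + tau])) {
        a <- c(a, p[t]); b <- c(b, p[t + tau])
      }
    }
  }
  list(a = a, b = b)
}

# Per-lag Pearson normalization (the n/(n-1) factors cancel, so stats::cor
# is an exact independent reference).
oracle_pr_autocorr_perlag <- function(set, tau) {
  pp <- oracle_pr_pairs(set, tau)
  stats::cor(pp$a, pp$b)
}

# Grand-mean normalization: lagged covariance about the global mean over its
# lag-0 value.
oracle_pr_autocorr_global <- function(set, tau) {
  allp <- unlist(lapply(set$bursts, oracle_bin_pr))
  gm <- mean(allp, na.rm = TRUE)
  pp <- oracle_pr_pairs(set, tau)
  num <- mean((pp$a - gm) * (pp$b - gm))
  den <- mean((allp[!is.na(allp)] - gm)^2)
  num / den
}

# Recurrence pair counts by explicit enumeration of (t - tau, t) pairs.
oracle_recurrence <- function(set, tau) {
  allp <- unlist(lapply(set$bursts, oracle_bin_pr))
  med <- stats::median(allp, na.rm = TRUE)
  hf_hf <- 0; n_hf <- 0; lf_hf <- 0; n_lf <- 0
  for (burst in set$bursts) {
    p <- oracle_bin_pr(burst)
    n <- length(p)
    if (n > tau) for (t in (tau + 1):n) {
      p0 <- p[t - tau]; p1 <- p[t]
      if (is.na(p0) || is.na(p1) || p0 == med || p1 == med) next
      if (p0 > med) { n_hf <- n_hf + 1; if (p1 > med) hf_hf <- hf_hf + 1 }
      else { n_lf <- n_lf + 1; if (p1 > med) lf_hf <- lf_hf + 1 }
    }
  }
  list(median = med, hf_hf = hf_hf, n_hf = n_hf, lf_hf = lf_hf, n_lf = n_lf)
}

oracle_msd <- function(x, y, tau) {
  n <- length(x)
  acc <- 0
  for (t in seq_len(n - tau)) acc <- acc + (x[t + tau] - x[t])^2 + (y[t + tau] - y[t])^2
  acc / (n - tau)
}
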