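new_correlation_curve <- function(kind, lags, values, n_pairs,
                                  normalization = NULL) {
  structure(
    data.frame(lag = lags, value = values, n_pairs = n_pairs,
               ci_low = NA_real_, ci_high = NA_real_),
    class = c("correlation_curve", "data.frame"),
    kind = kind, normalization = normalization)
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat("<correlation_curve> kind ", attr(x, "kind"),
      if (!is.null(attr(x, "normalization")))
        paste0(" (", attr(x, "normalization"), ")"),
      ", ", nrow(x), " lags\n", sep = "")
  print.data.frame(utils::head(x, 6L), row.names = FALSE, digits = 4)
  if (nrow(x) > 6L) cat("  ... (", nrow(x) - 6L, " more lags)\n", sep = "")
  invisible(x)
}

# Corrected intensity series per burst for one channel.
channel_series <- function(set, channel) {
  lapply(set$bursts, function(b) {
    corr <- correct_background(b)
    switch(channel,
           donor = corr$donor,
           acceptor = corr$acceptor,
           sum = corr$donor + corr$acceptor)
  })
}

#' Burst-edge-aware intensity correlation function
#'
#' Segmented correlation estimator for finite bursts: for each lag `tau` (in
#' bins) only bursts longer than `tau` contribute, products and marginal sums
#' run over `t = 0 ... T_k - tau - 1` within each qualifying burst, and
#'
#' `G(tau) = (sum_k sum_t X_k(t) Y_k(t+tau)) * (sum_k (T_k - tau)) /
#'           ((sum_k sum_t X_k(t)) * (sum_k sum_t Y_k(t+tau))) - 1`
#'
#' so that a constant signal gives `G = 0` at every lag. Intensities are
#' background-corrected.
#'
#' @param set A filtered `burst_set`.
#' @param x,y Channels: `"donor"`, `"acceptor"`, or `"sum"`.
#' @param max_lag Maximum lag in bins (= ms at 1-ms binning).
#' @param lags Optional explicit lag vector (>= 1).
#' @return A `correlation_curve` with kind `"DxD"`, `"AxA"`, `"DxA"`, etc.;
#'   `NA` value where no burst qualifies or a marginal sum vanishes.
#' @export
intensity_correlation <- function(set, x = "acceptor", y = x, max_lag = 300,
                                  lags = NULL) {
  x <- match.arg(x, c("donor", "acceptor", "sum"))
  y <- match.arg(y, c("donor", "acceptor", "sum"))
  if (is.null(lags)) lags <- seq_len(max_lag)
  stopifnot(all(lags >= 1), all(lags == floor(lags)))
  gap <- max(lags)
  xv <- pad_series(channel_series(set, x), gap)
  yv <- if (y == x) xv else pad_series(channel_series(set, y), gap)
  L <- length(xv)
  vals <- rep(NA_real_, length(lags)); np <- integer(length(lags))
  for (j in seq_along(lags)) {
    tau <- lags[j]
    a <- xv[seq_len(L - tau)]
    b <- yv[seq_len(L - tau) + tau]
    ok <- !is.na(a) & !is.na(b)
    n <- sum(ok)
    np[j] <- n
    if (n == 0L) next
    sx <- sum(a[ok]); sy <- sum(b[ok])
    if (sx == 0 || sy == 0) next
    vals[j] <- sum(a[ok] * b[ok]) * n / (sx * sy) - 1
  }
  abbr <- c(donor = "D", acceptor = "A", sum = "sum")
  new_correlation_curve(paste0(abbr[[x]], "x", abbr[[y]]), lags, vals, np)
}

#' Normalized PR autocorrelation function
#'
#' Autocorrelation of the bin-wise PR across all bursts, aware of burst edges:
#' a pair `(t, t + tau)` contributes only when both bins lie inside the same
#' burst and both are valid.
#'
#' Two normalizations are available. `"per_lag"` (default, used for all
#' figures) is the Pearson correlation coefficient of the paired samples
#' `PR(t)` and `PR(t + tau)` at each lag: means and SDs are computed over
#' exactly the contributing index sets, so `g` lies in `[-1, 1]` and
#' `g(0) = 1`. `"global"` divides the lagged covariance about the single
#' grand-mean PR by its lag-0 value.
#'
#' @param set A filtered `burst_set`.
#' @param max_lag Maximum lag in bins.
#' @param normalization `"per_lag"` or `"global"`.
#' @param lags Optional explicit lag vector (>= 0); defaults to `0:max_lag`.
#' @return A `correlation_curve` of kind `"PRxPR"`; `NA` where undefined
#'   (no pairs, or zero variance at that lag).
#' @export
pr_autocorrelation <- function(set, max_lag = 300,
                               normalization = c("per_lag", "global"),
                               lags = NULL) {
  normalization <- match.arg(normalization)
  if (is.null(lags)) lags <- 0:max_lag
  stopifnot(all(lags >= 0), all(lags == floor(lags)))
  gap <- max(lags, 1L)
  v <- pad_series(pr_list(set), gap)
  L <- length(v)
  vals <- rep(NA_real_, length(lags)); np <- integer(length(lags))
  if (normalization == "global") {
    gm <- mean(v, na.rm = TRUE)
    d <- v - gm
    denom <- mean(d[!is.na(d)]^2)
    if (!is.finite(denom) || denom <= 0)
      stop("zero PR variance: global normalization undefined", call. = FALSE)
  }
  for (j in seq_along(lags)) {
    tau <- lags[j]
    a <- v[seq_len(L - tau)]
    b <- v[seq_len(L - tau) + tau]
    ok <- !is.na(a) & !is.na(b)
    n <- sum(ok)
    np[j] <- n
    if (n == 0L) next
    a <- a[ok]; b <- b[ok]
    if (normalization == "per_lag") {
      mu_a <- mean(a); mu_b <- mean(b)
      va <- mean((a - mu_a)^2); vb <- mean((b - mu_b)^2)
      if (va <= 0 || vb <= 0) next
      vals[j] <- mean((a - mu_a) * (b - mu_b)) / sqrt(va * vb)
    } else {
      vals[j] <- mean((a - gm) * (b - gm)) / denom
    }
  }
  new_correlation_curve("PRxPR", lags, vals, np, normalization)
}

# Per-burst, per-lag sufficient statistics of the per-lag Pearson estimator:
# pair count and the sums of a, b, a*b, a^2, b^2 over valid (t, t+tau) pairs
# within each burst. Additive across bursts, which makes burst-level
# bootstrap a weighted sum instead of a full re-walk of the data.
pr_pair_stats <- function(set, lags) {
  prs <- pr_list(set)
  nb <- length(prs)
  nl <- length(lags)
  out <- lapply(1:6, function(i) matrix(0, nl, nb))
  names(out) <- c("n", "sx", "sy", "sxy", "sxx", "syy")
  for (k in seq_len(nb)) {
    p <- prs[[k]]
    m <- as.numeric(!is.na(p))
    z <- ifelse(is.na(p), 0, p)
    z2 <- z * z
    n_k <- length(p)
    for (j in seq_len(nl)) {
      tau <- lags[j]
      if (tau >= n_k && tau > 0) next
      i1 <- seq_len(n_k - tau)
      i2 <- i1 + tau
      m1 <- m[i1]; m2 <- m[i2]
      out$n[j, k] <- sum(m1 * m2)
      out$sx[j, k] <- sum(z[i1] * m2)
      out$sy[j, k] <- sum(m1 * z[i2])
      out$sxy[j, k] <- sum(z[i1] * z[i2])
      out$sxx[j, k] <- sum(z2[i1] * m2)
      out$syy[j, k] <- sum(m1 * z2[i2])
    }
  }
  out
}

# Per-lag Pearson values from aggregated pair sums (one column per lag set).
pearson_from_stats <- function(n, sx, sy, sxy, sxx, syy) {
  vx <- sxx - sx^2 / n
  vy <- syy - sy^2 / n
  val <- (sxy - sx * sy / n) / sqrt(vx * vy)
  val[!is.finite(val) | n == 0 | vx <= 0 | vy <= 0] <- NA_real_
  val
}

# Fast burst-bootstrap of the per-lag PR autocorrelation: resampling a burst
# w times multiplies its (additive) pair sums by w, so each replicate is six
# matrix-vector products. Exactly equivalent to rerunning the estimator on
# the resampled set; used by analyze_bursts for CI bands.
boot_pr_autocorrelation <- function(set, lags, n_resamples = 200,
                                    level = 0.95) {
  st <- pr_pair_stats(set, lags)
  nb <- length(set$bursts)
  w <- matrix(0, nb, n_resamples)
  for (r in seq_len(n_resamples))
    w[, r] <- tabulate(sample.int(nb, nb, replace = TRUE), nbins = nb)
  reps <- pearson_from_stats(st$n %*% w, st$sx %*% w, st$sy %*% w,
                             st$sxy %*% w, st$sxx %*% w, st$syy %*% w)
  alpha <- (1 - level) / 2
  list(ci_low = apply(reps, 1L, stats::quantile, probs = alpha,
                      na.rm = TRUE, names = FALSE, type = 6),
       ci_high = apply(reps, 1L, stats::quantile, probs = 1 - alpha,
                       na.rm = TRUE, names = FALSE, type = 6))
}

#' Fit a single-exponential relaxation time to a correlation curve
#'
#' Log-linear least squares of `g(tau) = A exp(-tau / tau_r)` over the lags in
#' `lag_range` whose value exceeds `min_value` (log of non-positive values is
#' undefined; very small values are noise-dominated).
#'
#' @param curve A `correlation_curve`.
#' @param lag_range Two-element range of lags (bins) to fit.
#' @param min_value Smallest usable correlation value.
#' @return List with `tau_r` (relaxation time, bins), `amplitude`, and
#'   `n_points` used.
#' @export
fit_relaxation_time <- function(curve, lag_range = c(1, 150),
                                min_value = 0.02) {
  sel <- curve$lag >= lag_range[1L] & curve$lag <= lag_range[2L] &
    !is.na(curve$value) & curve$value > min_value
  if (sum(sel) < 3L)
    stop("fewer than 3 usable points in the fit range", call. = FALSE)
  fit <- stats::lm(log(curve$value[sel]) ~ curve$lag[sel])
  slope <- unname(stats::coef(fit)[2L])
  if (slope >= 0)
    warning("non-decaying correlation curve; relaxation time is not meaningful")
  list(tau_r = -1 / slope, amplitude = exp(unname(stats::coef(fit)[1L])),
       n_points = sum(sel))
}
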