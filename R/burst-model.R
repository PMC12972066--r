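#' Construct a single binned two-channel burst
#'
#' A burst is a contiguous stretch of elevated donor/acceptor fluorescence
#' from one trapped molecule, binned on a fixed time grid (1 ms by default).
#' Counts are raw (uncorrected) photon counts per bin; the per-burst
#' background rates are stored alongside so that background correction can be
#' applied burst-by-burst (background drifts between trapping events).
#'
#' Bins are half-open intervals `[t, t + bin_width)` indexed from 0; the burst
#' duration is `n_bins * bin_width` milliseconds.
#'
#' @param id Character scalar, unique within a [burst_set()].
#' @param donor,acceptor Non-negative integer vectors of equal length: raw
#'   photon counts per bin in the donor and acceptor channels.
#' @param bg_donor,bg_acceptor Background rates in counts per bin (>= 0).
#' @param condition Character label for the experimental condition
#'   (e.g. `"APO"`, `"NECA"`).
#' @param bin_width Bin width in milliseconds.
#' @param ground_truth Optional numeric vector of per-bin true PR values
#'   (synthetic data only), same length as the count vectors.
#' @return An object of class `binned_burst`.
#' @export
binned_burst <- function(id, donor, acceptor, bg_donor, bg_acceptor,
                         condition = "NA", bin_width = 1,
                         ground_truth = NULL) {
  b <- structure(
    list(id = as.character(id), condition = as.character(condition),
         bin_width = as.numeric(bin_width),
         donor = as.numeric(donor), acceptor = as.numeric(acceptor),
         bg_donor = as.numeric(bg_donor), bg_acceptor = as.numeric(bg_acceptor),
         ground_truth = if (is.null(ground_truth)) NULL else as.numeric(ground_truth)),
    class = "binned_burst")
  validate_burst(b)
  b
}

validate_burst <- function(b) {
  n <- length(b$donor)
  if (n < 1L || length(b$acceptor) != n)
    stop("burst '", b$id, "': donor/acceptor count vectors must have equal length >= 1",
         call. = FALSE)
  if (anyNA(b$donor) || anyNA(b$acceptor) ||
      any(b$donor < 0) || any(b$acceptor < 0) ||
      any(b$donor != floor(b$donor)) || any(b$acceptor != floor(b$acceptor)))
    stop("burst '", b$id, "': counts must be non-negative integers", call. = FALSE)
  if (length(b$bg_donor) != 1L || length(b$bg_acceptor) != 1L ||
      is.na(b$bg_donor) || is.na(b$bg_acceptor) ||
      b$bg_donor < 0 || b$bg_acceptor < 0)
    stop("burst '", b$id, "': background rates must be scalar and >= 0", call. = FALSE)
  if (!is.null(b$ground_truth) && length(b$ground_truth) != n)
    stop("burst '", b$id, "': ground_truth length must match the count vectors",
         call. = FALSE)
  if (!(is.finite(b$bin_width) && b$bin_width > 0))
    stop("burst '", b$id, "': bin_width must be > 0", call. = FALSE)
  invisible(b)
}

#' Number of bins and duration of a burst
#' @param burst A `binned_burst`.
#' @return `n_bins()`: integer bin count. `burst_duration()`: duration in ms.
#' @export
n_bins <- function(burst) length(burst$donor)

#' @rdname n_bins
#' @export
burst_duration <- function(burst) length(burst$donor) * burst$bin_width

#' Construct a set of bursts
#'
#' The burst set is the unit of analysis and of bootstrap resampling. All
#' bursts must share one bin width; ids must be unique (internal bootstrap
#' resamples relax the uniqueness requirement via `validate = FALSE`).
#'
#' @param bursts List of [binned_burst()] objects.
#' @param condition Character label; defaults to the first burst's condition.
#' @param provenance Free-form list of metadata (source file, generator
#'   configuration, seed).
#' @param validate Logical; skip invariant checks (internal use).
#' @return An object of class `burst_set`.
#' @export
burst_set <- function(bursts, condition = NULL, provenance = list(),
                      validate = TRUE) {
  if (!length(bursts)) stop("a burst_set needs at least one burst", call. = FALSE)
  ids <- vapply(bursts, `[[`, character(1), "id")
  if (validate) {
    if (anyDuplicated(ids))
      stop("duplicate burst id(s): ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
    bw <- vapply(bursts, `[[`, numeric(1), "bin_width")
    if (length(unique(bw)) != 1L)
      stop("all bursts in a set must share one bin_width", call. = FALSE)
    lapply(bursts, validate_burst)
  }
  names(bursts) <- NULL
  if (is.null(condition)) condition <- bursts[[1L]]$condition
  structure(list(bursts = bursts, condition = condition, provenance = provenance),
            class = "burst_set")
}

#' @export
print.burst_set <- function(x, ...) {
  nb <- length(x$bursts)
  durs <- vapply(x$bursts, burst_duration, numeric(1))
  cat("<burst_set> ", nb, " bursts, condition '", x$condition, "'\n", sep = "")
  cat("  bin width: ", x$bursts[[1L]]$bin_width, " ms; durations ",
      round(min(durs)), "-", round(max(durs)), " ms (median ",
      round(stats::median(durs)), ")\n", sep = "")
  if (length(x$provenance))
    cat("  provenance: ", paste(names(x$provenance), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
length.burst_set <- function(x) length(x$bursts)

#' Burst ids of a set
#' @param set A `burst_set`.
#' @export
burst_ids <- function(set) vapply(set$bursts, `[[`, character(1), "id")

#' Split a multi-condition set into per-condition sets
#' @param set A `burst_set`.
#' @return Named list of `burst_set`, one per condition label.
#' @export
split_conditions <- function(set) {
  conds <- vapply(set$bursts, `[[`, character(1), "condition")
  lapply(split(seq_along(conds), conds), function(i)
    burst_set(set$bursts[i], condition = conds[i[1L]],
              provenance = set$provenance, validate = FALSE))
}

#' Background-corrected per-bin intensities
#'
#' Subtracts the burst's constant per-channel background rate from every bin.
#' Negative corrected values are retained, not clipped: clamping would bias
#' downstream PR distributions.
#'
#' @param burst A `binned_burst`.
#' @return List with numeric vectors `donor` and `acceptor`.
#' @export
correct_background <- function(burst) {
  list(donor = burst$donor - burst$bg_donor,
       acceptor = burst$acceptor - burst$bg_acceptor)
}

#' Bin-wise and burst-wise proximity ratio
#'
#' The proximity ratio PR = I_A / (I_D + I_A) is computed from
#' background-corrected intensities, either per 1-ms bin (bin-wise PR) or from
#' the sums over the whole burst (burst-wise PR). Bins whose corrected total
#' intensity is <= 0 carry no usable FRET information and are marked invalid
#' (PR set to `NA`); they are excluded from every downstream statistic.
#'
#' @param burst A `binned_burst`.
#' @return An object of class `pr_series`: list with `burst_id`, `pr`
#'   (numeric per bin, `NA` where invalid), `valid` (logical mask),
#'   `burst_pr` (scalar; `NA` if the whole burst's corrected total is <= 0,
#'   in which case the attribute `"excluded"` is `TRUE`).
#' @export
compute_bin_pr <- function(burst) {
  corr <- correct_background(burst)
  tot <- corr$donor + corr$acceptor
  valid <- tot > 0
  pr <- rep(NA_real_, length(tot))
  pr[valid] <- corr$acceptor[valid] / tot[valid]
  stot <- sum(tot)
  excluded <- stot <= 0
  structure(
    list(burst_id = burst$id, pr = pr, valid = valid,
         burst_pr = if (excluded) NA_real_ else sum(corr$acceptor) / stot),
    class = "pr_series", excluded = excluded)
}

#' Burst-wise PR for every burst in a set
#' @param set A `burst_set`.
#' @return Named numeric vector (names = burst ids); `NA` for bursts whose
#'   total corrected intensity is <= 0.
#' @export
burst_pr_values <- function(set) {
  v <- vapply(set$bursts, function(b) compute_bin_pr(b)$burst_pr, numeric(1))
  names(v) <- burst_ids(set)
  v
}

# Bin-wise PR vectors for all bursts (list, NA at invalid bins). Internal
# workhorse shared by the correlation/recurrence/variance estimators.
pr_list <- function(set) lapply(set$bursts, function(b) compute_bin_pr(b)$pr)

#' Filter bursts by duration and mean intensity
#'
#' Reproduces the two selection rules applied after burst marking: bursts
#' shorter than `min_duration` are removed (the boundary is retained:
#' "shorter than" is strict), and bursts whose background-corrected total
#' intensity, averaged over bins, exceeds `max_mean_intensity` are removed
#' (likely oligomers/aggregates). Rules are applied in that order and the
#' per-rule removal counts are attached as attribute `"removed"`.
#'
#' @param set A `burst_set` with backgrounds populated.
#' @param min_duration Minimum burst duration in ms (default 100).
#' @param max_mean_intensity Maximum mean corrected total intensity in counts
#'   per ms (default 40).
#' @return Filtered `burst_set` (subset of the input) with attribute
#'   `removed = c(short = ..., bright = ...)`.
#' @export
filter_bursts <- function(set, min_duration = 100, max_mean_intensity = 40) {
  durs <- vapply(set$bursts, burst_duration, numeric(1))
  keep_dur <- durs >= min_duration
  mean_tot <- vapply(set$bursts, function(b) {
    corr <- correct_background(b)
    mean(corr$donor + corr$acceptor) / b$bin_width
  }, numeric(1))
  keep_int <- mean_tot <= max_mean_intensity
  keep <- keep_dur & keep_int
  if (!any(keep))
    stop("filter_bursts removed every burst", call. = FALSE)
  out <- burst_set(set$bursts[keep], condition = set$condition,
                   provenance = set$provenance, validate = FALSE)
  attr(out, "removed") <- c(short = sum(!keep_dur),
                            bright = sum(keep_dur & !keep_int))
  out
}

#' Detect bursts in a raw two-channel trace by thresholding
#'
#' Approximate, automatic stand-in for manual burst marking: flags contiguous
#' runs of bins whose total count exceeds the summed background by at least
#' `rise_threshold` counts/ms, merging runs separated by a single below-threshold
#' bin. Pre-segmented data should bypass this step.
#'
#' @param donor,acceptor Raw count vectors of one continuous trace.
#' @param rise_threshold Rise above background, counts per ms (> 0); trapping
#'   events typically rise 25-40 counts/ms above background.
#' @param bg_donor,bg_acceptor Background rates, counts per bin.
#' @param bin_width Bin width, ms.
#' @param min_bins Discard detected segments shorter than this many bins
#'   (default 5): suppresses single-bin background spikes that a human marker
#'   would never call a trapping event.
#' @param condition Condition label for the detected bursts.
#' @return A `burst_set` of the detected segments (empty trace is an error; a
#'   trace with no super-threshold bins returns a zero-burst result as an
#'   empty list with class `burst_set`).
#' @export
detect_bursts <- function(donor, acceptor, rise_threshold,
                          bg_donor, bg_acceptor,
                          bin_width = 1, min_bins = 5, condition = "NA") {
  if (!length(donor) || length(donor) != length(acceptor))
    stop("trace must have >= 1 bin in both channels", call. = FALSE)
  if (!(is.finite(rise_threshold) && rise_threshold > 0))
    stop("rise_threshold must be > 0", call. = FALSE)
  above <- (donor + acceptor) - (bg_donor + bg_acceptor) >=
    rise_threshold * bin_width
  # bridge single-bin gaps between above-threshold runs
  n <- length(above)
  if (n >= 3L) {
    gap <- !above & c(FALSE, above[-n]) & c(above[-1L], FALSE)
    above <- above | gap
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values & r$lengths >= min_bins)
  bursts <- lapply(seq_along(idx), function(j) {
    i <- idx[j]
    s <- starts[i]:ends[i]
    binned_burst(id = sprintf("det_%03d", j),
                 donor = donor[s], acceptor = acceptor[s],
                 bg_donor = bg_donor, bg_acceptor = bg_acceptor,
                 condition = condition, bin_width = bin_width)
  })
  if (!length(bursts))
    return(structure(list(bursts = list(), condition = condition,
                          provenance = list(detector = "threshold")),
                     class = "burst_set"))
  burst_set(bursts, condition = condition,
            provenance = list(detector = "threshold",
                              rise_threshold = rise_threshold))
}

#' Chung-Kennedy edge-preserving smoothing
#'
#' Nonlinear filter for visualizing stepwise single-molecule traces: forward
#' (trailing) and backward (leading) running means of width `window` are
#' combined with weights proportional to the inverse local variance of each
#' window raised to `exponent`, so the mean computed on the quiet side of a
#' step dominates and the step edge is preserved. With `exponent = 0` the
#' filter reduces to the symmetric average of the two running means.
#' Visualization only; never used inside any statistic.
#'
#' @param x Numeric series (`NA`s are ignored within windows).
#' @param window Window width in bins (default 10).
#' @param exponent Non-negative weighting exponent (default 10).
#' @return Smoothed series, same length as `x`.
#' @export
chung_kennedy_smooth <- function(x, window = 10, exponent = 10) {
  n <- length(x)
  if (n < 1L) stop("series must have length >= 1", call. = FALSE)
  if (window < 1L) stop("window must be >= 1 bin", call. = FALSE)
  win_stats <- function(forward) {
    mu <- rep(NA_real_, n); v <- rep(NA_real_, n)
    for (t in seq_len(n)) {
      idx <- if (forward) max(1L, t - window + 1L):t else t:min(n, t + window - 1L)
      w <- x[idx]; w <- w[is.finite(w)]
      if (length(w)) {
        mu[t] <- mean(w)
        v[t] <- if (length(w) > 1L) mean((w - mu[t])^2) else 0
      }
    }
    list(mu = mu, v = v)
  }
  f <- win_stats(TRUE); b <- win_stats(FALSE)
  eps <- 1e-12
  wf <- (f$v + eps)^(-exponent)
  wb <- (b$v + eps)^(-exponent)
  # fall back to the available side when one window is all-NA
  wf[is.na(f$mu)] <- 0; wb[is.na(b$mu)] <- 0
  tot <- wf + wb
  out <- ifelse(tot > 0,
                (ifelse(is.na(f$mu), 0, f$mu) * wf +
                 ifelse(is.na(b$mu), 0, b$mu) * wb) / tot,
                NA_real_)
  out
}
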