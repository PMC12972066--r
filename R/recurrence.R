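#' Median split of the bin-wise PR into HF/LF regions
#'
#' The median PR over all valid bins in all bursts defines "high-FRET" (HF,
#' strictly above) and "low-FRET" (LF, strictly below) regions. Bins exactly
#' at the median (rare for continuous PRs) stay unlabeled and are excluded
#' from both regions.
#'
#' @param set A filtered `burst_set`.
#' @return List with `median_pr` and `labels`: per burst, integer vector with
#'   `1` = HF, `-1` = LF, `NA` = tie or invalid bin.
#' @export
median_split <- function(set) {
  prs <- pr_list(set)
  all_pr <- unlist(prs, use.names = FALSE)
  if (all(is.na(all_pr))) stop("no valid PR bins", call. = FALSE)
  med <- stats::median(all_pr, na.rm = TRUE)
  labels <- lapply(prs, function(p) {
    l <- rep(NA_integer_, length(p))
    l[!is.na(p) & p > med] <- 1L
    l[!is.na(p) & p < med] <- -1L
    l
  })
  list(median_pr = med, labels = labels)
}

# Vectorized (start, end) label pair counts at one lag on the padded vector.
recurrence_counts_at <- function(lab_vec, tau) {
  L <- length(lab_vec)
  s <- lab_vec[seq_len(L - tau)]
  e <- lab_vec[seq_len(L - tau) + tau]
  ok <- !is.na(s) & !is.na(e)
  s <- s[ok]; e <- e[ok]
  c(hf_hf = sum(s == 1L & e == 1L), n_hf = sum(s == 1L),
    lf_hf = sum(s == -1L & e == 1L), n_lf = sum(s == -1L))
}

#' Recurrence conditional probabilities of the PR median split
#'
#' For each time delay `tau`, over all bursts at least `tau` long and all
#' times `t` with both `t - tau` and `t` inside the same burst, computes the
#' conditional probabilities of finding the molecule in the HF region at `t`
#' given its region at `t - tau`:
#' `p(HF(t) | HF(t - tau))` and `p(HF(t) | LF(t - tau))`. Pairs involving
#' unlabeled (tie) or invalid bins are excluded. Molecules with long-lived
#' states keep both curves away from the unconditional `P(HF)` (0.5 by the
#' median construction) out to long delays; fast-exchanging or re-colored
#' static-homogeneity data converge to 0.5.
#'
#' @param set A filtered `burst_set`.
#' @param taus Integer delays in bins (>= 1); defaults to a log-spaced grid
#'   over 1-300.
#' @return A `recurrence_result`: list with `median_pr` and `curves`, a
#'   data.frame with columns `tau`, `p_hf_given_hf`, `p_hf_given_lf`, start
#'   counts, and CI placeholders (`NA` at delays with no qualifying starts).
#' @export
recurrence_curves <- function(set, taus = NULL) {
  if (is.null(taus)) taus <- log_tau_grid()
  stopifnot(all(taus >= 1), all(taus == floor(taus)))
  ms <- median_split(set)
  lab <- pad_series(lapply(ms$labels, as.numeric), max(taus))
  cnt <- vapply(taus, function(tau) recurrence_counts_at(lab, tau), numeric(4))
  p_hh <- ifelse(cnt["n_hf", ] > 0, cnt["hf_hf", ] / cnt["n_hf", ], NA_real_)
  p_lh <- ifelse(cnt["n_lf", ] > 0, cnt["lf_hf", ] / cnt["n_lf", ], NA_real_)
  structure(
    list(median_pr = ms$median_pr,
         curves = data.frame(tau = taus,
                             p_hf_given_hf = p_hh, p_hf_given_lf = p_lh,
                             n_start_hf = cnt["n_hf", ], n_start_lf = cnt["n_lf", ],
                             n_hf_hf = cnt["hf_hf", ], n_lf_hf = cnt["lf_hf", ],
                             ci_low_hf = NA_real_, ci_high_hf = NA_real_,
                             ci_low_lf = NA_real_, ci_high_lf = NA_real_)),
    class = "recurrence_result")
}

#' @export
print.recurrence_result <- function(x, ...) {
  cat("<recurrence_result> median PR ", round(x$median_pr, 4), ", ",
      nrow(x$curves), " delays\n", sep = "")
  print.data.frame(x$curves[, 1:5], row.names = FALSE, digits = 4)
  invisible(x)
}

#' Conditional PR histograms at selected delays
#'
#' Histograms of `PR(t)` conditioned on the region (HF or LF) occupied at
#' `t - tau`, alongside the unconditional bin-wise PR histogram. For delays
#' much longer than the exchange relaxation time the conditional histograms
#' relax onto the unconditional one; for static heterogeneity they stay
#' separated.
#'
#' @param set A filtered `burst_set`.
#' @param taus Delays in bins (default 1 and 200).
#' @param n_bins Number of histogram bins.
#' @param breaks Optional explicit break points (overrides `n_bins`).
#' @return A `pr_histograms` object: list with `breaks`, `mids`,
#'   `unconditional` (probability per bin), and per-delay data.frames
#'   `start_hf` / `start_lf`. Empty conditions yield all-zero histograms with
#'   a warning.
#' @export
conditional_pr_histograms <- function(set, taus = c(1, 200), n_bins = 40,
                                      breaks = NULL) {
  stopifnot(all(taus >= 1))
  ms <- median_split(set)
  prs <- pr_list(set)
  gap <- max(taus)
  v <- pad_series(prs, gap)
  lab <- pad_series(lapply(ms$labels, as.numeric), gap)
  all_pr <- v[!is.na(v)]
  if (is.null(breaks)) {
    rng <- range(all_pr)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1L] - 1e-9, rng[2L] + 1e-9, length.out = n_bins + 1L)
  }
  hist_prob <- function(x) {
    if (!length(x)) return(rep(0, length(breaks) - 1L))
    h <- graphics::hist(pmin(pmax(x, breaks[1L]), breaks[length(breaks)]),
                        breaks = breaks, plot = FALSE)
    h$counts / length(x)
  }
  L <- length(v)
  cond <- lapply(taus, function(tau) {
    start <- lab[seq_len(L - tau)]
    end <- v[seq_len(L - tau) + tau]
    ok <- !is.na(start) & !is.na(end)
    hf <- end[ok & start == 1]
    lf <- end[ok & start == -1]
    if (!length(hf) || !length(lf))
      warning("empty conditional set at tau = ", tau)
    list(start_hf = hist_prob(hf), start_lf = hist_prob(lf),
         n_hf = length(hf), n_lf = length(lf))
  })
  names(cond) <- paste0("tau_", taus)
  structure(list(breaks = breaks,
                 mids = (breaks[-1L] + breaks[-length(breaks)]) / 2,
                 unconditional = hist_prob(all_pr),
                 taus = taus, conditional = cond, median_pr = ms$median_pr),
            class = "pr_histograms")
}
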