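#' Scenario ground-truth PR for photon re-coloring
#'
#' Static homogeneity: every burst gets the one shared PR equal to the grand
#' mean of the bin-wise PR over all valid bins in all bursts. Static
#' heterogeneity: each burst keeps its own burst-wise PR. Values are clamped
#' to `[0, 1]` before use as binomial success probabilities (corrected-intensity
#' PRs can leave the unit interval through noise).
#'
#' @param set A `burst_set`.
#' @param scenario `"static_homogeneity"` or `"static_heterogeneity"`.
#' @return Named numeric vector of per-burst ground-truth PRs.
#' @export
ground_truth_pr <- function(set,
                            scenario = c("static_homogeneity",
                                         "static_heterogeneity")) {
  scenario <- match.arg(scenario)
  if (!length(set$bursts)) stop("empty burst set", call. = FALSE)
  out <- if (scenario == "static_homogeneity") {
    prs <- unlist(pr_list(set), use.names = FALSE)
    prs <- prs[!is.na(prs)]
    if (!length(prs)) stop("no valid bins to average", call. = FALSE)
    rep(mean(prs), length(set$bursts))
  } else {
    burst_pr_values(set)
  }
  out <- pmin(1, pmax(0, out))
  names(out) <- burst_ids(set)
  out
}

#' Photon re-coloring null models
#'
#' Builds a "static homogeneity" or "static heterogeneity" re-colored version
#' of an experimental burst set. Per bin, the total raw photon count is
#' preserved exactly. A constant expected background total
#' `b = bg_donor + bg_acceptor` (rounded to the nearest integer, capped at the
#' bin's total) is allocated per bin; those background photons are re-colored
#' binomially with success probability `bg_acceptor / (bg_donor + bg_acceptor)`,
#' and the remaining (signal) photons binomially with the scenario's
#' ground-truth PR. The output bursts carry the same background rates, so the
#' usual background correction applies unchanged downstream.
#'
#' @param set A `burst_set` with backgrounds populated.
#' @param scenario `"static_homogeneity"` or `"static_heterogeneity"`.
#' @param seed Integer seed or `NULL`.
#' @return A `burst_set` with the same ids, durations and per-bin totals;
#'   `ground_truth` holds the scenario PR; provenance records scenario + seed.
#' @export
recolor_bursts <- function(set,
                           scenario = c("static_homogeneity",
                                        "static_heterogeneity"),
                           seed = NULL) {
  scenario <- match.arg(scenario)
  if (!is.null(seed)) set.seed(seed)
  truth <- ground_truth_pr(set, scenario)
  zero_bg <- FALSE
  bursts <- lapply(seq_along(set$bursts), function(i) {
    b <- set$bursts[[i]]
    tot <- b$donor + b$acceptor
    bsum <- b$bg_donor + b$bg_acceptor
    if (bsum <= 0) {
      if (any(tot > 0)) zero_bg <<- TRUE
      n_bg <- rep(0L, length(tot))
      p_bg <- 0
    } else {
      n_bg <- pmin(as.integer(round(bsum)), as.integer(tot))
      p_bg <- b$bg_acceptor / bsum
    }
    n_sig <- as.integer(tot) - n_bg
    a_new <- stats::rbinom(length(tot), n_bg, p_bg) +
      stats::rbinom(length(tot), n_sig, truth[i])
    binned_burst(id = b$id, donor = as.integer(tot) - a_new, acceptor = a_new,
                 bg_donor = b$bg_donor, bg_acceptor = b$bg_acceptor,
                 condition = b$condition, bin_width = b$bin_width,
                 ground_truth = rep(truth[i], length(tot)))
  })
  if (zero_bg)
    message("recolor_bursts: zero background with nonzero counts; ",
            "all photons treated as signal")
  burst_set(bursts, condition = set$condition,
            provenance = c(set$provenance,
                           list(recolored = scenario, recolor_seed = seed)))
}
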