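#' Configuration for the synthetic burst-trace generator
#'
#' Defaults describe a trapped-molecule smFRET experiment at 1-ms binning:
#' total signal brightness 25 counts/ms (reported range 20-30), backgrounds
#' 12 counts/ms (donor) and 22 counts/ms (acceptor) (reported ranges 10-15 and
#' 20-25), burst durations drawn from an exponential distribution truncated to
#' the 100-2000 ms trapping range, and a two-state conformational exchange
#' between PR 0.4 and PR 0.8 with rate constants k12 = k21 = 5 /s.
#'
#' @param state_prs Ground-truth PR per conformational state, in `[0, 1]`.
#' @param rates Two-state switching rates `c(k12, k21)` in 1/s (state 1 -> 2
#'   and 2 -> 1). Both 0 means no switching.
#' @param brightness Mean total signal photons per bin (> 0).
#' @param bg_donor,bg_acceptor Background rates, counts per bin.
#' @param duration_model List: `kind` one of `"exponential"`, `"uniform"`,
#'   `"empirical"`; `mean` (exponential, ms), `min`/`max` (truncation /
#'   uniform bounds, ms), `values` (empirical durations, ms).
#' @param n_bursts Number of bursts (>= 1).
#' @param pr_heterogeneity_sd Inter-molecule SD of a per-burst additive shift
#'   applied to all state PRs (clamped back to `[0, 1]`).
#' @param bin_width Bin width, ms.
#' @param condition Condition label.
#' @param seed Integer seed or `NULL`.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(state_prs = c(0.4, 0.8), rates = c(5, 5),
                              brightness = 25, bg_donor = 12, bg_acceptor = 22,
                              duration_model = list(kind = "exponential",
                                                    mean = 350, min = 100,
                                                    max = 2000),
                              n_bursts = 100, pr_heterogeneity_sd = 0,
                              bin_width = 1, condition = "SIM", seed = NULL) {
  cfg <- list(state_prs = state_prs, rates = rates, brightness = brightness,
              bg_donor = bg_donor, bg_acceptor = bg_acceptor,
              duration_model = duration_model, n_bursts = n_bursts,
              pr_heterogeneity_sd = pr_heterogeneity_sd,
              bin_width = bin_width, condition = condition, seed = seed)
  stopifnot(all(cfg$state_prs >= 0 & cfg$state_prs <= 1),
            all(cfg$rates >= 0), cfg$brightness > 0,
            cfg$bg_donor >= 0, cfg$bg_acceptor >= 0, cfg$n_bursts >= 1,
            cfg$pr_heterogeneity_sd >= 0, cfg$bin_width > 0)
  structure(cfg, class = "simulation_config")
}

sample_durations <- function(dm, n, bin_width) {
  kind <- match.arg(dm$kind, c("exponential", "uniform", "empirical"))
  lo <- if (is.null(dm$min)) 100 else dm$min
  hi <- if (is.null(dm$max)) 2000 else dm$max
  d <- switch(kind,
    exponential = {
      rate <- 1 / dm$mean
      # inverse-CDF sampling of the truncated exponential on [lo, hi]
      u <- stats::runif(n)
      plo <- stats::pexp(lo, rate); phi <- stats::pexp(hi, rate)
      stats::qexp(plo + u * (phi - plo), rate)
    },
    uniform = stats::runif(n, lo, hi),
    empirical = sample(dm$values, n, replace = TRUE))
  pmax(1L, as.integer(round(d / bin_width)))   # n_bins per burst
}

# Continuous-time two-state Markov path discretized to per-bin occupancy of
# state 2 (fraction of the bin spent in state 2). Rates in 1/s, bins in ms.
# keep_path additionally records completed dwell times (ms) per state.
sample_state_occupancy <- function(nb, bin_width, k12, k21, keep_path = FALSE) {
  total <- nb * bin_width
  ksum <- k12 + k21
  p2 <- if (ksum > 0) k12 / ksum else 0.5
  s <- if (stats::runif(1) < p2) 2L else 1L
  occ2 <- numeric(nb)
  t <- 0
  transitions <- 0L
  dwell_state <- integer(0); dwell_len <- numeric(0)
  while (t < total) {
    rate_ms <- (if (s == 1L) k12 else k21) / 1000
    dwell <- if (rate_ms > 0) stats::rexp(1, rate_ms) else Inf
    t2 <- min(total, t + dwell)
    if (s == 2L && t2 > t) {
      i0 <- floor(t / bin_width) + 1
      i1 <- min(nb, floor((t2 - 1e-9) / bin_width) + 1)
      if (i0 == i1) occ2[i0] <- occ2[i0] + (t2 - t)
      else {
        occ2[i0] <- occ2[i0] + (i0 * bin_width - t)
        occ2[i1] <- occ2[i1] + (t2 - (i1 - 1) * bin_width)
        if (i1 > i0 + 1) occ2[(i0 + 1):(i1 - 1)] <- occ2[(i0 + 1):(i1 - 1)] + bin_width
      }
    }
    if (t2 < total) {
      if (keep_path) {   # completed (uncensored) dwell
        dwell_state <- c(dwell_state, s)
        dwell_len <- c(dwell_len, t2 - t)
      }
      s <- 3L - s
      transitions <- transitions + 1L
    }
    t <- t2
  }
  out <- list(occ2 = occ2 / bin_width, transitions = transitions)
  if (keep_path) out$dwells <- data.frame(state = dwell_state, dwell_ms = dwell_len)
  out
}

emit_photons <- function(true_pr, cfg) {
  nb <- length(true_pr)
  n_sig <- stats::rpois(nb, cfg$brightness)
  a_sig <- stats::rbinom(nb, n_sig, pmin(1, pmax(0, true_pr)))
  list(donor = (n_sig - a_sig) + stats::rpois(nb, cfg$bg_donor),
       acceptor = a_sig + stats::rpois(nb, cfg$bg_acceptor))
}

#' Simulate a ground-truth-labeled two-state burst ensemble
#'
#' Each burst: a duration is drawn from the configured model; a
#' continuous-time two-state Markov path is sampled and discretized to a
#' per-bin occupancy-weighted true PR (sub-bin dynamics average within each
#' 1-ms bin); per bin, the total signal photon number is Poisson with mean
#' `brightness` and is split donor/acceptor binomially by the true PR;
#' Poisson background photons are added per channel. The per-bin true PR is
#' stored in each burst's `ground_truth`.
#'
#' @param config A [simulation_config()].
#' @return A `burst_set` with `ground_truth` filled; provenance records the
#'   config and seed. Attribute `"n_transitions"` gives the total number of
#'   state transitions across the latent paths.
#' @export
simulate_burst_ensemble <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (length(config$state_prs) > 2L)
    stop("only one- or two-state exchange is supported", call. = FALSE)
  nb_vec <- sample_durations(config$duration_model, config$n_bursts,
                             config$bin_width)
  pr1 <- config$state_prs[1L]
  pr2 <- if (length(config$state_prs) >= 2L) config$state_prs[2L] else pr1
  trans_total <- 0L
  bursts <- vector("list", config$n_bursts)
  for (i in seq_len(config$n_bursts)) {
    nb <- nb_vec[i]
    shift <- if (config$pr_heterogeneity_sd > 0)
      stats::rnorm(1, 0, config$pr_heterogeneity_sd) else 0
    p1 <- min(1, max(0, pr1 + shift)); p2 <- min(1, max(0, pr2 + shift))
    if (p1 == p2 || all(config$rates == 0)) {
      occ <- sample_state_occupancy(nb, config$bin_width, 0, 0)
      true_pr <- rep(if (occ$occ2[1L] > 0) p2 else p1, nb)
    } else {
      occ <- sample_state_occupancy(nb, config$bin_width,
                                    config$rates[1L], config$rates[2L])
      true_pr <- p1 + (p2 - p1) * occ$occ2
      trans_total <- trans_total + occ$transitions
    }
    ph <- emit_photons(true_pr, config)
    bursts[[i]] <- binned_burst(
      id = sprintf("sim_%05d", i), donor = ph$donor, acceptor = ph$acceptor,
      bg_donor = config$bg_donor, bg_acceptor = config$bg_acceptor,
      condition = config$condition, bin_width = config$bin_width,
      ground_truth = true_pr)
  }
  out <- burst_set(bursts, condition = config$condition,
                   provenance = list(generator = "simulate_burst_ensemble",
                                     config = unclass(config),
                                     seed = config$seed))
  attr(out, "n_transitions") <- trans_total
  out
}

#' Simulate a static (non-switching) burst ensemble
#'
#' Each burst holds one constant true PR for its whole duration; photon
#' emission is identical to [simulate_burst_ensemble()]. Used to build
#' static-homogeneity (one shared PR) and static-heterogeneity (a PR
#' distribution) ground truths directly.
#'
#' @param pr_values Either a single PR (shared by all bursts), a vector of
#'   length `n_bursts` (one per burst), or a longer vector sampled from with
#'   replacement.
#' @param config A [simulation_config()]; its `state_prs`/`rates` are ignored.
#' @return A `burst_set` with constant per-burst `ground_truth`.
#' @export
simulate_static_ensemble <- function(pr_values, config) {
  stopifnot(inherits(config, "simulation_config"),
            all(pr_values >= 0 & pr_values <= 1))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_bursts
  prs <- if (length(pr_values) == 1L) rep(pr_values, n)
         else if (length(pr_values) == n) pr_values
         else sample(pr_values, n, replace = TRUE)
  nb_vec <- sample_durations(config$duration_model, n, config$bin_width)
  bursts <- vector("list", n)
  for (i in seq_len(n)) {
    true_pr <- rep(prs[i], nb_vec[i])
    ph <- emit_photons(true_pr, config)
    bursts[[i]] <- binned_burst(
      id = sprintf("sim_%05d", i), donor = ph$donor, acceptor = ph$acceptor,
      bg_donor = config$bg_donor, bg_acceptor = config$bg_acceptor,
      condition = config$condition, bin_width = config$bin_width,
      ground_truth = true_pr)
  }
  burst_set(bursts, condition = config$condition,
            provenance = list(generator = "simulate_static_ensemble",
                              config = unclass(config), seed = config$seed))
}
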