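#' Full burst-statistics analysis of one condition
#'
#' The central entry point: takes a (filtered) burst set and computes the
#' burst-wise PR distribution, the burst-variance profile, the five
#' burst-edge-aware correlation functions, the recurrence conditional
#' probabilities and conditional PR histograms, and the same statistics for
#' re-colored static null models, with burst-level bootstrap confidence
#' intervals on the selected statistics.
#'
#' @param set A `burst_set` (apply [filter_bursts()] first for experimental
#'   data).
#' @param max_lag Maximum correlation lag, bins (default 300).
#' @param taus Recurrence delay grid, bins; default log-spaced 1-300.
#' @param hist_taus Delays for conditional PR histograms (default 1 and 200).
#' @param n_boot Bootstrap replicates (default 200); `0` disables CIs.
#' @param boot_targets Statistics to bootstrap: any of
#'   `"pr_autocorrelation"`, `"variance_profile"`, `"recurrence"`,
#'   `"intensity_correlation"`.
#' @param scenarios Re-coloring null scenarios to run (default both).
#' @param normalization PR autocorrelation normalization (see
#'   [pr_autocorrelation()]).
#' @param seed Integer seed for re-coloring and bootstrap.
#' @return A `fret_analysis` object (list) with components `burst_pr`,
#'   `variance`, `correlations` (named list), `recurrence`, `histograms`,
#'   `nulls` (per scenario: the same statistics on the re-colored set), and
#'   `settings`.
#' @export
analyze_bursts <- function(set, max_lag = 300, taus = NULL,
                           hist_taus = c(1, 200), n_boot = 200,
                           boot_targets = c("pr_autocorrelation",
                                            "variance_profile", "recurrence"),
                           scenarios = c("static_homogeneity",
                                         "static_heterogeneity"),
                           normalization = "per_lag", seed = NULL) {
  if (is.null(taus)) taus <- log_tau_grid(max_tau = min(max_lag, 300))
  if (!is.null(seed)) set.seed(seed)
  boot_targets <- match.arg(boot_targets,
                            c("pr_autocorrelation", "variance_profile",
                              "recurrence", "intensity_correlation"),
                            several.ok = TRUE)

  analyze_one <- function(s) {
    corr <- list(
      AxA = intensity_correlation(s, "acceptor", "acceptor", max_lag),
      DxD = intensity_correlation(s, "donor", "donor", max_lag),
      DxA = intensity_correlation(s, "donor", "acceptor", max_lag),
      SxS = intensity_correlation(s, "sum", "sum", max_lag),
      PRxPR = pr_autocorrelation(s, max_lag, normalization = normalization))
    res <- list(
      burst_pr = burst_pr_values(s),
      variance = variance_profile(s),
      correlations = corr,
      recurrence = recurrence_curves(s, taus),
      histograms = conditional_pr_histograms(s, hist_taus))
    if (n_boot > 0) {
      if ("pr_autocorrelation" %in% boot_targets) {
        if (normalization == "per_lag") {
          # additive-sufficient-statistics fast path (identical estimator)
          bo <- boot_pr_autocorrelation(s, res$correlations$PRxPR$lag,
                                        n_resamples = n_boot)
        } else {
          bo <- bootstrap_ci(s, function(ss)
            pr_autocorrelation(ss, max_lag, normalization = normalization)$value,
            n_resamples = n_boot)
        }
        res$correlations$PRxPR$ci_low <- bo$ci_low
        res$correlations$PRxPR$ci_high <- bo$ci_high
      }
      if ("intensity_correlation" %in% boot_targets) {
        for (k in c("AxA", "DxD", "DxA", "SxS")) {
          ch <- switch(k, AxA = c("acceptor", "acceptor"),
                       DxD = c("donor", "donor"), DxA = c("donor", "acceptor"),
                       SxS = c("sum", "sum"))
          bo <- bootstrap_ci(s, function(ss)
            intensity_correlation(ss, ch[1L], ch[2L], max_lag)$value,
            n_resamples = n_boot)
          res$correlations[[k]]$ci_low <- bo$ci_low
          res$correlations[[k]]$ci_high <- bo$ci_high
        }
      }
      if ("variance_profile" %in% boot_targets) {
        bo <- bootstrap_ci(s, function(ss) variance_profile(ss)$mean_sigma,
                           n_resamples = n_boot)
        res$variance$ci_low <- bo$ci_low
        res$variance$ci_high <- bo$ci_high
      }
      if ("recurrence" %in% boot_targets) {
        bo <- bootstrap_ci(s, function(ss) {
          cv <- recurrence_curves(ss, taus)$curves
          c(cv$p_hf_given_hf, cv$p_hf_given_lf)
        }, n_resamples = n_boot)
        m <- length(taus)
        res$recurrence$curves$ci_low_hf <- bo$ci_low[seq_len(m)]
        res$recurrence$curves$ci_high_hf <- bo$ci_high[seq_len(m)]
        res$recurrence$curves$ci_low_lf <- bo$ci_low[m + seq_len(m)]
        res$recurrence$curves$ci_high_lf <- bo$ci_high[m + seq_len(m)]
      }
    }
    res
  }

  out <- analyze_one(set)
  out$nulls <- list()
  for (sc in scenarios) {
    null_set <- recolor_bursts(set, sc)
    out$nulls[[sc]] <- analyze_one(null_set)
  }
  out$settings <- list(max_lag = max_lag, taus = taus, hist_taus = hist_taus,
                       n_boot = n_boot, boot_targets = boot_targets,
                       scenarios = scenarios, normalization = normalization,
                       seed = seed, n_bursts = length(set$bursts),
                       condition = set$condition)
  class(out) <- "fret_analysis"
  out
}

#' @export
print.fret_analysis <- function(x, ...) {
  s <- x$settings
  cat("<fret_analysis> condition '", s$condition, "', ", s$n_bursts,
      " bursts\n", sep = "")
  cat("  burst-wise PR: mean ", round(mean(x$burst_pr, na.rm = TRUE), 3),
      ", SD ", round(stats::sd(x$burst_pr, na.rm = TRUE), 3), "\n", sep = "")
  g <- x$correlations$PRxPR
  g1 <- g$value[g$lag == 1L]
  cat("  PR autocorrelation g(1 ms) = ", round(g1, 3), "\n", sep = "")
  rc <- x$recurrence$curves
  cat("  recurrence p(HF|HF): ", round(rc$p_hf_given_hf[1L], 3), " at tau = ",
      rc$tau[1L], "; median PR ", round(x$recurrence$median_pr, 3), "\n",
      sep = "")
  cat("  nulls: ", paste(names(x$nulls), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.fret_analysis <- function(object, ...) {
  x <- object
  rc <- x$recurrence$curves
  near <- function(target) rc[which.min(abs(rc$tau - target)), ]
  out <- list(
    condition = x$settings$condition,
    n_bursts = x$settings$n_bursts,
    mean_burst_pr = mean(x$burst_pr, na.rm = TRUE),
    sd_burst_pr = stats::sd(x$burst_pr, na.rm = TRUE),
    median_bin_pr = x$recurrence$median_pr,
    g_at_1ms = x$correlations$PRxPR$value[x$correlations$PRxPR$lag == 1L],
    p_hf_hf_1ms = near(1)$p_hf_given_hf,
    p_hf_hf_200ms = near(200)$p_hf_given_hf)
  class(out) <- "summary.fret_analysis"
  out
}

#' @export
print.summary.fret_analysis <- function(x, ...) {
  cat("Burst-statistics summary - condition '", x$condition, "'\n", sep = "")
  cat(sprintf("  bursts analyzed:        %d\n", x$n_bursts))
  cat(sprintf("  burst-wise PR:          %.3f +/- %.3f (mean +/- SD)\n",
              x$mean_burst_pr, x$sd_burst_pr))
  cat(sprintf("  median bin-wise PR:     %.3f\n", x$median_bin_pr))
  cat(sprintf("  PR autocorr g(1 ms):    %.3f\n", x$g_at_1ms))
  cat(sprintf("  p(HF|HF) at 1 ms:       %.3f\n", x$p_hf_hf_1ms))
  cat(sprintf("  p(HF|HF) at ~200 ms:    %.3f\n", x$p_hf_hf_200ms))
  invisible(x)
}

write_csv_out <- function(df, dir, name) {
  utils::write.csv(df, file.path(dir, name), row.names = FALSE)
}

export_analysis_csv <- function(res, dir, prefix = "") {
  pre <- if (nzchar(prefix)) paste0(prefix, "_") else ""
  write_csv_out(data.frame(burst_id = names(res$burst_pr),
                           burst_pr = unname(res$burst_pr)),
                dir, paste0(pre, "burst_pr.csv"))
  write_csv_out(as.data.frame(res$variance), dir, paste0(pre, "variance_profile.csv"))
  corr <- do.call(rbind, lapply(names(res$correlations), function(k) {
    d <- as.data.frame(res$correlations[[k]])
    cbind(kind = k, d)
  }))
  write_csv_out(corr, dir, paste0(pre, "correlations.csv"))
  write_csv_out(cbind(median_pr = res$recurrence$median_pr,
                      res$recurrence$curves),
                dir, paste0(pre, "recurrence.csv"))
  h <- res$histograms
  hist_df <- data.frame(mid = h$mids, unconditional = h$unconditional)
  for (i in seq_along(h$taus)) {
    hist_df[[paste0("start_hf_tau", h$taus[i])]] <- h$conditional[[i]]$start_hf
    hist_df[[paste0("start_lf_tau", h$taus[i])]] <- h$conditional[[i]]$start_lf
  }
  write_csv_out(hist_df, dir, paste0(pre, "pr_histograms.csv"))
}

#' Run the end-to-end analysis pipeline and write a report bundle
#'
#' Orchestrates simulate/ingest -> filter -> analysis (with re-colored nulls
#' and bootstrap CIs) and writes CSV outputs plus a machine-readable JSON run
#' manifest into `out_dir`. Conditions in the input are processed
#' independently.
#'
#' @param config List (or path to a JSON file) with elements:
#'   `input` - path to a burst-table CSV, or a [simulation_config()] (a plain
#'   list is coerced); `filter` - list(`min_duration`, `max_mean_intensity`);
#'   `analysis` - arguments passed to [analyze_bursts()]; `seed` - global
#'   seed; `out_dir` - output directory.
#' @return Invisibly, the named list of `fret_analysis` objects (one per
#'   condition).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(config$out_dir)) stop("config$out_dir is required", call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  set.seed(seed)

  if (is.character(config$input)) {
    if (!file.exists(config$input))
      stop("input stage: file not found: ", config$input, call. = FALSE)
    set <- read_burst_table(config$input)
  } else if (!is.null(config$input)) {
    sim_cfg <- config$input
    if (!inherits(sim_cfg, "simulation_config"))
      sim_cfg <- do.call(simulation_config, sim_cfg)
    if (is.null(sim_cfg$seed)) sim_cfg$seed <- seed
    set <- simulate_burst_ensemble(sim_cfg)
  } else stop("config$input is required (file path or simulation config)",
              call. = FALSE)

  filt <- config$filter
  min_dur <- if (is.null(filt$min_duration)) 100 else filt$min_duration
  max_int <- if (is.null(filt$max_mean_intensity)) 40 else filt$max_mean_intensity
  n_before <- length(set$bursts)
  fset <- filter_bursts(set, min_dur, max_int)
  removed <- attr(fset, "removed")

  args <- if (is.null(config$analysis)) list() else config$analysis
  results <- list()
  for (sub in split_conditions(fset)) {
    cond <- sub$condition
    res <- do.call(analyze_bursts, c(list(set = sub, seed = seed), args))
    export_analysis_csv(res, config$out_dir, prefix = cond)
    for (sc in names(res$nulls))
      export_analysis_csv(res$nulls[[sc]], config$out_dir,
                          prefix = paste0(cond, "_", sc))
    results[[cond]] <- res
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("fretburst")),
    r_version = R.version.string,
    seed = seed,
    n_bursts_input = n_before,
    n_removed_short = unname(removed["short"]),
    n_removed_bright = unname(removed["bright"]),
    n_bursts_analyzed = length(fset$bursts),
    conditions = names(results),
    filter = list(min_duration = min_dur, max_mean_intensity = max_int),
    analysis = args,
    n_boot = if (is.null(args$n_boot)) 200 else args$n_boot)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}
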