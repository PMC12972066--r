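ci_polygon <- function(xx, lo, hi, col) {
  ok <- !is.na(lo) & !is.na(hi)
  if (!any(ok)) return(invisible())
  graphics::polygon(c(xx[ok], rev(xx[ok])), c(lo[ok], rev(hi[ok])),
                    col = col, border = NA)
}

#' @export
plot.correlation_curve <- function(x, log_x = TRUE, add = FALSE, col = "purple4",
                                   ylim = NULL, ...) {
  sel <- x$lag >= 1 & !is.na(x$value)
  xx <- x$lag[sel]; yy <- x$value[sel]
  if (is.null(ylim)) {
    r <- range(c(yy, x$ci_low[sel], x$ci_high[sel]), na.rm = TRUE)
    ylim <- r + c(-0.05, 0.05) * diff(r)
  }
  if (!add) {
    plot(xx, yy, type = "n", log = if (log_x) "x" else "",
         xlab = expression(tau ~ "(ms)"),
         ylab = paste0(attr(x, "kind"), " correlation"), ylim = ylim, ...)
    graphics::abline(h = 0, col = "grey70", lty = 2)
  }
  ci_polygon(xx, x$ci_low[sel], x$ci_high[sel],
             grDevices::adjustcolor(col, 0.25))
  graphics::lines(xx, yy, col = col, lwd = 2)
  invisible(x)
}

#' @export
plot.variance_profile <- function(x, col = "purple4", add = FALSE, ...) {
  sel <- !is.na(x$mean_sigma)
  if (!add)
    plot(x$center[sel], x$mean_sigma[sel], type = "n",
         xlab = "burst-wise PR", ylab = expression("<" * sigma * ">"),
         xlim = c(0, 1), ...)
  ci_polygon(x$center[sel], x$ci_low[sel], x$ci_high[sel],
             grDevices::adjustcolor(col, 0.25))
  graphics::lines(x$center[sel], x$mean_sigma[sel], col = col, lwd = 2)
  graphics::points(x$center[sel], x$mean_sigma[sel], col = col, pch = 16)
  invisible(x)
}

#' @export
plot.recurrence_result <- function(x, add = FALSE, cols = c("red3", "blue3"),
                                   ...) {
  cv <- x$curves
  if (!add) {
    plot(range(cv$tau), c(0, 1), type = "n", log = "x",
         xlab = expression(tau ~ "(ms)"), ylab = "p(HF at t)", ...)
    graphics::abline(h = 0.5, col = "grey70", lty = 2)
  }
  ci_polygon(cv$tau, cv$ci_low_hf, cv$ci_high_hf,
             grDevices::adjustcolor(cols[1L], 0.25))
  ci_polygon(cv$tau, cv$ci_low_lf, cv$ci_high_lf,
             grDevices::adjustcolor(cols[2L], 0.25))
  graphics::lines(cv$tau, cv$p_hf_given_hf, col = cols[1L], lwd = 2)
  graphics::lines(cv$tau, cv$p_hf_given_lf, col = cols[2L], lwd = 2)
  graphics::legend("topright", bty = "n", lwd = 2, col = cols,
                   legend = c("start at HF", "start at LF"))
  invisible(x)
}

#' @export
plot.pr_histograms <- function(x, which_tau = 1L, ...) {
  h <- x$conditional[[which_tau]]
  plot(x$mids, x$unconditional, type = "s", col = "black", lwd = 2,
       xlab = "bin-wise PR", ylab = "probability",
       ylim = c(0, max(x$unconditional, h$start_hf, h$start_lf)), ...)
  graphics::lines(x$mids, h$start_hf, type = "s", col = "red3", lwd = 2, lty = 2)
  graphics::lines(x$mids, h$start_lf, type = "s", col = "blue3", lwd = 2, lty = 2)
  graphics::abline(v = x$median_pr, col = "grey70", lty = 3)
  graphics::legend("topleft", bty = "n", lwd = 2, lty = c(1, 2, 2),
                   col = c("black", "red3", "blue3"),
                   legend = c("all bins",
                              paste0("start at HF (tau=", x$taus[which_tau], ")"),
                              paste0("start at LF (tau=", x$taus[which_tau], ")")))
  invisible(x)
}

#' @export
plot.binned_burst <- function(x, smooth = TRUE, window = 10, exponent = 10,
                              ...) {
  corr <- correct_background(x)
  t_ms <- (seq_along(x$donor) - 0.5) * x$bin_width
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(old))
  plot(t_ms, corr$donor, type = "l",
       col = grDevices::adjustcolor("dodgerblue", 0.4),
       xlab = "", ylab = "counts/ms",
       ylim = range(c(corr$donor, corr$acceptor)), ...)
  graphics::lines(t_ms, corr$acceptor, col = grDevices::adjustcolor("red3", 0.4))
  if (smooth) {
    graphics::lines(t_ms, chung_kennedy_smooth(corr$donor, window, exponent),
                    col = "dodgerblue4", lwd = 2)
    graphics::lines(t_ms, chung_kennedy_smooth(corr$acceptor, window, exponent),
                    col = "red4", lwd = 2)
  }
  s <- compute_bin_pr(x)
  plot(t_ms, s$pr, type = "l", col = grDevices::adjustcolor("black", 0.35),
       xlab = "time (ms)", ylab = "PR", ylim = c(-0.1, 1.1))
  if (smooth)
    graphics::lines(t_ms, chung_kennedy_smooth(s$pr, window, exponent),
                    col = "black", lwd = 2)
  graphics::abline(h = c(0, 1), col = "grey80", lty = 3)
  invisible(x)
}

#' Four-panel overview figure of a `fret_analysis`
#'
#' Burst-wise PR distribution, variance profile, PR autocorrelation, and
#' recurrence curves, each with the matching re-colored null overlaid where
#' available.
#'
#' @param x A `fret_analysis`.
#' @param ... Ignored.
#' @export
plot.fret_analysis <- function(x, ...) {
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::hist(x$burst_pr, breaks = 30, col = "plum3", border = "white",
                 main = "burst-wise PR", xlab = "PR")
  plot(x$variance, main = "variance profile")
  if (!is.null(x$nulls$static_heterogeneity))
    plot(x$nulls$static_heterogeneity$variance, add = TRUE, col = "darkorange3")
  plot(x$correlations$PRxPR, main = "PR autocorrelation")
  if (!is.null(x$nulls$static_heterogeneity))
    plot(x$nulls$static_heterogeneity$correlations$PRxPR, add = TRUE,
         col = "darkorange3")
  if (!is.null(x$nulls$static_homogeneity))
    plot(x$nulls$static_homogeneity$correlations$PRxPR, add = TRUE,
         col = "seagreen")
  plot(x$recurrence, main = "recurrence")
  invisible(x)
}
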