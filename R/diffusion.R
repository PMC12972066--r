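#' Two-dimensional position trajectory
#'
#' Container for a reconstructed (or simulated) diffusion path of a trapped
#' molecule, sampled on a regular time grid.
#'
#' @param x,y Position sequences, micrometers, equal length >= 2.
#' @param dt Time step, milliseconds (> 0).
#' @return An object of class `trajectory2d`.
#' @export
trajectory2d <- function(x, y, dt = 1) {
  if (length(x) < 2L || length(x) != length(y))
    stop("x and y must have equal length >= 2", call. = FALSE)
  if (!(is.finite(dt) && dt > 0)) stop("dt must be > 0", call. = FALSE)
  structure(list(x = as.numeric(x), y = as.numeric(y), dt = as.numeric(dt)),
            class = "trajectory2d")
}

#' Mean squared displacement of a 2D trajectory
#'
#' Overlapping-window estimator:
#' `MSD(tau) = <(x(t+tau) - x(t))^2 + (y(t+tau) - y(t))^2>` over all valid
#' start times `t`.
#'
#' @param traj A [trajectory2d()].
#' @param max_lag Maximum lag in steps (< trajectory length).
#' @return Data.frame with `lag` (steps), `lag_ms`, and `msd` (um^2).
#' @export
msd_curve <- function(traj, max_lag = NULL) {
  n <- length(traj$x)
  if (is.null(max_lag)) max_lag <- min(n - 1L, 50L)
  if (max_lag >= n) stop("max_lag must be < trajectory length", call. = FALSE)
  msd <- vapply(seq_len(max_lag), function(tau) {
    dx <- traj$x[(1L + tau):n] - traj$x[seq_len(n - tau)]
    dy <- traj$y[(1L + tau):n] - traj$y[seq_len(n - tau)]
    mean(dx^2 + dy^2)
  }, numeric(1))
  data.frame(lag = seq_len(max_lag), lag_ms = seq_len(max_lag) * traj$dt,
             msd = msd)
}

#' Diffusion coefficient from an MSD curve
#'
#' Least-squares fit (with intercept) of MSD versus lag time over `fit_lags`;
#' in two dimensions `MSD = 4 D tau`, so `D = slope / 4`, converted to
#' um^2/s from the ms lag axis.
#'
#' @param msd Data.frame from [msd_curve()] (columns `lag`, `lag_ms`, `msd`).
#' @param fit_lags Lags (steps) to fit; default 1-10.
#' @return List with `D` (um^2/s), `slope` (um^2/ms), `intercept`,
#'   `fit_lags`, and `residuals`. Non-positive slopes are reported with a
#'   warning.
#' @export
estimate_D <- function(msd, fit_lags = 1:10) {
  if (!length(fit_lags)) stop("empty fit range", call. = FALSE)
  sel <- msd$lag %in% fit_lags
  if (sum(sel) < 2L)
    stop("fit range must contain >= 2 lags inside the curve", call. = FALSE)
  fit <- stats::lm(msd ~ lag_ms, data = msd[sel, ])
  slope <- unname(stats::coef(fit)[2L])   # um^2 per ms
  if (slope <= 0)
    warning("non-positive MSD slope; D estimate is not meaningful")
  list(D = slope / 4 * 1000, slope = slope,
       intercept = unname(stats::coef(fit)[1L]),
       fit_lags = msd$lag[sel], residuals = unname(stats::residuals(fit)))
}

#' Simulate a 2D Brownian trajectory
#'
#' Gaussian increments with per-axis variance `2 D dt`; oracle for the MSD
#' estimator.
#'
#' @param n_steps Number of positions.
#' @param D Diffusion coefficient, um^2/s.
#' @param dt Time step, ms.
#' @param seed Integer seed or `NULL`.
#' @return A [trajectory2d()].
#' @export
simulate_brownian2d <- function(n_steps, D, dt = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sdd <- sqrt(2 * D * dt / 1000)
  trajectory2d(cumsum(c(0, stats::rnorm(n_steps - 1L, 0, sdd))),
               cumsum(c(0, stats::rnorm(n_steps - 1L, 0, sdd))), dt = dt)
}
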