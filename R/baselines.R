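## Classical TA-MSD estimators: global and sliding-window fits of the
## diffusion coefficient and the anomalous exponent.

#' Time-averaged mean squared displacement
#'
#' \deqn{\mathrm{TA\text{-}MSD}(\Delta) = \frac{1}{n-\Delta}
#'   \sum_{t=0}^{n-\Delta-1} \lVert r(t+\Delta) - r(t) \rVert^2}
#' computed exactly over all start points at each lag.
#'
#' @param traj a `traj`.
#' @param max_lag largest lag in frames; must be < n.
#' @return data frame of class `msd_curve` with columns `lag` (frames),
#'   `msd`, `n_pairs`.
#' @export
tamsd <- function(traj, max_lag = n_steps(traj) - 1L) {
  n <- n_steps(traj)
  if (max_lag >= n || max_lag < 1L) stop("max_lag must be in [1, n-1]")
  p <- traj$positions
  out <- vapply(seq_len(max_lag), function(k) {
    d <- p[(k + 1L):n, , drop = FALSE] - p[seq_len(n - k), , drop = FALSE]
    mean(rowSums(d * d))
  }, numeric(1))
  structure(data.frame(lag = seq_len(max_lag), msd = out,
                       n_pairs = n - seq_len(max_lag)),
            class = c("msd_curve", "data.frame"))
}

## least-squares D from msd values at lags (frames): msd = 4 D (lag dt) [+ c]
fit_D_from_msd <- function(msd, lags, dt, allow_offset) {
  x <- 4 * lags * dt
  if (allow_offset) {
    if (length(lags) < 2L) stop("offset fit needs at least 2 lags")
    cf <- stats::coef(stats::lm(msd ~ x))
    c(D = unname(cf[2L]), intercept = unname(cf[1L]))
  } else {
    c(D = sum(x * msd) / sum(x * x), intercept = 0)
  }
}

#' Diffusion coefficient from a linear TA-MSD fit
#'
#' Least-squares fit of \eqn{\mathrm{TA\text{-}MSD}(\Delta) = 4 D \Delta
#' \Delta t} over `fit_lags`; with `allow_offset` an intercept absorbs the
#' \eqn{4\sigma^2} localization-noise plateau.
#'
#' @param traj a `traj`.
#' @param fit_lags lags (frames) used for the fit; default 1:2, the
#'   near-optimal choice for noiseless Brownian motion.
#' @param allow_offset include an intercept (recommended under noise, with
#'   lags 2:10).
#' @return the estimated D, with the fitted intercept as attribute
#'   `"intercept"`.
#' @export
fit_D <- function(traj, fit_lags = 1:2, allow_offset = FALSE) {
  mc <- tamsd(traj, max(fit_lags))
  f <- fit_D_from_msd(mc$msd[fit_lags], fit_lags, traj$dt, allow_offset)
  structure(f[["D"]], intercept = f[["intercept"]])
}

#' Anomalous exponent from a log-log TA-MSD fit
#'
#' Slope of \eqn{\log \mathrm{TA\text{-}MSD}(\Delta)} versus
#' \eqn{\log \Delta} over `fit_lags`.
#'
#' @param traj a `traj`.
#' @param fit_lags lags (frames), at least 2.
#' @return the estimated alpha.
#' @export
fit_alpha <- function(traj, fit_lags = 1:5) {
  if (length(fit_lags) < 2L) stop("need at least 2 lags")
  mc <- tamsd(traj, max(fit_lags))
  y <- mc$msd[fit_lags]
  if (any(y <= 0)) stop("zero TA-MSD in the fit range")
  unname(stats::coef(stats::lm(log(y) ~ log(fit_lags * traj$dt)))[2L])
}

#' Sliding-window pointwise TA-MSD profile
#'
#' Classical per-step estimate of D or alpha: at every frame the TA-MSD is
#' computed within a window of `window` frames centered on that frame
#' (truncated at the edges, never below half a window), and fitted as in
#' [fit_D()] / [fit_alpha()]. Used both as the model-free baseline and as
#' the comparator for continuous diffusivity changes.
#'
#' @param traj a `traj`.
#' @param window window size in frames (>= 5).
#' @param target `"D"` or `"alpha"`.
#' @param fit_lags lags used within each window; defaults: 1:2 for D,
#'   `1:max(2, floor(window/5))` for alpha.
#' @param allow_offset intercept in the D fit.
#' @return a [pointwise_profile()] (log10 scale for D) of length n.
#' @export
sliding_profile <- function(traj, window, target = c("D", "alpha"),
                            fit_lags = NULL, allow_offset = FALSE) {
  target <- match.arg(target)
  n <- n_steps(traj)
  if (window < 5L) stop("window < 5 gives unstable fits")
  if (window > n) stop("window exceeds trajectory length")
  if (is.null(fit_lags))
    fit_lags <- if (target == "D") 1:2 else seq_len(max(2L, window %/% 5L))
  h <- window %/% 2L
  p <- traj$positions
  ## squared displacements per lag, with rolling sums for O(n) window MSDs
  msd_win <- matrix(0, n, length(fit_lags))
  cnt_win <- matrix(0, n, length(fit_lags))
  i <- seq_len(n)
  lo <- pmax(1L, i - h); hi <- pmin(n, i + h)
  for (j in seq_along(fit_lags)) {
    k <- fit_lags[j]
    d <- p[(k + 1L):n, , drop = FALSE] - p[seq_len(n - k), , drop = FALSE]
    s <- c(0, cumsum(rowSums(d * d)))       # s[t+1] = sum of first t pairs
    t_hi <- pmin(hi - k, n - k); t_lo <- lo
    cnt <- pmax(0L, t_hi - t_lo + 1L)
    val <- s[pmax(t_hi, 0L) + 1L] - s[pmin(pmax(t_lo - 1L, 0L), n - k) + 1L]
    msd_win[, j] <- ifelse(cnt > 0, val / cnt, NA_real_)
    cnt_win[, j] <- cnt
  }
  dt <- traj$dt
  if (target == "D") {
    if (allow_offset) {
      x <- 4 * fit_lags * dt
      sx <- sum(x); sxx <- sum(x * x); m <- length(x)
      sy <- rowSums(msd_win); sxy <- msd_win %*% x
      slope <- (m * sxy - sx * sy) / (m * sxx - sx * sx)
      est <- as.numeric(slope)
    } else {
      x <- 4 * fit_lags * dt
      est <- as.numeric(msd_win %*% x) / sum(x * x)
    }
    est <- pmax(est, 1e-12)                 # log10 scale needs positivity
    pointwise_profile(log10(est), "D")
  } else {
    y <- log(pmax(msd_win, 1e-300))
    x <- log(fit_lags * dt); xc <- x - mean(x)
    est <- as.numeric(y %*% xc) / sum(xc * xc)
    pointwise_profile(est, "alpha")
  }
}

#' Ensemble mean squared displacement
#'
#' \eqn{\mathrm{MSD}(t) = \langle \lVert r(t) - r(0) \rVert^2 \rangle}
#' averaged over a collection of trajectories of equal length.
#'
#' @param trajs list of `traj` objects with identical n and dt.
#' @return data frame with columns `lag` (frames) and `msd`.
#' @export
ensemble_msd <- function(trajs) {
  n <- n_steps(trajs[[1L]])
  acc <- numeric(n - 1L)
  for (tr in trajs) {
    d <- tr$positions[-1L, , drop = FALSE] -
      matrix(tr$positions[1L, ], n - 1L, 2L, byrow = TRUE)
    acc <- acc + rowSums(d * d)
  }
  data.frame(lag = seq_len(n - 1L), msd = acc / length(trajs))
}

#' Power-law exponent of an MSD curve
#'
#' Log-log regression slope of `msd` versus time over a lag range.
#'
#' @param msd_df data frame with `lag` and `msd` (e.g. [ensemble_msd()]).
#' @param fit_range inclusive lag range (frames) used in the fit.
#' @param dt frame interval.
#' @return the fitted exponent.
#' @export
msd_exponent <- function(msd_df, fit_range = c(1, max(msd_df$lag)), dt = 1) {
  sel <- msd_df$lag >= fit_range[1] & msd_df$lag <= fit_range[2] & msd_df$msd > 0
  if (sum(sel) < 2L) stop("fewer than 2 usable lags in fit_range")
  unname(stats::coef(stats::lm(log(msd_df$msd[sel]) ~
                                 log(msd_df$lag[sel] * dt)))[2L])
}
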