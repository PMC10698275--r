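## Segment-level analysis operators: power-law tails of the diffusivity
## distribution, dwell-time/diffusivity coupling, diffusive-state clustering,
## turning angles and confinement radii.

#' Maximum-likelihood exponent of a truncated power-law density
#'
#' Fits the density \eqn{p(D) = \sigma D^{\sigma-1} / (b^\sigma - a^\sigma)}
#' on `tail_bounds` = (a, b) by maximum likelihood, using only the values
#' inside the bounds. The exponent is reported in the
#' \eqn{p(D) \propto D^{\sigma-1}} convention.
#'
#' @param values positive observations (e.g. per-segment diffusion
#'   coefficients).
#' @param tail_bounds fitting window (a, b), 0 < a < b.
#' @return the ML estimate of sigma.
#' @export
fit_powerlaw_tail <- function(values, tail_bounds) {
  a <- tail_bounds[1]; b <- tail_bounds[2]
  stopifnot(a > 0, a < b)
  x <- values[values >= a & values <= b]
  if (length(x) < 50L) stop("fewer than 50 values inside tail_bounds")
  if (stats::sd(log(x)) == 0) stop("degenerate (constant) data")
  slx <- sum(log(x)); n <- length(x)
  nll <- function(s) -(n * log(s) + (s - 1) * slx - n * log(b^s - a^s))
  stats::optimize(nll, c(1e-4, 20))$minimum
}

#' Dwell-time versus diffusivity coupling exponent
#'
#' Estimates \eqn{\gamma} in the coupling \eqn{\tau(D) \sim D^{-\gamma}} by
#' robust regression of \eqn{\log \tau} on \eqn{\log D} over a segment
#' table; returns \eqn{\gamma = -\mathrm{slope}}. Missed changepoints
#' between similar-D segments can produce a faint secondary band at
#' \eqn{2 D^{-\gamma}}, which the robust fit down-weights.
#'
#' @param segment_table data frame with positive `tau` and `mean_D`.
#' @return the gamma estimate.
#' @export
dwell_vs_D <- function(segment_table) {
  tau <- segment_table$tau; D <- segment_table$mean_D
  if (length(tau) < 20L) stop("need at least 20 segments")
  if (any(tau <= 0) || any(D <= 0)) stop("tau and mean_D must be positive")
  fit <- tryCatch(
    MASS::rlm(log(tau) ~ log(D), maxit = 100),
    error = function(e) stats::lm(log(tau) ~ log(D)),
    warning = function(w) stats::lm(log(tau) ~ log(D)))
  -unname(stats::coef(fit)[2L])
}

#' Cluster segments into diffusive states
#'
#' k-means on the standardized per-segment features
#' (\eqn{\log_{10} D}, \eqn{\alpha}), with the number of states chosen by
#' the elbow method: the k maximizing the discrete second difference
#' (curvature) of the log within-cluster dispersion curve. The log scale
#' makes the criterion sensitive to where the *relative* dispersion drop
#' levels off, so a dominant first split cannot mask later structure.
#' Occupancies are time-weighted by segment dwell.
#'
#' @param segment_table data frame with `mean_D`, `mean_alpha`, `tau`.
#' @param k_candidates candidate state counts (contiguous, >= 3 values).
#' @param nstart k-means restarts.
#' @return list of class `state_clustering`: `k`, `labels`, `centers`
#'   (original feature units), `occupancy`, `wss`.
#' @export
cluster_segments <- function(segment_table, k_candidates = 1:8, nstart = 10L) {
  f <- cbind(log10(segment_table$mean_D), segment_table$mean_alpha)
  if (!all(is.finite(f))) stop("non-finite segment features")
  if (nrow(f) < max(k_candidates) * 5L) stop("too few segments for clustering")
  mu <- colMeans(f); sdv <- apply(f, 2L, stats::sd)
  if (any(sdv == 0)) stop("degenerate segment features")
  z <- sweep(sweep(f, 2L, mu), 2L, sdv, "/")
  ks <- sort(k_candidates)
  fits <- lapply(ks, function(k)
    stats::kmeans(z, centers = k, nstart = nstart, iter.max = 50L))
  wss <- vapply(fits, function(f) f$tot.withinss, numeric(1))
  k_best <- if (length(ks) < 3L) ks[length(ks)] else {
    lw <- log(pmax(wss, 1e-12))
    curv <- diff(diff(lw))                  # lw[k-1] - 2 lw[k] + lw[k+1]
    ks[which.max(curv) + 1L]
  }
  fit <- fits[[match(k_best, ks)]]
  tau <- segment_table$tau
  occ <- as.numeric(tapply(tau, factor(fit$cluster, levels = seq_len(k_best)),
                           sum))
  occ[is.na(occ)] <- 0
  occ <- occ / sum(tau)
  centers <- cbind(D = 10^(fit$centers[, 1L] * sdv[1L] + mu[1L]),
                   alpha = fit$centers[, 2L] * sdv[2L] + mu[2L])
  structure(list(k = k_best, labels = fit$cluster, centers = centers,
                 occupancy = occ, wss = data.frame(k = ks, wss = wss)),
            class = "state_clustering")
}

#' @export
print.state_clustering <- function(x, ...) {
  cat(sprintf("diffusive-state clustering: k = %d\n", x$k))
  df <- data.frame(D = x$centers[, "D"], alpha = x$centers[, "alpha"],
                   occupancy = x$occupancy)
  print(format(df, digits = 3), row.names = TRUE)
  invisible(x)
}

#' Turning angles between successive steps
#'
#' The angle between consecutive displacement vectors, in degrees: 0 means
#' persistent (directed) motion, 180 a reversal (typical of confinement).
#' Zero-length steps are skipped.
#'
#' @param traj a `traj` with at least 3 frames.
#' @return numeric vector of angles in [0, 180].
#' @export
turning_angles <- function(traj) {
  p <- traj$positions
  if (nrow(p) < 3L) stop("need at least 3 frames")
  d <- diff(p)
  len <- sqrt(rowSums(d * d))
  keep <- len > 0
  d <- d[keep, , drop = FALSE]; len <- len[keep]
  if (nrow(d) < 2L) return(numeric(0))
  m <- nrow(d)
  dot <- rowSums(d[-m, , drop = FALSE] * d[-1L, , drop = FALSE])
  cosang <- pmin(1, pmax(-1, dot / (len[-m] * len[-1L])))
  acos(cosang) * 180 / pi
}

#' Confinement radius of a trajectory segment
#'
#' Radius of gyration: the root-mean-square distance of the positions from
#' their centroid, in the input length unit. A proxy for the spatial extent
#' of restricted motion.
#'
#' @param traj a `traj` (or n x 2 position matrix) with at least 3 frames.
#' @return nonnegative radius.
#' @export
confinement_radius <- function(traj) {
  p <- if (inherits(traj, "traj")) traj$positions else as.matrix(traj)
  if (nrow(p) < 3L) stop("segment shorter than 3 frames")
  ctr <- colMeans(p)
  sqrt(mean((p[, 1L] - ctr[1L])^2 + (p[, 2L] - ctr[2L])^2))
}
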