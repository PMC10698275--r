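## Kernel changepoint detection (KCPD) and conversion of changepoints into
## per-segment summaries.
##
## The detector minimizes the standard kernel segmentation cost
##   sum_j [ len_j - (1/len_j) sum_{s,t in seg_j} k(x_s, x_t) ] + penalty * (#segments)
## with a radial-basis kernel and median-heuristic bandwidth, by exact
## dynamic programming (O(n^2) once the Gram matrix is integrated).

#' Default KCPD penalties
#'
#' Linear per-segment penalties calibrated on simulated single-changepoint
#' benchmarks (maximizing the mean Jaccard index at the benchmark's
#' tolerance), one per input type: `raw` for two-channel displacement
#' series, `profile` for model-predicted pointwise profiles, and
#' `sliding_alpha` for sliding-window TA-MSD alpha profiles.
#'
#' @return named numeric vector of penalties.
#' @export
kcpd_defaults <- function() c(raw = 2.5, profile = 4, sliding_alpha = 18)

#' Kernel changepoint detection
#'
#' Detects distribution changes in a one- or multi-channel per-step series
#' using an RBF kernel with median-heuristic bandwidth and a linear penalty
#' per segment, solved by exact dynamic programming. Larger penalties yield
#' fewer changepoints; an empty set is allowed.
#'
#' @param series numeric vector or n x c matrix of per-step values.
#' @param penalty linear penalty per additional segment; default
#'   `kcpd_defaults()["raw"]`.
#' @param min_size minimum segment length in steps (>= 2).
#' @return integer vector of 0-based changepoint indices (first step of each
#'   new segment), with attributes `penalty` and `cost`.
#' @export
detect_changepoints <- function(series, penalty = NULL, min_size = 3L) {
  X <- as.matrix(series)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("series contains non-finite values")
  n <- nrow(X)
  if (n < 2L * min_size) stop("series shorter than 2 * min_size")
  if (is.null(penalty)) penalty <- unname(kcpd_defaults()["raw"])

  ## squared distances and median-heuristic RBF Gram matrix
  sq <- rowSums(X * X)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  med <- stats::median(D2[upper.tri(D2)][D2[upper.tri(D2)] > 0])
  if (!length(med) || !is.finite(med) || med == 0)
    return(structure(integer(0), penalty = penalty, cost = 0))
  K <- exp(-D2 / med)

  ## integrated Gram matrix with zero padding: Cp[i+1, j+1] = sum K[1:i, 1:j]
  Cp <- matrix(0, n + 1L, n + 1L)
  Cp[-1L, -1L] <- apply(apply(K, 2L, cumsum), 1L, cumsum)
  dg <- diag(Cp)

  ## F[t+1] = optimal cost of x[1..t]; F[1] = -penalty
  F <- rep(Inf, n + 1L)
  F[1L] <- -penalty
  prev <- integer(n + 1L)
  for (t in min_size:n) {
    s <- 0L
    if (t >= 2L * min_size) s <- c(0L, min_size:(t - min_size))
    len <- t - s
    blk <- dg[t + 1L] - 2 * Cp[s + 1L, t + 1L] + dg[s + 1L]
    cand <- F[s + 1L] + (len - blk / len) + penalty
    j <- which.min(cand)
    F[t + 1L] <- cand[j]
    prev[t + 1L] <- s[j]
  }
  cps <- integer(0)
  t <- n
  while (t > 0L) {
    s <- prev[t + 1L]
    if (s > 0L) cps <- c(s, cps)
    t <- s
  }
  structure(as.integer(cps), penalty = penalty, cost = F[n + 1L])
}

#' Two-channel displacement series of a trajectory
#'
#' Per-step displacement components `(dx, dy)`, zero-padded at the first
#' frame so the series length equals the trajectory length. This is the
#' model-free input to [detect_changepoints()].
#'
#' @param traj a `traj`.
#' @return n x 2 matrix.
#' @export
displacement_series <- function(traj) {
  p <- traj$positions
  rbind(c(0, 0), diff(p))
}

#' Segment a trajectory from pointwise property profiles
#'
#' Runs KCPD on one profile, or jointly on two stacked profiles (each channel
#' standardized so the kernel weighs them comparably), and summarizes each
#' resulting segment: mean D (averaged on the log10 scale, reported linear),
#' mean alpha, and dwell time.
#'
#' @param traj a `traj`.
#' @param profiles a [pointwise_profile()] or a list of up to two (one per
#'   target), each aligned with `traj`.
#' @param penalty KCPD penalty; default `kcpd_defaults()["profile"]`.
#' @param min_size minimum segment length.
#' @return data frame of class `segment_table` with columns `traj_id`,
#'   `start`, `end` (0-based, half-open), `tau`, `mean_D`, `mean_alpha`;
#'   changepoints in attribute `"changepoints"`.
#' @export
segment_trajectory <- function(traj, profiles, penalty = NULL, min_size = 3L) {
  if (inherits(profiles, "pointwise_profile")) profiles <- list(profiles)
  n <- n_steps(traj)
  for (pr in profiles)
    if (length(pr$values) != n) stop("profile length does not match trajectory")
  if (is.null(penalty)) penalty <- unname(kcpd_defaults()["profile"])
  ch <- vapply(profiles, function(pr) {
    v <- pr$values
    s <- stats::sd(v)
    if (length(profiles) > 1L && is.finite(s) && s > 0) (v - mean(v)) / s else v
  }, numeric(n))
  cps <- detect_changepoints(ch, penalty = penalty, min_size = min_size)
  targets <- vapply(profiles, function(pr) pr$target, character(1))
  segs <- segments_from_cps(cps, n)
  get_mean <- function(target, f) {
    j <- match(target, targets)
    if (is.na(j)) return(rep(NA_real_, nrow(segs)))
    v <- profiles[[j]]$values
    vapply(seq_len(nrow(segs)),
           function(i) f(mean(v[(segs$start[i] + 1L):segs$end[i]])), numeric(1))
  }
  out <- data.frame(
    traj_id = if (is.null(traj$id)) 1L else traj$id,
    start = segs$start, end = segs$end,
    tau = (segs$end - segs$start) * traj$dt,
    mean_D = get_mean("D", function(m) 10^m),
    mean_alpha = get_mean("alpha", identity))
  structure(out, changepoints = as.integer(cps),
            class = c("segment_table", "data.frame"))
}

#' Segment table from known changepoints and ground truth
#'
#' Builds the per-segment summary directly from a ground-truth profile (or
#' any per-step labels), bypassing detection — used for oracle-segmented
#' analyses.
#'
#' @param gt a [gt_profile()].
#' @param dt frame interval.
#' @param traj_id identifier.
#' @return a `segment_table` data frame.
#' @export
segment_table_from_gt <- function(gt, dt = 1, traj_id = 1L) {
  n <- length(gt$D)
  segs <- segments_from_cps(gt$changepoints, n)
  idx <- lapply(seq_len(nrow(segs)), function(i) (segs$start[i] + 1L):segs$end[i])
  out <- data.frame(
    traj_id = traj_id, start = segs$start, end = segs$end,
    tau = (segs$end - segs$start) * dt,
    mean_D = vapply(idx, function(j) exp(mean(log(gt$D[j]))), numeric(1)),
    mean_alpha = vapply(idx, function(j) mean(gt$alpha[j]), numeric(1)))
  structure(out, changepoints = gt$changepoints,
            class = c("segment_table", "data.frame"))
}
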