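#' Trajectory object
#'
#' A 2D single-particle trajectory sampled on a regular time grid. Positions
#' are stored as an n x 2 matrix in the input length unit; `dt` is the frame
#' interval in the input time unit. All indices exposed by the package
#' (frames, changepoints, segment bounds) are 0-based, and segments are
#' half-open `[start, end)` intervals of step indices.
#'
#' @param positions numeric matrix (or 2-column data frame) of x, y positions.
#' @param dt frame interval; must be positive.
#' @param id optional trajectory identifier carried through to file output.
#' @return An object of class `traj`.
#' @examples
#' tr <- trajectory(cbind(0:9, 0), dt = 1)
#' n_steps(tr)
#' @export
trajectory <- function(positions, dt = 1, id = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L)
    stop("positions must have two columns (x, y)")
  storage.mode(positions) <- "double"
  dimnames(positions) <- NULL
  if (nrow(positions) < 2L)
    stop("a trajectory needs at least 2 positions")
  if (!all(is.finite(positions)))
    stop("positions must be finite")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a single positive number")
  structure(list(positions = positions, dt = dt, id = id), class = "traj")
}

#' @export
print.traj <- function(x, ...) {
  cat(sprintf("2D trajectory: %d steps, dt = %g%s\n", nrow(x$positions),
              x$dt, if (!is.null(x$id)) paste0(", id = ", x$id) else ""))
  invisible(x)
}

#' Number of time steps in a trajectory
#' @param traj a `traj` object.
#' @return integer step count.
#' @export
n_steps <- function(traj) nrow(traj$positions)

#' Ground-truth property profile of a simulated trajectory
#'
#' Per-step true diffusion coefficient, anomalous exponent and generating
#' model, plus the list of changepoints (0-based indices of the first step of
#' each new segment).
#'
#' @param D per-step diffusion coefficient (length^2 / time), positive.
#' @param alpha per-step anomalous exponent in (0, 2].
#' @param model per-step generating-model tag (character).
#' @param changepoints strictly increasing 0-based indices in (0, n).
#' @return An object of class `gt_profile`.
#' @export
gt_profile <- function(D, alpha, model, changepoints = integer(0)) {
  n <- length(D)
  if (length(alpha) != n || length(model) != n)
    stop("D, alpha and model must have equal lengths")
  if (any(D <= 0)) stop("D_true must be positive")
  if (any(alpha <= 0 | alpha > 2)) stop("alpha_true must lie in (0, 2]")
  changepoints <- as.integer(changepoints)
  if (length(changepoints)) {
    if (is.unsorted(changepoints, strictly = TRUE))
      stop("changepoints must be strictly increasing")
    if (any(changepoints <= 0L | changepoints >= n))
      stop("changepoints must lie strictly inside (0, n)")
  }
  structure(list(D = as.numeric(D), alpha = as.numeric(alpha),
                 model = as.character(model), changepoints = changepoints),
            class = "gt_profile")
}

#' @export
print.gt_profile <- function(x, ...) {
  cat(sprintf("ground truth: %d steps, %d changepoint(s), models: %s\n",
              length(x$D), length(x$changepoints),
              paste(unique(x$model), collapse = ", ")))
  invisible(x)
}

#' Per-step predicted property profile
#'
#' The pointwise output of a model or baseline: one value per trajectory step.
#' For `target = "D"` values are on the log10 scale.
#'
#' @param values numeric vector, one value per step.
#' @param target `"D"` (log10 diffusion coefficient) or `"alpha"`.
#' @return An object of class `pointwise_profile`.
#' @export
pointwise_profile <- function(values, target = c("D", "alpha")) {
  target <- match.arg(target)
  structure(list(values = as.numeric(values), target = target),
            class = "pointwise_profile")
}

#' @export
print.pointwise_profile <- function(x, ...) {
  cat(sprintf("pointwise %s profile, %d steps (mean %.3g)\n",
              if (x$target == "D") "log10 D" else "alpha",
              length(x$values), mean(x$values)))
  invisible(x)
}

#' Linear-scale diffusion coefficients from a D profile
#' @param profile a `pointwise_profile` with target `"D"`.
#' @return numeric vector of per-step D on the linear scale.
#' @export
profile_D_linear <- function(profile) {
  if (profile$target != "D") stop("profile target is not D")
  10^profile$values
}

## internal: expand changepoints into a 0-based segment table [start, end)
segments_from_cps <- function(cps, n) {
  bounds <- c(0L, as.integer(cps), as.integer(n))
  data.frame(start = bounds[-length(bounds)], end = bounds[-1L])
}

## internal: per-step segment index (1-based) from 0-based changepoints
segment_index <- function(cps, n) {
  idx <- rep.int(1L, n)
  if (length(cps)) idx <- findInterval(seq_len(n) - 1L, c(0L, cps))
  idx
}
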