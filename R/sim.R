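## Simulators for heterogeneous-diffusion trajectories.
##
## All generators work on a regular time grid with frame interval `dt` and
## produce `traj` objects (n positions = n frames). The per-step property at
## frame k (0-based) governs the displacement *into* frame k, so a changepoint
## at index k means the displacement k-1 -> k is already drawn from the new
## segment's law.

#' Rate of a truncated exponential with a prescribed mean
#'
#' Finds the unique rate \eqn{\lambda} such that an exponential distribution
#' truncated to `bounds` has the given mean, by root finding on the
#' closed-form truncated-exponential mean
#' \deqn{m(\lambda) = a + 1/\lambda - (b-a) e^{-\lambda (b-a)} / (1 - e^{-\lambda (b-a)}).}
#'
#' @param bounds length-2 numeric, truncation interval `(a, b)`.
#' @param mean target mean; must lie in `(a, (a+b)/2)` for a decaying
#'   exponential.
#' @return the calibrated rate (1 / time steps).
#' @export
truncexp_rate <- function(bounds, mean) {
  a <- bounds[1]; b <- bounds[2]
  if (!(a < mean && mean < (a + b) / 2))
    stop(sprintf("infeasible dwell configuration: mean %g outside (%g, %g)",
                 mean, a, (a + b) / 2))
  w <- b - a
  m <- function(lam) a + 1 / lam - w * exp(-lam * w) / (1 - exp(-lam * w)) - mean
  stats::uniroot(m, c(1e-8, 10), tol = 1e-12)$root
}

#' Sample integer dwell times from a truncated exponential
#'
#' Dwell times are drawn from an exponential distribution truncated to
#' `dwell_bounds`, with the rate calibrated so the (continuous) truncated mean
#' equals `dwell_mean`, and rounded to integer steps. Defaults follow the
#' benchmark convention of segments between 10 and 190 steps with mean 57.
#'
#' @param count number of samples.
#' @param dwell_bounds truncation interval in steps.
#' @param dwell_mean target mean dwell in steps.
#' @return integer vector of dwell times.
#' @export
sample_dwell_times <- function(count, dwell_bounds = c(10, 190),
                               dwell_mean = 57) {
  stopifnot(count >= 1)
  lam <- truncexp_rate(dwell_bounds, dwell_mean)
  a <- dwell_bounds[1]; w <- dwell_bounds[2] - a
  u <- stats::runif(count)
  t <- a - log(1 - u * (1 - exp(-lam * w))) / lam
  as.integer(round(t))
}

#' Piecewise Brownian motion from a per-step diffusion-coefficient profile
#'
#' Displacements are independent Gaussians with per-axis variance
#' \eqn{2 D(t) \Delta t}; `D_profile[k]` governs the displacement into frame
#' k (the first entry labels frame 0, which has no displacement).
#'
#' @param D_profile nonnegative per-step diffusion coefficients, length n.
#' @param dt frame interval.
#' @param origin starting position.
#' @return a `traj` with `length(D_profile)` frames.
#' @export
simulate_piecewise_bm <- function(D_profile, dt = 1, origin = c(0, 0)) {
  if (any(D_profile < 0)) stop("D_profile must be nonnegative")
  n <- length(D_profile)
  if (n < 2L) stop("need at least 2 steps")
  sd <- sqrt(2 * D_profile[-1L] * dt)
  incr <- cbind(stats::rnorm(n - 1L, 0, sd), stats::rnorm(n - 1L, 0, sd))
  pos <- rbind(origin, sweep(apply(incr, 2L, cumsum), 2L, -origin))
  ## apply() drops dims when n == 2
  if (n == 2L) pos <- rbind(origin, incr + origin)
  trajectory(pos, dt)
}

## fGn autocovariance at lag k for Hurst H (unit spacing, unit variance)
fgn_autocov <- function(k, H) {
  k <- abs(k)
  0.5 * ((k + 1)^(2 * H) - 2 * k^(2 * H) + abs(k - 1)^(2 * H))
}

.fbm_cache <- new.env(parent = emptyenv())

## upper Cholesky factor of the n x n standard fGn covariance, cached
fgn_chol <- function(n, H) {
  key <- sprintf("%d_%.8f", n, H)
  R <- .fbm_cache[[key]]
  if (is.null(R)) {
    C <- stats::toeplitz(fgn_autocov(0:(n - 1L), H))
    R <- chol(C)
    ## keep the cache small; factors for long ensembles dominate memory
    if (length(ls(.fbm_cache)) > 8L) rm(list = ls(.fbm_cache), envir = .fbm_cache)
    .fbm_cache[[key]] <- R
  }
  R
}

## one standard fGn sequence via circulant embedding (Davies-Harte);
## O(n log n), used for long sequences where the dense factor is too big
fgn_davies_harte <- function(n, H) {
  M <- 2L * n
  r <- fgn_autocov(c(0:n, (n - 1L):1L), H)
  lam <- Re(stats::fft(r))
  if (min(lam) < -1e-8 * max(lam)) stop("circulant embedding not nonnegative")
  lam[lam < 0] <- 0
  w <- complex(M)
  w[1L] <- sqrt(lam[1L] / M) * stats::rnorm(1L)
  w[n + 1L] <- sqrt(lam[n + 1L] / M) * stats::rnorm(1L)
  k <- 2L:n
  z1 <- stats::rnorm(n - 1L); z2 <- stats::rnorm(n - 1L)
  w[k] <- sqrt(lam[k] / (2 * M)) * complex(real = z1, imaginary = z2)
  w[M - k + 2L] <- Conj(w[k])
  Re(stats::fft(w))[1L:n]
}

## m x n matrix of standard fGn rows: exact dense factorization (cached) for
## short sequences, circulant embedding for long ones
fgn_sample <- function(m, n, H) {
  if (n <= 2048L) {
    R <- fgn_chol(n, H)
    matrix(stats::rnorm(m * n), m, n) %*% R
  } else {
    t(vapply(seq_len(m), function(i) fgn_davies_harte(n, H), numeric(n)))
  }
}

#' Fractional Brownian motion
#'
#' Exact 2D fBm with Hurst exponent \eqn{H = \alpha/2}: per-axis increments
#' are fractional Gaussian noise (sampled through a Cholesky factorization of
#' the exact covariance), scaled so the ensemble MSD is
#' \eqn{\mathrm{MSD}(t) = 4 D t^\alpha}.
#'
#' @param n number of frames.
#' @param alpha anomalous exponent in (0, 2) (exclusive).
#' @param D generalized diffusion coefficient.
#' @param dt frame interval.
#' @return a `traj`.
#' @export
simulate_fbm <- function(n, alpha, D = 1, dt = 1) {
  if (alpha <= 0 || alpha >= 2) stop("fBm requires alpha in (0, 2)")
  H <- alpha / 2
  s <- sqrt(2 * D) * dt^H
  incr <- t(fgn_sample(2L, n - 1L, H)) * s
  trajectory(rbind(c(0, 0), apply(incr, 2L, cumsum)), dt)
}

#' Scaled Brownian motion
#'
#' Gaussian increments with a deterministic time-dependent diffusivity
#' \eqn{D(t) = D_0 \alpha t^{\alpha-1}}, normalized so the ensemble MSD is
#' \eqn{4 D_0 t^\alpha}. The displacement into frame k integrates D(t) over
#' the frame interval exactly.
#'
#' @param n number of frames.
#' @param alpha anomalous exponent in (0, 2].
#' @param D0 amplitude of the MSD power law.
#' @param dt frame interval.
#' @return a `traj`.
#' @export
simulate_sbm <- function(n, alpha, D0 = 1, dt = 1) {
  if (alpha <= 0 || alpha > 2) stop("SBM requires alpha in (0, 2]")
  k <- seq_len(n - 1L)
  ## per-axis variance of increment k: 2 D0 ((k dt)^a - ((k-1) dt)^a)
  v <- 2 * D0 * ((k * dt)^alpha - ((k - 1) * dt)^alpha)
  incr <- cbind(stats::rnorm(n - 1L, 0, sqrt(v)), stats::rnorm(n - 1L, 0, sqrt(v)))
  trajectory(rbind(c(0, 0), apply(incr, 2L, cumsum)), dt)
}

#' Continuous-time random walk
#'
#' Waiting times with a power-law tail \eqn{\psi(t) \sim t^{-1-\alpha}}
#' (Pareto, minimum one frame) separate instantaneous Gaussian jumps;
#' positions are sampled on the regular frame grid, so the walker sits still
#' between jumps. Subdiffusive: the ensemble MSD grows as \eqn{t^\alpha}.
#'
#' @param n number of frames.
#' @param alpha anomalous exponent in (0, 1].
#' @param D jump-scale coefficient (jump variance per axis is `2 D dt`).
#' @param dt frame interval.
#' @return a `traj`.
#' @export
simulate_ctrw <- function(n, alpha, D = 1, dt = 1) {
  if (alpha <= 0 || alpha > 1) stop("CTRW requires alpha in (0, 1]")
  t_end <- n * dt
  ## expected number of events is bounded by t_end (waits >= dt)
  times <- numeric(0); t <- 0
  while (t < t_end) {
    m <- max(16L, ceiling((t_end - t) / dt))
    w <- dt * stats::runif(m)^(-1 / alpha)
    tt <- t + cumsum(w)
    times <- c(times, tt)
    t <- tt[length(tt)]
  }
  times <- times[times < t_end]
  k <- length(times)
  sd <- sqrt(2 * D * dt)
  jumps <- cbind(stats::rnorm(k, 0, sd), stats::rnorm(k, 0, sd))
  grid <- (seq_len(n) - 1L) * dt
  idx <- findInterval(grid, times)      # events completed by each frame
  path <- rbind(c(0, 0), apply(jumps, 2L, cumsum))
  if (k == 1L) path <- rbind(c(0, 0), jumps)
  trajectory(path[idx + 1L, , drop = FALSE], dt)
}

#' Levy walk
#'
#' Constant-speed flights in random directions with power-law flight times
#' \eqn{\psi(t) \sim t^{-1-(3-\alpha)}}; the ensemble MSD grows as
#' \eqn{t^\alpha} for \eqn{\alpha \in (1, 2)} and ballistically for
#' \eqn{\alpha = 2}. Positions are sampled on the regular frame grid.
#'
#' @param n number of frames.
#' @param alpha anomalous exponent in [1, 2].
#' @param speed flight speed (length / time).
#' @param dt frame interval.
#' @return a `traj`.
#' @export
simulate_lw <- function(n, alpha, speed = 1, dt = 1) {
  if (alpha < 1 || alpha > 2) stop("LW requires alpha in [1, 2]")
  sig <- 3 - alpha                      # flight-time tail exponent
  t_end <- n * dt
  ft <- numeric(0); t <- 0
  while (t < t_end) {
    m <- max(16L, ceiling((t_end - t) / dt))
    w <- if (sig == 1) dt / stats::runif(m) else dt * stats::runif(m)^(-1 / sig)
    ft <- c(ft, w)
    t <- t + sum(w)
  }
  bounds <- c(0, cumsum(ft))
  theta <- stats::runif(length(ft), 0, 2 * pi)
  vx <- speed * cos(theta); vy <- speed * sin(theta)
  grid <- (seq_len(n) - 1L) * dt
  seg <- findInterval(grid, bounds, rightmost.closed = TRUE)
  ## position = completed flights + partial current flight
  cx <- c(0, cumsum(vx * ft)); cy <- c(0, cumsum(vy * ft))
  rem <- grid - bounds[seg]
  pos <- cbind(cx[seg] + vx[seg] * rem, cy[seg] + vy[seg] * rem)
  trajectory(pos, dt)
}

#' Simulate one anomalous-diffusion segment
#'
#' Dispatches to the model-specific simulator; enforces the admissible
#' (model, alpha) domain: CTRW and ATTM are subdiffusive only
#' (\eqn{\alpha \le 1}), LW superdiffusive only (\eqn{\alpha \ge 1}).
#'
#' @param model_tag one of `"BM"`, `"fBm"`, `"SBM"`, `"CTRW"`, `"LW"`,
#'   `"ATTM"`.
#' @param n number of frames.
#' @param alpha anomalous exponent.
#' @param D diffusion-coefficient scale.
#' @param dt frame interval.
#' @return a `traj` whose ensemble MSD exponent is `alpha`.
#' @export
simulate_anomalous_segment <- function(model_tag, n, alpha, D = 1, dt = 1) {
  switch(model_tag,
    BM = {
      if (abs(alpha - 1) > 1e-9) stop("BM requires alpha = 1")
      simulate_piecewise_bm(rep(D, n), dt)
    },
    fBm = simulate_fbm(n, alpha, D, dt),
    SBM = simulate_sbm(n, alpha, D, dt),
    CTRW = {
      if (alpha > 1) stop("CTRW is subdiffusive only (alpha <= 1)")
      simulate_ctrw(n, alpha, D, dt)
    },
    ATTM = {
      if (alpha >= 1) stop("ATTM is subdiffusive only (alpha < 1)")
      ## sigma/gamma = alpha with gamma = 1 stays in the anomalous regime
      simulate_attm(n, sigma = alpha, gamma = 1,
                    D_bounds = c(1e-3, 1) * 2 * D, dt = dt)$traj
    },
    LW = {
      if (alpha < 1) stop("LW is superdiffusive only (alpha >= 1)")
      simulate_lw(n, alpha, speed = sqrt(2 * D / dt), dt = dt)
    },
    stop("unknown model tag: ", model_tag)
  )
}

#' Draw diffusion coefficients from the truncated power-law density
#'
#' Inverse-CDF sampling from the density \eqn{p(D) \propto D^{\sigma-1}} on
#' `D_bounds`.
#'
#' @param count number of draws.
#' @param sigma tail exponent (> 0).
#' @param D_bounds support `(D_min, D_max)`.
#' @return numeric vector of diffusion coefficients.
#' @export
sample_powerlaw_D <- function(count, sigma, D_bounds) {
  stopifnot(sigma > 0, D_bounds[1] > 0, D_bounds[1] < D_bounds[2])
  a <- D_bounds[1]^sigma; b <- D_bounds[2]^sigma
  (a + stats::runif(count) * (b - a))^(1 / sigma)
}

#' Annealed transient-time model
#'
#' Brownian motion whose diffusion coefficient is redrawn at random epochs:
#' each segment's D has density \eqn{\propto D^{\sigma-1}} on `D_bounds` and
#' persists for \eqn{\tau = \mathrm{round}(D^{-\gamma})} frames (unit
#' proportionality constant, frame units). In the anomalous regime
#' \eqn{\sigma/\gamma < 1} the ensemble MSD grows as \eqn{t^{\sigma/\gamma}}.
#'
#' @param n_steps trajectory length in frames.
#' @param sigma D-distribution tail exponent.
#' @param gamma dwell-coupling exponent.
#' @param D_bounds support of the D distribution; default `(10^-6.7, 1)`.
#' @param dt frame interval.
#' @return list with elements `traj` and `gt` (a [gt_profile()]).
#' @export
simulate_attm <- function(n_steps, sigma = 0.3, gamma = 0.4,
                          D_bounds = c(10^-6.7, 1), dt = 1) {
  stopifnot(sigma > 0, gamma > 0, n_steps >= 2)
  if (sigma / gamma >= 1)
    warning("sigma/gamma >= 1: not the anomalous regime")
  Ds <- numeric(0); taus <- integer(0); tot <- 0L
  while (tot < n_steps) {
    D <- sample_powerlaw_D(1L, sigma, D_bounds)
    tau <- max(1L, as.integer(round(D^(-gamma))))
    Ds <- c(Ds, D); taus <- c(taus, tau); tot <- tot + tau
  }
  dwell <- taus
  dwell[length(dwell)] <- dwell[length(dwell)] - (tot - n_steps)
  D_prof <- rep.int(Ds, dwell)
  cps <- cumsum(dwell[-length(dwell)])
  traj <- simulate_piecewise_bm(D_prof, dt)
  gt <- gt_profile(D_prof, rep(sigma / gamma, n_steps),
                   rep("ATTM", n_steps), cps)
  list(traj = traj, gt = gt)
}

#' Concatenate model segments into one heterogeneous trajectory
#'
#' Each segment is simulated with its own model, alpha and D, then appended
#' with position continuity (a segment starts where the previous one ended).
#' The per-step ground truth labels every frame with its segment's
#' properties; changepoints sit at the segment boundaries.
#'
#' @param segment_specs data frame with columns `model`, `alpha`, `D`,
#'   `dwell` (frames per segment).
#' @param n_steps total length; the composition is clipped (or the last
#'   segment extended is not allowed — supply enough dwell).
#' @param dt frame interval.
#' @param normalize_segments if TRUE, rescale each segment's displacements to
#'   unit mean-squared displacement per frame before concatenation (used for
#'   the scale-free alpha datasets).
#' @return list with elements `traj` and `gt`.
#' @export
compose_trajectory <- function(segment_specs, n_steps = sum(segment_specs$dwell),
                               dt = 1, normalize_segments = FALSE) {
  specs <- as.data.frame(segment_specs)
  stopifnot(nrow(specs) >= 1, all(specs$dwell >= 1))
  if (sum(specs$dwell) < n_steps)
    stop("segment dwells cover fewer than n_steps frames")
  incr <- NULL; D_lab <- numeric(0); a_lab <- numeric(0); m_lab <- character(0)
  for (i in seq_len(nrow(specs))) {
    d <- specs$dwell[i]
    need <- if (i == 1L) d - 1L else d    # frame 0 has no displacement
    seg_inc <- NULL
    if (need > 0L) {
      seg <- simulate_anomalous_segment(specs$model[i], need + 1L,
                                        specs$alpha[i], specs$D[i], dt)
      seg_inc <- diff(seg$positions)
      if (normalize_segments) {
        msd1 <- mean(rowSums(seg_inc^2))
        if (msd1 > 0) seg_inc <- seg_inc / sqrt(msd1)
      }
    }
    incr <- rbind(incr, seg_inc)
    D_lab <- c(D_lab, rep(specs$D[i], d))
    a_lab <- c(a_lab, rep(specs$alpha[i], d))
    m_lab <- c(m_lab, rep(specs$model[i], d))
  }
  cps <- cumsum(specs$dwell)[-nrow(specs)]
  keep <- seq_len(n_steps)
  pos <- rbind(c(0, 0), apply(incr, 2L, cumsum))[keep, , drop = FALSE]
  cps <- cps[cps < n_steps]
  gt <- gt_profile(D_lab[keep], a_lab[keep], m_lab[keep], cps)
  list(traj = trajectory(pos, dt), gt = gt)
}

#' Add localization noise to a trajectory
#'
#' Independent zero-mean Gaussian offsets of standard deviation
#' `noise_sigma` (same length unit as the positions) are added to every
#' coordinate, emulating the finite localization precision of
#' single-particle tracking.
#'
#' @param traj a `traj`.
#' @param noise_sigma localization SD, nonnegative.
#' @return a noisy `traj`.
#' @export
add_localization_noise <- function(traj, noise_sigma) {
  if (noise_sigma < 0) stop("noise_sigma must be nonnegative")
  if (noise_sigma == 0) return(traj)
  n <- n_steps(traj)
  trajectory(traj$positions + matrix(stats::rnorm(2L * n, 0, noise_sigma), n, 2L),
             traj$dt, traj$id)
}

#' Configuration for piecewise heterogeneous datasets
#'
#' Holds the sampling ranges used to build labeled training and benchmark
#' sets: log-uniform D in `D_range`, uniform alpha in `alpha_range` (clipped
#' to each model's admissible domain), truncated-exponential dwell times,
#' and a uniform localization-noise range.
#'
#' @param n_steps frames per trajectory.
#' @param target `"D"` (Brownian segments, varying D) or `"alpha"`
#'   (anomalous segments, varying alpha, unit-scale segments).
#' @param D_range log-uniform sampling bounds for D.
#' @param alpha_range sampling bounds for alpha.
#' @param dwell_bounds,dwell_mean dwell-time law (steps).
#' @param noise_range localization SD drawn uniformly from this range.
#' @param model_set candidate segment models for `target = "alpha"`.
#' @return an object of class `piecewise_config`.
#' @export
piecewise_config <- function(n_steps = 200L, target = c("D", "alpha"),
                             D_range = c(1e-3, 1e3), alpha_range = c(0.05, 2),
                             dwell_bounds = c(10, 190), dwell_mean = 57,
                             noise_range = c(0, 0),
                             model_set = c("fBm", "SBM", "CTRW", "LW")) {
  target <- match.arg(target)
  stopifnot(dwell_bounds[1] < dwell_mean, dwell_mean < dwell_bounds[2],
            D_range[1] < D_range[2], alpha_range[1] < alpha_range[2])
  structure(list(n_steps = as.integer(n_steps), target = target,
                 D_range = D_range, alpha_range = alpha_range,
                 dwell_bounds = dwell_bounds, dwell_mean = dwell_mean,
                 noise_range = noise_range, model_set = model_set),
            class = "piecewise_config")
}

## admissible alpha interval for a model, intersected with `range`
admissible_alpha <- function(model, range) {
  dom <- switch(model,
    CTRW = c(range[1], min(range[2], 1)),
    ATTM = c(range[1], min(range[2], 0.95)),
    LW   = c(max(range[1], 1), range[2]),
    fBm  = c(range[1], min(range[2], 1.95)),
    SBM  = range,
    BM   = c(1, 1),
    stop("unknown model: ", model))
  if (dom[1] > dom[2]) NULL else dom
}

#' Generate a labeled heterogeneous dataset
#'
#' Draws `n_traj` piecewise trajectories under a [piecewise_config()]:
#' dwell times from the truncated exponential, segment properties from the
#' configured ranges, optional localization noise, and full per-step ground
#' truth. For `target = "D"` all segments are Brownian with log-uniform D;
#' for `target = "alpha"` each segment uses a model drawn from `model_set`
#' with an admissible alpha, and segments are rescaled to unit per-step MSD.
#'
#' @param config a [piecewise_config()].
#' @param n_traj number of trajectories.
#' @param seed optional integer seed for reproducibility.
#' @return list of `list(traj =, gt =)` pairs.
#' @export
generate_dataset <- function(config, n_traj, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_traj), function(i) {
    specs <- NULL; tot <- 0L
    while (tot < config$n_steps) {
      d <- sample_dwell_times(1L, config$dwell_bounds, config$dwell_mean)
      if (config$target == "D") {
        model <- "BM"; alpha <- 1
        D <- 10^stats::runif(1, log10(config$D_range[1]), log10(config$D_range[2]))
      } else {
        repeat {
          model <- sample(config$model_set, 1L)
          dom <- admissible_alpha(model, config$alpha_range)
          if (!is.null(dom)) break
        }
        alpha <- stats::runif(1, dom[1], dom[2])
        D <- 1
      }
      specs <- rbind(specs, data.frame(model = model, alpha = alpha,
                                       D = D, dwell = d))
      tot <- tot + d
    }
    out <- compose_trajectory(specs, config$n_steps, dt = 1,
                              normalize_segments = config$target == "alpha")
    ns <- stats::runif(1, config$noise_range[1], config$noise_range[2])
    if (ns > 0) out$traj <- add_localization_noise(out$traj, ns)
    out$traj$id <- i
    out
  })
}

#' Synthetic multi-state diffusive mixture
#'
#' Generates a segment population emulating a membrane protein switching
#' between four canonical diffusive states (immobile, confined, Brownian,
#' directed), for exercising segment-level clustering. Each segment draws a
#' state from `fractions` (time-weighted via state-specific dwells), a
#' diffusion coefficient lognormally scattered about the state center, and an
#' alpha with Gaussian scatter.
#'
#' @param n_segments number of segments to generate.
#' @param centers data frame with columns `D`, `alpha`, `dwell_mean` (one row
#'   per state); defaults emulate immobile / confined / Brownian / directed
#'   motion.
#' @param fractions target time fractions per state (sum to 1).
#' @param sd_log10D,sd_alpha scatter of segment features about the centers.
#' @param seed optional integer seed.
#' @return data frame with columns `traj_id`, `start`, `end`, `tau`,
#'   `mean_D`, `mean_alpha`, `state` (generating state index).
#' @export
simulate_multistate_segments <- function(n_segments = 2000,
    centers = data.frame(D = c(1.2e-5, 0.06, 0.10, 0.14),
                         alpha = c(0.23, 0.46, 0.88, 1.30),
                         dwell_mean = c(60, 40, 50, 45)),
    fractions = c(0.40, 0.15, 0.25, 0.20),
    sd_log10D = 0.25, sd_alpha = 0.08, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(centers)
  stopifnot(length(fractions) == k, abs(sum(fractions) - 1) < 1e-8)
  ## segment-count weights so that time-weighted occupancy matches fractions
  w <- fractions / centers$dwell_mean
  state <- sample.int(k, n_segments, replace = TRUE, prob = w / sum(w))
  tau <- pmax(3, round(stats::rexp(n_segments, 1 / centers$dwell_mean[state])))
  D <- 10^(log10(centers$D[state]) + stats::rnorm(n_segments, 0, sd_log10D))
  al <- pmin(2, pmax(0.05, centers$alpha[state] +
                       stats::rnorm(n_segments, 0, sd_alpha)))
  data.frame(traj_id = seq_len(n_segments), start = 0L, end = as.integer(tau),
             tau = as.numeric(tau), mean_D = D, mean_alpha = al, state = state)
}
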