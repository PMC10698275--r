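## Shared fixture builders: single-changepoint benchmarks used by the
## segmentation and metric tests. All fixtures are generated in code under
## the seed set by each test.

## 200-step Brownian trajectories with one D changepoint at a uniform
## position and two independent log-uniform D values
make_bm_cp_benchmark <- function(n_traj, n = 200L, cp_range = c(10L, 190L),
                                 logD_range = c(-3, 3)) {
  lapply(seq_len(n_traj), function(i) {
    cp <- sample(cp_range[1]:cp_range[2], 1L)
    D <- 10^stats::runif(2, logD_range[1], logD_range[2])
    list(traj = simulate_piecewise_bm(rep(D, c(cp, n - cp))),
         cp = cp, D = D)
  })
}

## 200-step fBm trajectories with one alpha changepoint (unit-scale segments)
make_fbm_cp_benchmark <- function(n_traj, n = 200L, cp_range = c(10L, 190L),
                                  alpha_range = c(0.05, 1.95)) {
  lapply(seq_len(n_traj), function(i) {
    cp <- sample(cp_range[1]:cp_range[2], 1L)
    al <- stats::runif(2, alpha_range[1], alpha_range[2])
    out <- compose_trajectory(
      data.frame(model = "fBm", alpha = al, D = 1, dwell = c(cp, n - cp)),
      n, normalize_segments = TRUE)
    list(traj = out$traj, cp = cp, alpha = al)
  })
}

## exact moments of tau = max(1, round(D^-gamma)) with D ~ sigma D^(sigma-1)
## on (a, b): tau is piecewise constant in D, so sum the closed-form CDF over
## the rounding cells — an analytic oracle for renewal-count predictions
attm_tau_moments <- function(sigma, gamma, D_bounds) {
  a <- D_bounds[1]; b <- D_bounds[2]
  cdf <- function(q) (pmin(pmax(q, a), b)^sigma - a^sigma) /
    (b^sigma - a^sigma)
  kmax <- ceiling(a^-gamma)
  k <- seq_len(kmax)
  hi <- (k - 0.5)^(-1 / gamma)            # D giving round(D^-gamma) = k
  lo <- (k + 0.5)^(-1 / gamma)
  hi[1] <- b                              # tau = 1 also covers D^-gamma < 1.5
  p <- pmax(0, cdf(hi) - cdf(lo))
  p <- p / sum(p)
  c(m1 = sum(k * p), m2 = sum(k^2 * p))
}
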