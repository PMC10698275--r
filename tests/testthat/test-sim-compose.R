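test_that("a single segment yields no changepoints and constant labels", {
  set.seed(51)
  out <- compose_trajectory(data.frame(model = "fBm", alpha = 0.7, D = 1,
                                       dwell = 80))
  expect_length(out$gt$changepoints, 0)
  expect_equal(length(unique(out$gt$alpha)), 1L)
  expect_equal(n_steps(out$traj), 80L)
})

test_that("segment boundaries are position-continuous changepoints", {
  set.seed(52)
  out <- compose_trajectory(data.frame(model = c("BM", "BM"), alpha = 1,
                                       D = c(1, 1), dwell = c(100, 100)), 200)
  expect_identical(out$gt$changepoints, 100L)
  steps <- sqrt(rowSums(diff(out$traj$positions)^2))
  ## the boundary displacement is an ordinary draw, not a positional jump
  expect_lt(steps[100], max(steps) * 1.0001)
  expect_true(all(is.finite(out$traj$positions)))
})

test_that("per-step labels round-trip through the changepoint list", {
  set.seed(53)
  specs <- data.frame(model = c("fBm", "SBM", "fBm"), alpha = c(0.4, 1.2, 0.8),
                      D = 1, dwell = c(40, 60, 50))
  out <- compose_trajectory(specs, 150)
  rebuilt <- rep(specs$alpha,
                 diff(c(0, out$gt$changepoints, 150)))
  expect_equal(out$gt$alpha, rebuilt)
})

test_that("CTRW and LW segments recover their MSD exponents", {
  set.seed(54)
  trs <- replicate(4000, simulate_ctrw(500, 0.5), simplify = FALSE)
  sl <- msd_exponent(ensemble_msd(trs), c(100, 450))
  expect_lt(abs(sl - 0.5), 0.05)
  trs <- replicate(4000, simulate_lw(400, 1.5), simplify = FALSE)
  sl <- msd_exponent(ensemble_msd(trs), c(50, 300))
  expect_lt(abs(sl - 1.5), 0.05)
})

test_that("inadmissible model/alpha pairs are rejected by name", {
  expect_error(simulate_anomalous_segment("LW", 100, 0.5), "superdiffusive")
  expect_error(simulate_anomalous_segment("CTRW", 100, 1.5), "subdiffusive")
  expect_error(simulate_anomalous_segment("ATTM", 100, 1.2), "subdiffusive")
  expect_error(simulate_anomalous_segment("BM", 100, 0.5), "alpha = 1")
  expect_error(simulate_anomalous_segment("nope", 100, 1), "unknown")
})

test_that("datasets are reproducible and respect the configured ranges", {
  cfg <- piecewise_config(n_steps = 120L, target = "alpha")
  d1 <- generate_dataset(cfg, 5, seed = 99)
  d2 <- generate_dataset(cfg, 5, seed = 99)
  expect_identical(d1[[3]]$traj$positions, d2[[3]]$traj$positions)
  al <- unlist(lapply(d1, function(d) d$gt$alpha))
  expect_true(all(al >= 0.05 & al <= 2))
  cfgD <- piecewise_config(n_steps = 120L, target = "D")
  dD <- generate_dataset(cfgD, 10, seed = 100)
  D <- unlist(lapply(dD, function(d) d$gt$D))
  expect_true(all(D >= 1e-3 & D <= 1e3))
  expect_true(all(unlist(lapply(dD, function(d) d$gt$model)) == "BM"))
})

test_that("dataset dwell times follow the truncated-exponential windowing law", {
  cfg <- piecewise_config(n_steps = 200L, target = "D")
  ds <- generate_dataset(cfg, 300, seed = 56)
  ## complete (uncensored) segments: every one before the final truncation
  dw <- unlist(lapply(ds, function(d) diff(c(0, d$gt$changepoints))))
  expect_true(all(dw >= 10 & dw <= 190))
  ## oracle: the same windowing applied directly to the dwell sampler
  ## (complete segments in a finite window are length-biased short, so the
  ## comparison is like-with-like, not against the unconditional mean 57)
  set.seed(57)
  dw_ref <- unlist(replicate(600, {
    tot <- 0; d <- integer(0)
    while (tot < 200) { x <- sample_dwell_times(1); d <- c(d, x); tot <- tot + x }
    d[-length(d)]
  }, simplify = FALSE))
  se <- sqrt(var(dw) / length(dw) + var(dw_ref) / length(dw_ref))
  expect_lt(abs(mean(dw) - mean(dw_ref)), 4 * se)
})
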