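brute_tamsd <- function(p, max_lag) {
  vapply(seq_len(max_lag), function(k) {
    tot <- 0; n <- nrow(p)
    for (t in seq_len(n - k)) tot <- tot + sum((p[t + k, ] - p[t, ])^2)
    tot / (n - k)
  }, numeric(1))
}

test_that("tamsd equals the brute-force double loop", {
  set.seed(71)
  for (i in 1:5) {
    tr <- trajectory(matrix(rnorm(40), 20, 2))
    expect_equal(tamsd(tr, 19)$msd, brute_tamsd(tr$positions, 19),
                 tolerance = 1e-12)
  }
})

test_that("tamsd hand examples", {
  line <- trajectory(cbind(0:9, 0))
  expect_equal(tamsd(line, 5)$msd, (1:5)^2)
  const <- trajectory(matrix(1, 10, 2))
  expect_equal(tamsd(const, 4)$msd, rep(0, 4))
  toy <- trajectory(cbind(c(0, 1, 0, 1, 0), 0))
  expect_equal(tamsd(toy, 2)$msd, c(1, 0))
  expect_error(tamsd(line, 10), "max_lag")
})

test_that("fit_D is exact on a noiseless synthetic curve and unbiased on BM", {
  f <- pointdiff:::fit_D_from_msd(4 * 2.5 * (1:4), 1:4, 1, FALSE)
  expect_equal(unname(f["D"]), 2.5)
  set.seed(72)
  est <- replicate(3000, fit_D(simulate_piecewise_bm(rep(1, 200))))
  expect_lt(abs(mean(est) - 1), 0.02)
})

test_that("the offset fit absorbs the localization-noise plateau", {
  set.seed(73)
  ic <- replicate(4000, attr(fit_D(
    add_localization_noise(simulate_piecewise_bm(rep(1, 200)), 0.1),
    fit_lags = 2:10, allow_offset = TRUE), "intercept"))
  expect_lt(abs(mean(ic) - 0.04), 3 * sd(ic) / sqrt(length(ic)))
  expect_error(fit_D(simulate_piecewise_bm(rep(1, 50)), fit_lags = 1,
                     allow_offset = TRUE), "2 lags")
})

test_that("fit_alpha: ballistic, Brownian and fractional cases", {
  expect_equal(fit_alpha(trajectory(cbind(0:99, 0))), 2, tolerance = 1e-10)
  set.seed(74)
  est <- replicate(2000, fit_alpha(simulate_piecewise_bm(rep(1, 200))))
  expect_lt(abs(mean(est) - 1), 0.02)
  est <- replicate(2000, fit_alpha(simulate_fbm(200, 0.5)))
  expect_lt(abs(mean(est) - 0.5), 0.03)
  expect_error(fit_alpha(trajectory(matrix(0, 50, 2))), "zero TA-MSD")
})

test_that("sliding profiles preserve length and match the global fit", {
  set.seed(75)
  tr <- simulate_piecewise_bm(rep(2, 101))
  sp <- sliding_profile(tr, window = 101, target = "D")
  expect_length(sp$values, 101)
  expect_equal(10^sp$values[51], unclass(fit_D(tr)), tolerance = 1e-10,
               ignore_attr = TRUE)
  spa <- sliding_profile(tr, window = 101, target = "alpha", fit_lags = 1:5)
  expect_equal(spa$values[51], fit_alpha(tr, 1:5), tolerance = 1e-10)
  expect_error(sliding_profile(tr, window = 4, target = "D"), "unstable")
  expect_error(sliding_profile(tr, window = 300, target = "D"), "exceeds")
})

test_that("sliding estimates far from a changepoint match the segment fit", {
  set.seed(76)
  est <- ref <- numeric(80)
  for (i in 1:80) {
    tr <- simulate_piecewise_bm(rep(c(1, 100), each = 100))
    sp <- profile_D_linear(sliding_profile(tr, window = 40, target = "D"))
    ref[i] <- unclass(fit_D(trajectory(tr$positions[1:100, ])))
    est[i] <- mean(sp[40:60])
  }
  expect_lt(abs(mean(est) / mean(ref) - 1), 0.05)
})

test_that("ensemble MSD slope matches theory for Brownian motion", {
  set.seed(77)
  trs <- replicate(2000, simulate_piecewise_bm(rep(1, 100)), simplify = FALSE)
  em <- ensemble_msd(trs)
  expect_lt(abs(msd_exponent(em, c(1, 80)) - 1), 0.02)
  expect_lt(abs(em$msd[10] - 40), 3)
})
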