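test_that("power-law tail MLE recovers the exponent and is scale invariant", {
  set.seed(111)
  x <- sample_powerlaw_D(1e5, 0.3, c(1e-5, 1))
  est <- fit_powerlaw_tail(x, c(1e-5, 1))
  expect_lt(abs(est - 0.3), 0.01)
  est10 <- fit_powerlaw_tail(10 * x, 10 * c(1e-5, 1))
  expect_equal(est10, est, tolerance = 1e-4)
  expect_error(fit_powerlaw_tail(rep(0.5, 100), c(0.1, 1)), "degenerate")
  expect_error(fit_powerlaw_tail(x[1:10], c(1e-5, 1)), "fewer than 50")
})

test_that("dwell-coupling exponent: exact, null and error cases", {
  set.seed(112)
  D <- sample_powerlaw_D(500, 0.3, c(1e-4, 1))
  st <- data.frame(tau = D^-0.4, mean_D = D)
  expect_equal(dwell_vs_D(st), 0.4, tolerance = 1e-6)
  st0 <- data.frame(tau = rep(7, 100), mean_D = D[1:100])
  expect_lt(abs(dwell_vs_D(st0)), 1e-6)
  expect_error(dwell_vs_D(st[1:10, ]), "20 segments")
  expect_error(dwell_vs_D(data.frame(tau = c(rep(1, 30), -1),
                                     mean_D = rep(1, 31))), "positive")
})

test_that("ATTM ground-truth segments recover sigma and gamma", {
  set.seed(113)
  tabs <- lapply(1:2000, function(i) {
    st <- segment_table_from_gt(simulate_attm(200)$gt, traj_id = i)
    if (nrow(st) > 1) st[-nrow(st), ] else NULL    # drop censored tail segment
  })
  st <- do.call(rbind, tabs)
  sig <- fit_powerlaw_tail(st$mean_D, c(10^-6.7, 1))
  expect_gt(sig, 0.25); expect_lt(sig, 0.35)
  gam <- dwell_vs_D(st)
  expect_gt(gam, 0.35); expect_lt(gam, 0.45)
})

test_that("state clustering finds well-separated blobs exactly", {
  set.seed(114)
  n <- 120
  st <- data.frame(
    mean_D = 10^c(rnorm(n, -4, 0.15), rnorm(n, -1, 0.15)),
    mean_alpha = c(rnorm(n, 0.3, 0.05), rnorm(n, 1.2, 0.05)),
    tau = rep(10, 2 * n))
  set.seed(200)
  cl <- cluster_segments(st, k_candidates = 1:6)
  expect_equal(cl$k, 2L)
  lab <- cl$labels
  expect_true(all(lab[1:n] == lab[1]) && all(lab[-(1:n)] == lab[n + 1]))
  expect_equal(sum(cl$occupancy), 1)
  ## identical seed -> identical labels
  set.seed(200)
  cl2 <- cluster_segments(st, k_candidates = 1:6)
  expect_identical(cl2$labels, lab)
  ## occupancy is invariant to row order
  set.seed(115)
  perm <- sample(nrow(st))
  cl3 <- cluster_segments(st[perm, ], k_candidates = 1:6)
  expect_equal(sort(cl3$occupancy), sort(cl$occupancy), tolerance = 1e-12)
})

test_that("the four-state mixture is recovered with its occupancies", {
  st <- simulate_multistate_segments(2500, seed = 116)
  cl <- cluster_segments(st)
  expect_equal(cl$k, 4L)
  occ_true <- as.numeric(tapply(st$tau, st$state, sum) / sum(st$tau))
  ## match clusters to generating states via alpha ordering
  ord_est <- order(cl$centers[, "alpha"])
  ord_true <- order(c(0.23, 0.46, 0.88, 1.30))
  expect_true(all(abs(cl$occupancy[ord_est] - occ_true[ord_true]) < 0.05))
})

test_that("turning angles: persistence, reversal, uniformity, mirror", {
  line <- trajectory(cbind(0:20, 0))
  expect_true(all(turning_angles(line) < 1e-8))
  zig <- trajectory(cbind(rep(c(0, 1), 10), 0))
  expect_true(all(abs(turning_angles(zig) - 180) < 1e-8))
  set.seed(117)
  tr <- simulate_piecewise_bm(rep(1, 1e5))
  ang <- turning_angles(tr)
  h <- table(cut(ang, seq(0, 180, by = 18)))
  expect_gt(chisq.test(h)$p.value, 0.01)
  mir <- trajectory(tr$positions %*% diag(c(-1, 1)))
  expect_equal(turning_angles(mir), ang, tolerance = 1e-10)
  expect_error(turning_angles(trajectory(matrix(0, 2, 2))), "3 frames")
})

test_that("confinement radius: degenerate, circle and reflected BM cases", {
  expect_equal(confinement_radius(matrix(1, 5, 2)), 0)
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  circ <- cbind(3 + 2 * cos(th), -1 + 2 * sin(th))
  expect_equal(confinement_radius(circ), 2, tolerance = 1e-10)
  expect_error(confinement_radius(matrix(0, 2, 2)), "3 frames")
  ## reflected BM in a disc of radius R equilibrates to uniform: Rg -> R/sqrt(2)
  set.seed(118)
  reflect_bm <- function(n, R, s = 0.1 * R) {
    p <- matrix(0, n, 2)
    for (i in 2:n) {
      q <- p[i - 1, ] + rnorm(2, 0, s)
      r <- sqrt(sum(q^2))
      if (r > R) q <- q * (2 * R - r) / r
      p[i, ] <- q
    }
    p
  }
  for (R in c(1, 2)) {
    rg <- confinement_radius(reflect_bm(2e4, R))
    expect_lt(abs(rg - R / sqrt(2)) / (R / sqrt(2)), 0.1)
  }
})
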