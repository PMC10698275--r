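test_that("KCPD basics: constant, single step, exact label series", {
  expect_length(detect_changepoints(rep(1.5, 100)), 0)
  set.seed(81)
  s <- c(rep(0, 100), rep(10, 100)) + rnorm(200, 0, 0.5)
  cp <- detect_changepoints(s, penalty = 4)
  expect_length(cp, 1)
  expect_lte(abs(cp - 100), 1)
  expect_equal(detect_changepoints(c(rep(1, 57), rep(5, 143)), penalty = 4),
               57L, ignore_attr = TRUE)
  expect_error(detect_changepoints(c(1, NA, 3, 4, 5, 6, 7)), "non-finite")
  expect_error(detect_changepoints(c(1, 2, 3)), "min_size")
})

test_that("increasing the penalty never adds changepoints", {
  set.seed(82)
  for (i in 1:5) {
    x <- rnorm(150) + rep(c(0, 2.5, 0), c(50, 50, 50))
    ncp <- vapply(c(0.5, 1, 2, 4, 8, 16, 32, 64),
                  function(p) length(detect_changepoints(x, penalty = p)),
                  integer(1))
    expect_true(all(diff(ncp) <= 0))
  }
})

test_that("detected segments respect the minimum size", {
  set.seed(83)
  x <- rnorm(60)                           # pure noise, low penalty
  cp <- detect_changepoints(x, penalty = 0.05, min_size = 5L)
  expect_true(all(diff(c(0L, cp, 60L)) >= 5))
})

test_that("order-of-magnitude D steps are located within 5 frames", {
  set.seed(84)
  hit <- 0; n_rep <- 60
  for (i in seq_len(n_rep)) {
    tr <- simulate_piecewise_bm(rep(c(1, 100), each = 100))
    cp <- detect_changepoints(displacement_series(tr))
    hit <- hit + any(abs(cp - 100) <= 5)
  }
  expect_gt(hit / n_rep, 0.95)
})

test_that("displacement series: shape, constants, round trip", {
  tr <- trajectory(cbind(0:9, 0))
  ds <- displacement_series(tr)
  expect_equal(dim(ds), c(10L, 2L))
  expect_equal(ds[1, ], c(0, 0))
  expect_true(all(ds[-1, 1] == 1) && all(ds[-1, 2] == 0))
  set.seed(85)
  tr <- simulate_piecewise_bm(rep(1, 30))
  ds <- displacement_series(tr)
  expect_equal(apply(ds, 2, cumsum) + tr$positions[1, ][col(ds)],
               unname(tr$positions), tolerance = 1e-12)
})

test_that("segment tables summarize profiles over detected segments", {
  ## hand example: one stepped channel drives the changepoint
  prof_a <- pointwise_profile(c(1, 1, 1, 5, 5), "alpha")
  tr <- trajectory(matrix(0, 5, 2), id = 7L)
  st <- segment_trajectory(tr, prof_a, penalty = 0.5, min_size = 2L)
  expect_equal(attr(st, "changepoints"), 3L)
  expect_equal(st$mean_alpha, c(1, 5))
  expect_equal(st$tau, c(3, 2))            # [0,3) and [3,5)
  expect_equal(st$traj_id, c(7L, 7L))
  ## D profiles average on the log10 scale
  prof_d <- pointwise_profile(c(-2, -2, -2, 2, 2), "D")
  st2 <- segment_trajectory(tr, prof_d, penalty = 0.5, min_size = 2L)
  expect_equal(st2$mean_D, c(1e-2, 1e2))
  expect_true(all(is.na(st2$mean_alpha)))
  ## joint segmentation: constant channel plus stepped channel
  st3 <- segment_trajectory(tr, list(pointwise_profile(rep(0, 5), "D"),
                                     prof_a), penalty = 0.5, min_size = 2L)
  expect_equal(attr(st3, "changepoints"), 3L)
  expect_error(segment_trajectory(tr, pointwise_profile(1:4, "alpha")),
               "length")
})

test_that("single-segment tables equal whole-profile means and rebuild cps", {
  set.seed(86)
  v <- rnorm(50)
  tr <- trajectory(matrix(rnorm(100), 50, 2))
  st <- segment_trajectory(tr, pointwise_profile(v, "alpha"), penalty = 1e3)
  expect_equal(nrow(st), 1L)
  expect_equal(st$mean_alpha, mean(v))
  ## reconstruction: piecewise-constant profile built from a segment table
  ## has exactly the table's changepoints
  gt <- gt_profile(rep(c(2, 0.5, 4), c(20, 15, 15)), rep(1, 50),
                   rep("BM", 50), c(20L, 35L))
  st2 <- segment_table_from_gt(gt)
  prof <- rep(log10(st2$mean_D), st2$end - st2$start)
  expect_identical(which(diff(prof) != 0), as.integer(attr(st2, "changepoints")))
})
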