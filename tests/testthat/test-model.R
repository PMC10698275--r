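small_cfg <- function(target = "D")
  model_config(target, embed_dim = 8L, conv_blocks = 1L, encoder_layers = 1L,
               heads = 2L, ffn_dim = 16L, head_dim = 8L)

test_that("features are per-step displacements with the right invariances", {
  set.seed(101)
  for (n in c(20, 200, 1000)) {
    tr <- simulate_piecewise_bm(rep(1, n))
    expect_equal(nrow(featurize(tr, "D")), n)
  }
  tr <- simulate_piecewise_bm(rep(1, 50))
  shifted <- trajectory(tr$positions + 5)
  expect_equal(featurize(tr, "D"), featurize(shifted, "D"))
  scaled <- trajectory(tr$positions * 10)
  expect_equal(featurize(tr, "alpha"), featurize(scaled, "alpha"),
               tolerance = 1e-12)
  ## D features keep the raw scale
  expect_equal(featurize(scaled, "D"), 10 * featurize(tr, "D"))
  expect_error(featurize(trajectory(matrix(0, 2, 2))), NA)
})

test_that("forward pass preserves length, is deterministic and bounded", {
  set.seed(102)
  model <- init_model(small_cfg(), seed = 1)
  for (n in c(10, 50, 200, 999)) {
    tr <- simulate_piecewise_bm(rep(1, n))
    y <- pointwise_forward(featurize(tr, "D"), model)
    expect_equal(nrow(y), n)
    y2 <- pointwise_forward(featurize(tr, "D"), model)
    expect_identical(y, y2)
    expect_true(all(is.finite(y)))
    expect_true(all(y >= -3 & y <= 3))
  }
})

test_that("analytic gradients match finite differences", {
  set.seed(103)
  cfg <- small_cfg()
  model <- init_model(cfg, seed = 2)
  T <- 6L; B <- 2L
  M0 <- matrix(rnorm(T * B * 2), T * B, 2)
  lab <- matrix(runif(T * B, -2, 2), T, B)
  fw <- pointdiff:::net_fwd(model$params, M0, T, B, cfg)
  dy <- sign(fw$y - lab) / length(lab)
  g <- pointdiff:::net_bwd(model$params, fw$cache, dy, T, B, cfg)
  loss_of <- function(p) mean(abs(pointdiff:::net_fwd(p, M0, T, B, cfg)$y - lab))
  probe <- list(c("stem", "W", "1"), c("res", "1", "c1", "W", "2"),
                c("enc", "1", "Wq"), c("enc", "1", "Wo"),
                c("enc", "1", "ln1_g"), c("enc", "1", "W2"),
                c("head", "W1"))
  for (path in probe) {
    p <- model$params; gg <- g
    for (k in path) {
      k2 <- if (grepl("^[0-9]+$", k)) as.integer(k) else k
      p <- p[[k2]]; gg <- gg[[k2]]
    }
    for (i in sample(length(p), 2)) {
      eps <- 1e-6
      set_leaf <- function(params, path, i, v) {
        k <- path[1]
        k2 <- if (grepl("^[0-9]+$", k)) as.integer(k) else k
        if (length(path) == 1) params[[k2]][i] <- v
        else params[[k2]] <- set_leaf(params[[k2]], path[-1], i, v)
        params
      }
      num <- (loss_of(set_leaf(model$params, path, i, p[i] + eps)) -
              loss_of(set_leaf(model$params, path, i, p[i] - eps))) / (2 * eps)
      expect_lt(abs(num - gg[i]) / max(1e-8, abs(num) + abs(gg[i])), 1e-4)
    }
  }
})

test_that("sequence reversal does not shift predictions systematically", {
  set.seed(104)
  model <- init_model(small_cfg(), seed = 3)
  d <- replicate(100, {
    tr <- simulate_piecewise_bm(rep(1, 60))
    f <- featurize(tr, "D")
    mean(pointwise_forward(f, model)) -
      mean(pointwise_forward(f[60:1, ], model))
  })
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)) + 0.02)
})

test_that("long trajectories are handled by overlapping windows", {
  set.seed(105)
  cfg <- model_config("D", embed_dim = 8L, conv_blocks = 1L,
                      encoder_layers = 1L, heads = 2L, ffn_dim = 16L,
                      head_dim = 8L, max_length = 64L)
  model <- init_model(cfg, seed = 4)
  tr <- simulate_piecewise_bm(rep(1, 150))
  pr <- predict_pointwise(tr, model)
  expect_length(pr$values, 150)
  expect_true(all(pr$values >= -3 & pr$values <= 3))
  expect_error(pointwise_forward(featurize(tr, "D"), model), "max_length")
})

test_that("model files round-trip with their configuration", {
  model <- init_model(small_cfg("alpha"), seed = 5)
  f <- tempfile(fileext = ".rds")
  save_model(model, f)
  m2 <- load_model(f)
  expect_identical(m2$config$target, "alpha")
  expect_equal(m2$params, model$params)
  bad <- tempfile(fileext = ".rds"); saveRDS(1:3, bad)
  expect_error(load_model(bad), "not a pointwise model")
  unlink(c(f, bad))
})
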