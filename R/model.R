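## User-facing model surface: configuration, featurization, forward pass and
## pointwise prediction.

#' Pointwise model configuration
#'
#' Architecture and output contract of the sequence-to-sequence regressor.
#' One model predicts a single target: the log10 diffusion coefficient
#' (output range \eqn{[-3, 3]}, matching training labels
#' \eqn{D \in [10^{-3}, 10^3]}) or the anomalous exponent (range
#' \eqn{[0.05, 2]}). The defaults are a compact CPU-trainable architecture;
#' all convolutions are stride-1 with symmetric padding and attention is
#' full-sequence, so the output length always equals the input length.
#'
#' @param target `"D"` or `"alpha"`.
#' @param embed_dim embedding width of the encoder.
#' @param conv_blocks number of residual convolutional blocks after the stem.
#' @param kernel_size odd convolution kernel width.
#' @param encoder_layers number of transformer encoder layers.
#' @param heads attention heads (must divide `embed_dim`).
#' @param ffn_dim hidden width of the encoder feed-forward sublayer.
#' @param head_dim hidden width of the pointwise output head.
#' @param output_range the target interval onto which the output sigmoid is
#'   scaled; defaults depend on `target`.
#' @param max_length longest sequence processed in one pass; longer inputs
#'   are handled in overlapping windows.
#' @return an object of class `model_config`.
#' @export
model_config <- function(target = c("D", "alpha"), embed_dim = 32L,
                         conv_blocks = 2L, kernel_size = 3L,
                         encoder_layers = 1L, heads = 2L, ffn_dim = 64L,
                         head_dim = 32L, output_range = NULL,
                         max_length = 1000L) {
  target <- match.arg(target)
  if (is.null(output_range))
    output_range <- if (target == "D") c(-3, 3) else c(0.05, 2)
  stopifnot(embed_dim %% heads == 0L, kernel_size %% 2L == 1L,
            conv_blocks >= 1L, encoder_layers >= 1L,
            output_range[1] < output_range[2])
  structure(list(target = target, n_features = 2L,
                 embed_dim = as.integer(embed_dim),
                 conv_blocks = as.integer(conv_blocks),
                 kernel_size = as.integer(kernel_size),
                 encoder_layers = as.integer(encoder_layers),
                 heads = as.integer(heads), ffn_dim = as.integer(ffn_dim),
                 head_dim = as.integer(head_dim),
                 output_range = output_range,
                 max_length = as.integer(max_length)),
            class = "model_config")
}

#' Initialize a pointwise model
#'
#' @param config a [model_config()].
#' @param seed optional integer seed for the weight initialization.
#' @return an object of class `pointwise_model` (config + parameters).
#' @export
init_model <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  structure(list(config = config, params = init_params(config),
                 version = as.character(utils::packageVersion("pointdiff"))),
            class = "pointwise_model")
}

#' @export
print.pointwise_model <- function(x, ...) {
  cfg <- x$config
  np <- sum(rapply(x$params, length, how = "unlist"))
  cat(sprintf(paste0("pointwise %s model: %d conv blocks (d=%d, k=%d), ",
                     "%d encoder layer(s) x %d heads, %d parameters\n"),
              cfg$target, cfg$conv_blocks, cfg$embed_dim, cfg$kernel_size,
              cfg$encoder_layers, cfg$heads, np))
  invisible(x)
}

#' Per-step displacement features
#'
#' One feature vector per frame: the displacement components into that frame
#' (zero-padded at frame 0), which makes the representation translation
#' invariant. For `target = "alpha"` the whole sequence is additionally
#' divided by the global displacement standard deviation, making it scale
#' free; for `target = "D"` the raw displacement scale carries the signal
#' and is preserved.
#'
#' @param traj a `traj` with at least 2 frames.
#' @param target `"D"` or `"alpha"`.
#' @return n x 2 feature matrix.
#' @export
featurize <- function(traj, target = c("D", "alpha")) {
  target <- match.arg(target)
  if (n_steps(traj) < 2L) stop("need at least 2 frames")
  F <- displacement_series(traj)
  if (target == "alpha") {
    s <- stats::sd(F[-1L, ])
    if (s > 0) F <- F / s
  }
  F
}

#' Raw forward pass over a feature batch
#'
#' Evaluates the network on a batch of equal-length feature sequences.
#' Deterministic given the parameters; output length equals input length.
#'
#' @param features a single n x 2 feature matrix or a list of them (equal n).
#' @param model a `pointwise_model`.
#' @return matrix of per-step outputs, n x batch.
#' @export
pointwise_forward <- function(features, model) {
  if (is.matrix(features)) features <- list(features)
  T <- nrow(features[[1L]])
  if (T > model$config$max_length)
    stop("sequence longer than max_length; use predict_pointwise")
  B <- length(features)
  M0 <- do.call(rbind, features)
  net_fwd(model$params, M0, T, B, model$config)$y
}

#' Pointwise prediction for a trajectory
#'
#' Featurizes the trajectory and runs the model; trajectories longer than
#' the supported window are processed in half-overlapping windows whose
#' predictions are averaged on the overlaps. D models return the log10
#' profile (see [profile_D_linear()] for the linear scale).
#'
#' @param traj a `traj`.
#' @param model a trained or initialized `pointwise_model`.
#' @return a [pointwise_profile()] of length `n_steps(traj)`.
#' @export
predict_pointwise <- function(traj, model) {
  cfg <- model$config
  Fm <- featurize(traj, cfg$target)
  n <- nrow(Fm)
  if (n <= cfg$max_length) {
    vals <- as.numeric(pointwise_forward(Fm, model))
  } else {
    w <- cfg$max_length; stride <- w %/% 2L
    acc <- numeric(n); cnt <- numeric(n)
    start <- 1L
    repeat {
      end <- min(start + w - 1L, n)
      s0 <- end - w + 1L                    # full window, right-aligned
      y <- as.numeric(pointwise_forward(Fm[s0:end, , drop = FALSE], model))
      acc[s0:end] <- acc[s0:end] + y
      cnt[s0:end] <- cnt[s0:end] + 1
      if (end == n) break
      start <- start + stride
    }
    vals <- acc / cnt
  }
  pointwise_profile(pmin(pmax(vals, cfg$output_range[1]),
                         cfg$output_range[2]), cfg$target)
}

#' Save / load a pointwise model
#'
#' The file embeds the model configuration, the package version and the
#' parameters.
#'
#' @param model a `pointwise_model`.
#' @param path file path.
#' @return `load_model` returns the `pointwise_model`.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "pointwise_model")) stop("not a pointwise model file")
  m
}
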