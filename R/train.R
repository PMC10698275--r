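## Training: L1 losses on the model's output scale and an Adam / one-cycle
## training loop over on-the-fly simulated data.

#' Pointwise training loss
#'
#' For `target = "D"` the mean absolute error between log10 diffusion
#' coefficients (a relative-error-like loss, invariant to joint rescaling);
#' for `target = "alpha"` the mean absolute error of the exponent.
#'
#' @param pred,true per-step values; for `"D"` on the linear scale.
#' @param target `"D"` or `"alpha"`.
#' @return scalar loss.
#' @export
pointwise_loss <- function(pred, true, target = c("D", "alpha")) {
  target <- match.arg(target)
  if (length(pred) != length(true)) stop("length mismatch")
  if (target == "D") mean(abs(log10(pred) - log10(true)))
  else mean(abs(pred - true))
}

#' Training configuration
#'
#' @param data a [piecewise_config()] describing the simulated training
#'   distribution; its `target` must match the model's.
#' @param epochs number of epochs; a fresh dataset is simulated every epoch
#'   from an epoch-indexed seed stream (unlimited-data regime).
#' @param traj_per_epoch trajectories simulated per epoch.
#' @param batch_size trajectories per gradient step.
#' @param lr_max peak learning rate of the one-cycle schedule.
#' @param val_traj size of the frozen validation set.
#' @param seed base seed (drives weights, data stream and batching).
#' @return an object of class `train_config`.
#' @export
train_config <- function(data, epochs = 5L, traj_per_epoch = 200L,
                         batch_size = 25L, lr_max = 2e-3, val_traj = 100L,
                         seed = 1L) {
  stopifnot(inherits(data, "piecewise_config"), epochs >= 1L,
            traj_per_epoch >= batch_size, val_traj >= 1L)
  structure(list(data = data, epochs = as.integer(epochs),
                 traj_per_epoch = as.integer(traj_per_epoch),
                 batch_size = as.integer(batch_size), lr_max = lr_max,
                 val_traj = as.integer(val_traj), seed = as.integer(seed)),
            class = "train_config")
}

## dataset -> list(features = list of n x 2, labels = list of n-vectors)
dataset_tensors <- function(dataset, target) {
  list(features = lapply(dataset, function(d) featurize(d$traj, target)),
       labels = lapply(dataset, function(d)
         if (target == "D") log10(d$gt$D) else d$gt$alpha))
}

## mean L1 validation loss of `params` on prepared tensors
eval_loss <- function(params, tensors, cfg, batch_size = 50L) {
  n <- length(tensors$features)
  T <- nrow(tensors$features[[1L]])
  tot <- 0
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, n)
    M0 <- do.call(rbind, tensors$features[idx])
    y <- net_fwd(params, M0, T, length(idx), cfg)$y
    lab <- matrix(unlist(tensors$labels[idx]), T, length(idx))
    tot <- tot + sum(abs(y - lab))
  }
  tot / (n * T)
}

#' Train a pointwise model
#'
#' Adam with a one-cycle learning-rate schedule (30% linear warmup, cosine
#' decay), L1 loss on the model's output scale, fresh simulated data every
#' epoch, and a frozen validation set. Returns the best-validation
#' checkpoint. Fully reproducible for a fixed seed.
#'
#' @param model_cfg a [model_config()].
#' @param tc a [train_config()] with a matching target.
#' @param verbose print per-epoch losses.
#' @return list: `model` (best checkpoint), `history` (per-epoch data frame).
#' @export
train_model <- function(model_cfg, tc, verbose = FALSE) {
  if (model_cfg$target != tc$data$target)
    stop("model and training-data targets differ")
  model <- init_model(model_cfg, seed = tc$seed)
  cfg <- model$config
  val <- dataset_tensors(
    generate_dataset(tc$data, tc$val_traj, seed = tc$seed + 10000L),
    cfg$target)
  m <- adam_init(model$params); v <- adam_init(model$params)
  steps_per_epoch <- tc$traj_per_epoch %/% tc$batch_size
  total_steps <- tc$epochs * steps_per_epoch
  lr_at <- function(t) {
    warm <- max(1, round(0.3 * total_steps))
    if (t <= warm) tc$lr_max * t / warm
    else {
      frac <- (t - warm) / max(1, total_steps - warm)
      tc$lr_max * (0.01 + 0.99 * 0.5 * (1 + cos(pi * frac)))
    }
  }
  best <- list(loss = Inf, params = model$params)
  hist <- data.frame(epoch = integer(0), train = numeric(0), val = numeric(0))
  step <- 0L
  T <- tc$data$n_steps
  for (ep in seq_len(tc$epochs)) {
    tens <- dataset_tensors(
      generate_dataset(tc$data, tc$traj_per_epoch, seed = tc$seed + ep),
      cfg$target)
    set.seed(tc$seed * 1000L + ep)
    ord <- sample.int(tc$traj_per_epoch)
    ep_loss <- 0
    for (bi in seq_len(steps_per_epoch)) {
      idx <- ord[((bi - 1L) * tc$batch_size + 1L):(bi * tc$batch_size)]
      B <- length(idx)
      M0 <- do.call(rbind, tens$features[idx])
      lab <- matrix(unlist(tens$labels[idx]), T, B)
      fw <- net_fwd(model$params, M0, T, B, cfg)
      resid <- fw$y - lab
      loss <- mean(abs(resid))
      if (!is.finite(loss))
        stop(sprintf("training diverged (non-finite loss at epoch %d, step %d)",
                     ep, bi))
      ep_loss <- ep_loss + loss
      dy <- sign(resid) / length(resid)
      g <- net_bwd(model$params, fw$cache, dy, T, B, cfg)
      step <- step + 1L
      up <- adam_step(model$params, g, m, v, lr_at(step), step)
      model$params <- up$params; m <- up$m; v <- up$v
    }
    vl <- eval_loss(model$params, val, cfg)
    if (vl < best$loss) best <- list(loss = vl, params = model$params)
    hist <- rbind(hist, data.frame(epoch = ep,
                                   train = ep_loss / steps_per_epoch,
                                   val = vl))
    if (verbose)
      message(sprintf("epoch %d: train %.4f  val %.4f", ep,
                      ep_loss / steps_per_epoch, vl))
  }
  model$params <- best$params
  list(model = model, history = hist, best_val = best$loss)
}
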