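## Benchmark metrics: relative / absolute pointwise errors and the Jaccard
## index for changepoint sets, plus stratified benchmark reports.

#' Mean relative error of diffusion-coefficient predictions
#'
#' \eqn{\mathrm{MRE} = \langle |D_\mathrm{true} - D_\mathrm{pred}| /
#' D_\mathrm{true} \rangle} pooled over all steps (linear scale).
#'
#' @param pred_D,true_D per-step diffusion coefficients (linear scale).
#' @return scalar MRE.
#' @export
mre <- function(pred_D, true_D) {
  if (length(pred_D) != length(true_D)) stop("length mismatch")
  if (any(true_D == 0)) stop("true_D contains zeros")
  mean(abs(true_D - pred_D) / true_D)
}

#' Mean absolute error
#' @param pred_a,true_a per-step values (e.g. anomalous exponents).
#' @return scalar MAE.
#' @export
mae <- function(pred_a, true_a) {
  if (length(pred_a) != length(true_a)) stop("length mismatch")
  mean(abs(pred_a - true_a))
}

#' Jaccard index for changepoint sets with a position tolerance
#'
#' Predictions and ground-truth changepoints are matched greedily one-to-one
#' by increasing distance (ties broken toward the earlier true index); a
#' matched pair within `eps` steps is a true positive. The index is
#' \eqn{TP / (TP + FP + FN)}; two empty sets score 1.
#'
#' @param true_cps,pred_cps integer changepoint positions (any order).
#' @param eps matching tolerance in steps (>= 0).
#' @return JI in [0, 1].
#' @export
jaccard_cps <- function(true_cps, pred_cps, eps) {
  stopifnot(eps >= 0)
  nt <- length(true_cps); np <- length(pred_cps)
  if (nt == 0L && np == 0L) return(1)
  if (nt == 0L || np == 0L) return(0)
  true_cps <- sort(true_cps); pred_cps <- sort(pred_cps)
  d <- abs(outer(true_cps, pred_cps, "-"))
  pairs <- which(d <= eps, arr.ind = TRUE)
  tp <- 0L
  if (nrow(pairs)) {
    ord <- order(d[pairs], pairs[, 1L], pairs[, 2L])
    used_t <- logical(nt); used_p <- logical(np)
    for (r in ord) {
      i <- pairs[r, 1L]; j <- pairs[r, 2L]
      if (!used_t[i] && !used_p[j]) {
        used_t[i] <- TRUE; used_p[j] <- TRUE; tp <- tp + 1L
      }
    }
  }
  tp / (tp + (np - tp) + (nt - tp))
}

#' Stratified benchmark report
#'
#' Aggregates pointwise prediction errors over a labeled dataset, overall
#' and stratified by the length of the segment each step belongs to —
#' the benchmark curves for heterogeneous trajectories. For `target = "D"`
#' the metric is the mean relative error; for `"alpha"` the mean absolute
#' error.
#'
#' @param dataset list of `list(traj =, gt =)` pairs (see
#'   [generate_dataset()]).
#' @param predictions list of [pointwise_profile()]s aligned with `dataset`.
#' @param length_breaks bin edges (steps) for the segment-length
#'   stratification.
#' @return list of class `benchmark_report`: `target`, `overall`,
#'   `by_segment_length` (data frame with bin, metric, n), `n_traj`.
#' @export
stratified_report <- function(dataset, predictions,
                              length_breaks = c(0, 20, 40, 80, 120, Inf)) {
  stopifnot(length(dataset) == length(predictions))
  target <- predictions[[1L]]$target
  err <- numeric(0); seglen <- numeric(0)
  for (i in seq_along(dataset)) {
    gt <- dataset[[i]]$gt
    pr <- predictions[[i]]
    if (pr$target != target) stop("mixed prediction targets")
    n <- length(gt$D)
    if (length(pr$values) != n) stop("prediction/label length mismatch")
    e <- if (target == "D") {
      abs(gt$D - 10^pr$values) / gt$D
    } else {
      abs(gt$alpha - pr$values)
    }
    segs <- segments_from_cps(gt$changepoints, n)
    len_per_step <- rep.int(segs$end - segs$start, segs$end - segs$start)
    err <- c(err, e); seglen <- c(seglen, len_per_step)
  }
  bin <- cut(seglen, breaks = length_breaks, right = FALSE)
  tab <- data.frame(
    bin = levels(bin),
    metric = as.numeric(tapply(err, bin, mean)),
    n = as.integer(table(bin)))
  structure(list(target = target,
                 overall = mean(err),
                 metric = if (target == "D") "MRE" else "MAE",
                 by_segment_length = tab,
                 n_traj = length(dataset)),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("benchmark report (%s, %d trajectories): overall %s = %.3f\n",
              x$target, x$n_traj, x$metric, x$overall))
  print(x$by_segment_length, row.names = FALSE)
  invisible(x)
}

#' Mean Jaccard index over a changepoint benchmark
#'
#' Per-trajectory Jaccard indices at tolerance `eps`, averaged over the
#' dataset, with stratification by ground-truth property contrast and
#' changepoint position.
#'
#' @param true_list,pred_list lists of integer changepoint vectors.
#' @param eps matching tolerance in steps.
#' @param contrast optional numeric per-trajectory contrast (e.g. log10
#'   D-ratio or delta-alpha of the two segments) for stratified curves.
#' @param breaks bin edges for `contrast`.
#' @return list: `mean_ji`, `per_traj`, optionally `by_contrast`.
#' @export
ji_benchmark <- function(true_list, pred_list, eps, contrast = NULL,
                         breaks = NULL) {
  stopifnot(length(true_list) == length(pred_list))
  ji <- mapply(jaccard_cps, true_list, pred_list, MoreArgs = list(eps = eps))
  out <- list(mean_ji = mean(ji), per_traj = ji, eps = eps)
  if (!is.null(contrast)) {
    if (is.null(breaks)) breaks <- stats::quantile(contrast, 0:5 / 5)
    bin <- cut(contrast, breaks, include.lowest = TRUE)
    out$by_contrast <- data.frame(
      bin = levels(bin),
      mean_ji = as.numeric(tapply(ji, bin, mean)),
      n = as.integer(table(bin)))
  }
  out
}
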