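# Evaluation metrics: membrane-potential RMSE, van Rossum spike-train
# distance in closed pairwise form, and spike-timing precision/recall/F1.

#' Root mean square error between true and predicted potentials
#'
#' @param u true membrane potentials (mV).
#' @param u_hat predicted membrane potentials, same length.
#' @return RMSE in mV.
#' @export
rmse <- function(u, u_hat) {
  if (length(u) != length(u_hat))
    stop("length mismatch: ", length(u), " vs ", length(u_hat))
  sqrt(mean((u - u_hat)^2))
}

#' van Rossum distance between two spike trains
#'
#' Closed pairwise form of the squared van Rossum distance with an
#' exponential kernel of time constant `tau`:
#' `sum_ij exp(-|t_i - t_j|/tau)` within each train, minus twice the cross
#' term.  Equals `(2/tau)` times the integral of the squared difference of
#' the two trains convolved with the causal kernel `exp(-t/tau)`.
#' Empty-train sums are zero, so the distance of a k-spike train to an
#' empty train approaches k for well-separated spikes.
#'
#' @param true_times,pred_times spike-time vectors (ms); may be empty.
#' @param tau kernel time constant in ms (default 1).
#' @return nonnegative dimensionless distance.
#' @export
van_rossum <- function(true_times, pred_times, tau = 1) {
  stopifnot(tau > 0)
  self_sum <- function(x) {
    if (!length(x)) return(0)
    sum(exp(-abs(outer(x, x, "-")) / tau))
  }
  cross_sum <- if (length(true_times) && length(pred_times))
    sum(exp(-abs(outer(true_times, pred_times, "-")) / tau)) else 0
  v <- self_sum(true_times) + self_sum(pred_times) - 2 * cross_sum
  max(v, 0)
}

#' Precision, recall and F1 of a predicted spike train
#'
#' Counts coincidences on the common sample grid: `TP` are samples where
#' both trains spike, `FP` predicted-only, `FN` true-only.  For F1 scoring
#' the predicted train is normally the tolerance-adjusted train of
#' [tolerant_spike_train()], so matched predictions coincide exactly.
#' Conventions for empty trains: if both trains are empty all three scores
#' are 1 (degenerate agreement); otherwise an undefined precision or recall
#' counts as 0.
#'
#' @param true_train,pred_train [spike_train()] objects on the same grid.
#' @return list with `precision`, `recall`, `f1`, `tp`, `fp`, `fn`.
#' @export
precision_recall_f1 <- function(true_train, pred_train) {
  stopifnot(inherits(true_train, "spike_train"),
            inherits(pred_train, "spike_train"))
  if (true_train$n_steps != pred_train$n_steps ||
      abs(true_train$dt - pred_train$dt) > 1e-12)
    stop("spike trains are on different grids")
  a <- true_train$indicator; b <- pred_train$indicator
  tp <- sum(a == 1 & b == 1)
  fp <- sum(a == 0 & b == 1)
  fn <- sum(a == 1 & b == 0)
  if (tp + fp + fn == 0) {
    precision <- recall <- f1 <- 1
  } else {
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
  }
  list(precision = precision, recall = recall, f1 = f1,
       tp = tp, fp = fp, fn = fn)
}
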