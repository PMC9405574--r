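# Conversion of predicted membrane potentials to spike trains and
# tolerance-based matching of predicted against true spike times.

#' Convert predicted membrane potentials to a spike train
#'
#' Thresholds the predicted potentials at the empirical `1 - r * beta`
#' quantile `q` (linear-interpolation convention): sample `t` is a predicted
#' spike iff `u_hat[t] > q`, `u_hat[t] > u_hat[t-1]` (strict) and
#' `u_hat[t] >= u_hat[t+1]` (tie-tolerant), so plateaus yield a single
#' spike and endpoints never fire.  The inflation coefficient `beta >= 1`
#' raises the estimated firing ratio `r * beta` above the true firing
#' proportion `r` to absorb fluctuations in the prediction.
#'
#' @param u_hat predicted membrane potentials.
#' @param r true firing proportion in (0, 1).
#' @param beta inflation coefficient; `r * beta` must stay below 1.
#' @param dt sample step (ms).
#' @param t0 time of the first sample (ms).
#' @return a [spike_train()]; the threshold is attached as attribute
#'   `"threshold"`.
#' @export
potentials_to_spikes <- function(u_hat, r, beta, dt = 1, t0 = 0) {
  n <- length(u_hat)
  stopifnot(n >= 2, r > 0, beta >= 1)
  if (r * beta >= 1) stop("estimated firing ratio r * beta must be below 1")
  q <- stats::quantile(u_hat, 1 - r * beta, names = FALSE, type = 7)
  mid <- 2:(n - 1)
  is_spike <- u_hat[mid] > q &
    u_hat[mid] > u_hat[mid - 1] &
    u_hat[mid] >= u_hat[mid + 1]
  idx <- mid[is_spike]
  out <- spike_train(t0 + (idx - 1) * dt, n_steps = n, dt = dt, t0 = t0)
  attr(out, "threshold") <- q
  out
}

# greedy closest-pair-first matching: candidate (a_i, b_j) pairs within tau
# are admitted in order of increasing |a_i - b_j| (ties by earlier a, then
# earlier b), skipping pairs whose member is already matched.  Because the
# admitted set is a prefix of a tau-independent ordering, enlarging tau can
# only add matches, which keeps tolerance-adjusted scores monotone in tau.
greedy_match <- function(a, b, tau) {
  na <- length(a); nb <- length(b)
  d <- abs(outer(a, b, "-"))
  cand <- which(d <= tau, arr.ind = TRUE)
  used_a <- logical(na); used_b <- logical(nb)
  pairs <- matrix(numeric(0), ncol = 2)
  if (nrow(cand)) {
    ord <- order(d[cand], a[cand[, 1]], b[cand[, 2]])
    cand <- cand[ord, , drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (!used_a[i] && !used_b[j]) {
        used_a[i] <- TRUE; used_b[j] <- TRUE
        pairs <- rbind(pairs, c(a[i], b[j]))
      }
    }
  }
  list(pairs = pairs, used = used_b, used_a = used_a)
}

#' Maximum tolerance between true and predicted spike trains
#'
#' Sweeps the tolerance `tau` upward from 0 on the `dt` grid; at each `tau`
#' predicted and true spikes are greedily matched closest-pair-first
#' (candidate pairs within `tau` admitted by increasing time difference).
#' The maximum tolerance
#' `tau_max` is the smallest `tau` at which every spike of the smaller set
#' is matched.  The sweep's upper bound is
#' `max(|max(pred) - min(true)|, |max(true) - min(pred)|)`.  The result is
#' capped at `cap` (with `capped = TRUE`) when the search exceeds it.
#'
#' @param true_times,pred_times nonempty spike-time vectors (ms).
#' @param cap tolerance cap in ms (default `Inf`; the benchmark uses 30 ms
#'   for the PCR and RCR models).
#' @param dt sweep resolution (ms).
#' @return list with `tau_max`, `tau_upper` (the analytic upper bound),
#'   `matching` (two-column matrix of true/predicted pairs at `tau_max`),
#'   `unmatched_true`, `unmatched_pred`, `capped`.
#' @export
max_tolerance <- function(true_times, pred_times, cap = Inf, dt = 0.25) {
  if (!length(true_times) || !length(pred_times))
    stop("both spike-time sets must be nonempty")
  true_times <- sort(true_times); pred_times <- sort(pred_times)
  tau_ub <- max(abs(max(pred_times) - min(true_times)),
                abs(max(true_times) - min(pred_times)))
  small_is_true <- length(true_times) <= length(pred_times)
  a <- if (small_is_true) true_times else pred_times
  b <- if (small_is_true) pred_times else true_times
  tau <- 0
  repeat {
    m <- greedy_match(a, b, tau)
    if (nrow(m$pairs) == length(a) || tau > tau_ub || tau >= cap) break
    tau <- tau + dt
  }
  capped <- FALSE
  if (tau >= cap && nrow(m$pairs) < length(a)) {
    tau <- cap
    m <- greedy_match(a, b, cap)
    capped <- TRUE
  }
  pairs <- m$pairs
  if (!small_is_true && nrow(pairs)) pairs <- pairs[, 2:1, drop = FALSE]
  matched_true <- if (nrow(pairs)) pairs[, 1] else numeric(0)
  matched_pred <- if (nrow(pairs)) pairs[, 2] else numeric(0)
  list(tau_max = tau, tau_upper = tau_ub,
       matching = pairs,
       unmatched_true = setdiff(true_times, matched_true),
       unmatched_pred = setdiff(pred_times, matched_pred),
       capped = capped)
}

#' Predicted spike train adjusted by a tolerance
#'
#' Greedily matches predicted to true spikes closest-pair-first within
#' `tau` and substitutes each matched prediction by its true time;
#' unmatched predictions are kept as-is.  The result is re-gridded to an
#' indicator train, so after substitution matched predictions coincide
#' exactly with true spikes.
#'
#' @param true_times true spike times (ms).
#' @param pred_times predicted spike times (ms).
#' @param tau tolerance (ms, >= 0).
#' @param n_steps,dt,t0 grid of the output train.
#' @return a [spike_train()].
#' @export
tolerant_spike_train <- function(true_times, pred_times, tau, n_steps, dt,
                                 t0 = 0) {
  stopifnot(tau >= 0)
  if (!length(pred_times))
    return(spike_train(numeric(0), n_steps = n_steps, dt = dt, t0 = t0))
  pred_times <- sort(pred_times)
  out <- pred_times
  if (length(true_times)) {
    m <- greedy_match(pred_times, sort(true_times), tau)
    if (nrow(m$pairs))
      out[match(m$pairs[, 1], pred_times)] <- m$pairs[, 2]
  }
  spike_train(unique(out), n_steps = n_steps, dt = dt, t0 = t0)
}

#' Default inflation-coefficient grids
#'
#' Full models (SRM, SSRM) search 11 uniform points on `[1, 1.5]`;
#' pruned models (RSRM, RSSRM, PCR, RCR) search 60 log-spaced points on
#' `[1, 270]`, reflecting the much larger fluctuations of their predictions.
#'
#' @param family `"full"` or `"reduced"`.
#' @return numeric vector of beta values.
#' @export
beta_grid <- function(family = c("full", "reduced")) {
  family <- match.arg(family)
  if (family == "full") seq(1, 1.5, length.out = 11)
  else exp(seq(log(1), log(270), length.out = 60))
}

#' Select the inflation coefficient by tolerance-adjusted F1
#'
#' Evaluates every `beta` in the grid: predicted potentials are converted
#' with [potentials_to_spikes()], the maximum tolerance is found with
#' [max_tolerance()], the prediction is adjusted with
#' [tolerant_spike_train()], and the F1-score against the truth is
#' computed.  The `beta` maximizing F1 wins; ties go to the smallest
#' `beta`, and among equal-F1 candidates the smaller `tau_max` is
#' preferred.
#'
#' @param u_hat predicted membrane potentials.
#' @param truth a [spike_train()] of ground-truth spikes on the same grid.
#' @param grid candidate beta values (filtered to `r * beta < 1`).
#' @param cap tolerance cap (ms).
#' @return list with `beta`, `train` (unadjusted predicted train),
#'   `adjusted` (tolerance-adjusted train), `tau_max`, `f1`, `report`
#'   (the [precision_recall_f1()] record), `threshold`.
#' @export
select_beta <- function(u_hat, truth, grid = beta_grid("reduced"), cap = Inf) {
  stopifnot(inherits(truth, "spike_train"), length(u_hat) == truth$n_steps)
  r <- truth$r
  if (r <= 0) stop("truth has no spikes; degenerate trace")
  grid <- grid[r * grid < 1]
  if (!length(grid)) stop("no beta in the grid satisfies r * beta < 1")
  best <- NULL
  for (beta in grid) {
    pred <- potentials_to_spikes(u_hat, r, beta, dt = truth$dt, t0 = truth$t0)
    if (length(pred$times) == 0) {
      cand <- list(beta = beta, train = pred, adjusted = pred,
                   tau_max = NA_real_, f1 = 0,
                   report = precision_recall_f1(truth, pred),
                   threshold = attr(pred, "threshold"))
    } else {
      tol <- max_tolerance(truth$times, pred$times, cap = cap, dt = truth$dt)
      adj <- tolerant_spike_train(truth$times, pred$times, tol$tau_max,
                                  n_steps = truth$n_steps, dt = truth$dt,
                                  t0 = truth$t0)
      rep <- precision_recall_f1(truth, adj)
      cand <- list(beta = beta, train = pred, adjusted = adj,
                   tau_max = tol$tau_max, f1 = rep$f1, report = rep,
                   threshold = attr(pred, "threshold"))
    }
    if (is.null(best) || cand$f1 > best$f1 + 1e-12 ||
        (abs(cand$f1 - best$f1) <= 1e-12 && !is.na(cand$tau_max) &&
         !is.na(best$tau_max) && cand$tau_max < best$tau_max - 1e-12))
      best <- cand
  }
  best
}
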