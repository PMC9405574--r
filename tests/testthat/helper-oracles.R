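# Shared fixtures and independent oracles used across test files.

# minimal behavior spec with a constant baseline current
toy_spec <- function(a = 0.02, b = 0.2, cc = -65, d = 6, v0 = -70,
                     u0 = b * v0, I = 0, dt = 0.25, n = 200, ...) {
  behavior_spec("toy", a = a, b = b, c = cc, d = d, v0 = v0, u0 = u0,
                dt = dt, n_steps = n,
                stimulus = stimulus_protocol(baseline = I), ...)
}

# numerical-quadrature van Rossum oracle: (2/tau) * integral of the squared
# difference of the trains convolved with the causal kernel exp(-t/tau)
vr_quadrature <- function(a, b, tau = 1, h = 0.002) {
  lo <- min(a, b, 0)
  hi <- max(a, b) + 20 * tau
  # include both one-sided limits at every spike: the filtered train jumps
  # there and the trapezoid rule must not bridge the discontinuity
  knots <- c(a, b)
  grid <- sort(unique(c(seq(lo, hi, by = h), knots, knots - 1e-9)))
  f <- function(times, t) {
    out <- numeric(length(t))
    for (s in times) {
      idx <- t >= s
      out[idx] <- out[idx] + exp(-(t[idx] - s) / tau)
    }
    out
  }
  d2 <- (f(a, grid) - f(b, grid))^2
  w <- diff(grid)
  (2 / tau) * sum((d2[-1] + d2[-length(d2)]) / 2 * w)
}

# brute-force optimal matching: smallest tau on a grid at which a perfect
# matching of the smaller set within tau exists (bipartite feasibility by
# recursion; sets are tiny)
bf_can_match_all <- function(a, b, tau) {
  if (!length(a)) return(TRUE)
  cand <- which(abs(b - a[1]) <= tau)
  for (j in cand) {
    if (bf_can_match_all(a[-1], b[-j], tau)) return(TRUE)
  }
  FALSE
}

bf_tau_max <- function(true_times, pred_times, dt = 0.25) {
  small <- if (length(true_times) <= length(pred_times)) true_times else pred_times
  big <- if (length(true_times) <= length(pred_times)) pred_times else true_times
  tau <- 0
  while (!bf_can_match_all(small, big, tau)) tau <- tau + dt
  tau
}

# brute-force local-maximum spike detection (Algorithm 1 oracle)
bf_detect <- function(u_hat, q) {
  n <- length(u_hat)
  which(vapply(2:(n - 1), function(t)
    u_hat[t] > q && u_hat[t] > u_hat[t - 1] && u_hat[t] >= u_hat[t + 1],
    logical(1))) + 1L
}
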