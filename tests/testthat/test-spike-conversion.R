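test_that("spike detection thresholds at the inflated-ratio quantile", {
  set.seed(11)
  u_hat <- rnorm(200)
  st <- potentials_to_spikes(u_hat, r = 0.10, beta = 1.5)
  expect_equal(attr(st, "threshold"),
               quantile(u_hat, 0.85, names = FALSE))
  expect_error(potentials_to_spikes(u_hat, r = 0.5, beta = 2), "below 1")
})

test_that("detection requires a strict-left, tie-tolerant-right local max", {
  expect_length(potentials_to_spikes(rep(1, 50), 0.1, 1)$times, 0)
  st <- potentials_to_spikes(c(0, 0, 10, 0, 0), r = 0.1, beta = 2, dt = 1)
  expect_equal(st$times, 2)       # third sample, t0 = 0 grid
  # a plateau yields exactly one spike (its left edge)
  st2 <- potentials_to_spikes(c(0, 1, 5, 5, 0, 0, 0, 0, 0, 0),
                              r = 0.1, beta = 2, dt = 1)
  expect_equal(st2$times, 2)
  # endpoints never fire
  st3 <- potentials_to_spikes(c(10, 0, 0, 0, 10), r = 0.2, beta = 2, dt = 1)
  expect_length(st3$times, 0)
})

test_that("detection agrees with the brute-force oracle on random inputs", {
  set.seed(12)
  for (rep in 1:20) {
    u_hat <- rnorm(60)
    r <- runif(1, 0.02, 0.2); beta <- runif(1, 1, 3)
    st <- potentials_to_spikes(u_hat, r, beta, dt = 1)
    q <- quantile(u_hat, 1 - r * beta, names = FALSE)
    expect_equal(which(st$indicator == 1), bf_detect(u_hat, q),
                 ignore_attr = TRUE)
  }
})

test_that("raising beta weakly increases the number of detected spikes", {
  set.seed(13)
  for (rep in 1:10) {
    u_hat <- cumsum(rnorm(120))
    counts <- vapply(seq(1, 4, by = 0.5), function(b)
      length(potentials_to_spikes(u_hat, 0.05, b, dt = 1)$times), numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("maximum tolerance reproduces the worked example and edge cases", {
  res <- max_tolerance(c(3, 15), c(1, 10), dt = 1)
  expect_equal(res$tau_upper, 14)
  expect_equal(res$tau_max, 5)    # greedy: 3~1 at tau >= 2, 15~10 at tau >= 5
  expect_equal(max_tolerance(c(2, 9), c(2, 9))$tau_max, 0)
  expect_equal(max_tolerance(5, 7, dt = 1)$tau_max, 2)
  expect_error(max_tolerance(numeric(0), 1), "nonempty")
})

test_that("greedy tolerance matches the brute-force optimum on small sets", {
  set.seed(14)
  for (rep in 1:25) {
    a <- sort(sample(0:40, sample(1:5, 1)))
    b <- sort(sample(0:40, sample(1:5, 1)))
    res <- max_tolerance(a, b, dt = 0.5)
    # every pair respects tau_max; the smaller set is fully matched
    if (nrow(res$matching))
      expect_true(all(abs(res$matching[, 1] - res$matching[, 2]) <=
                        res$tau_max + 1e-9))
    expect_equal(nrow(res$matching), min(length(a), length(b)))
    # greedy can need at least the optimal tolerance, never less
    expect_gte(res$tau_max, bf_tau_max(a, b, dt = 0.5))
  }
})

test_that("the tolerance cap binds for distant predictions", {
  res <- max_tolerance(c(5), c(100), cap = 30, dt = 1)
  expect_true(res$capped)
  expect_equal(res$tau_max, 30)
  expect_equal(nrow(res$matching), 0)
})

test_that("tolerance substitution rewrites matched predictions only", {
  out <- tolerant_spike_train(c(3, 15), c(1, 10), tau = 2, n_steps = 20,
                              dt = 1)
  expect_equal(out$times, c(3, 10))
  # tau = 0 keeps the prediction unchanged
  out0 <- tolerant_spike_train(c(3, 15), c(1, 10), tau = 0, n_steps = 20,
                               dt = 1)
  expect_equal(out0$times, c(1, 10))
  # at tau >= tau_max with equal counts, the output equals the truth
  set.seed(15)
  tt <- sort(sample(1:50, 4)); pp <- sort(sample(1:50, 4))
  tm <- max_tolerance(tt, pp, dt = 1)$tau_max
  adj <- tolerant_spike_train(tt, pp, tm, n_steps = 60, dt = 1)
  expect_equal(adj$times, tt)
})

test_that("tolerance-adjusted F1 is non-decreasing in tau", {
  set.seed(16)
  for (rep in 1:10) {
    tt <- sort(sample(1:80, 5))
    pp <- sort(sample(1:80, 6))
    truth <- spike_train(tt, 100, 1)
    f1s <- vapply(0:40, function(tau) {
      adj <- tolerant_spike_train(tt, pp, tau, n_steps = 100, dt = 1)
      precision_recall_f1(truth, adj)$f1
    }, numeric(1))
    expect_true(all(diff(f1s) >= -1e-12))
  }
})

test_that("beta selection maximizes tolerance-adjusted F1 with min-beta ties", {
  set.seed(17)
  tt <- c(10, 30, 50, 70)
  truth <- spike_train(tt, 100, 1)
  u_hat <- rep(0, 100); u_hat[tt + 1] <- 5   # perfect peaks at spike samples
  sel <- select_beta(u_hat, truth, grid = c(1, 1.2, 1.4))
  expect_equal(sel$beta, 1)
  expect_equal(sel$f1, 1)
  sel1 <- select_beta(u_hat, truth, grid = 2)
  expect_equal(sel1$beta, 2)
  # exhaustive oracle over a noisy prediction
  u_noisy <- rnorm(100) + 3 * (seq_len(100) %in% (tt + 1))
  grid <- seq(1, 8, by = 0.5)
  sel2 <- select_beta(u_noisy, truth, grid = grid)
  oracle <- max(vapply(grid, function(b) {
    pred <- potentials_to_spikes(u_noisy, truth$r, b, dt = 1)
    if (!length(pred$times)) return(0)
    tol <- max_tolerance(tt, pred$times, dt = 1)
    adj <- tolerant_spike_train(tt, pred$times, tol$tau_max, 100, 1)
    precision_recall_f1(truth, adj)$f1
  }, numeric(1)))
  expect_equal(sel2$f1, oracle)
})
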