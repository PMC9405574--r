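test_that("unpenalized fit on a perfectly informative column is exact", {
  set.seed(1)
  y <- rnorm(25)
  X <- matrix(y, ncol = 1, dimnames = list(NULL, "x"))
  f <- fit_penalized(X, y, penalty_spec(l2 = 0, l1 = 0), standardize = FALSE)
  expect_equal(unname(f$weights), 1, tolerance = 1e-10)
  expect_equal(f$intercept, 0, tolerance = 1e-10)
  expect_equal(rmse(y, predict(f, X)), 0, tolerance = 1e-10)
})

test_that("a saturating L1 penalty zeroes all weights and keeps the mean", {
  set.seed(2)
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(30, mean = 5)
  f <- fit_penalized(X, y, penalty_spec(l2 = 0.01, l1 = 1e6))
  expect_equal(f$nonzero_count, 0)
  expect_equal(unname(f$weights), c(0, 0))
  expect_equal(f$intercept, mean(y), tolerance = 1e-8)
})

test_that("lasso on an orthogonal design equals the soft-threshold formula", {
  set.seed(3)
  n <- 64
  B <- fourier_basis(n)[, 2:7]        # orthogonal, zero-mean columns
  w_true <- c(3, -2, 0, 0.8, 0, 0)
  y <- drop(B %*% w_true) + rnorm(n, sd = 0.2)
  for (l1 in c(0.5, 4, 20)) {
    for (l2 in c(0, 0.01)) {
      f <- fit_penalized(B, y, penalty_spec(l2 = l2, l1 = l1),
                         standardize = FALSE)
      z <- drop(crossprod(B, y - mean(y)))
      d <- colSums(B^2)
      oracle <- sign(z) * pmax(abs(z) - l1, 0) / (d + 2 * l2)
      expect_equal(unname(f$weights), unname(oracle), tolerance = 1e-6)
    }
  }
})

test_that("the l1 = 0 path matches the closed-form ridge solution", {
  set.seed(4)
  X <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("c", 1:6)))
  y <- rnorm(40)
  l2 <- 0.7
  f <- fit_penalized(X, y, penalty_spec(l2 = l2, l1 = 0), standardize = FALSE)
  Xc <- scale(X, scale = FALSE)
  w <- solve(crossprod(Xc) + 2 * l2 * diag(6), crossprod(Xc, y - mean(y)))
  expect_equal(unname(f$weights), unname(drop(w)), tolerance = 1e-8)
  # dual (p > n) and primal solves agree
  Xp <- matrix(rnorm(10 * 30), 10, 30)
  yp <- rnorm(10)
  fd <- fit_penalized(Xp, yp, penalty_spec(l2 = 0.5, l1 = 0))
  G <- crossprod(scale(Xp, center = TRUE,
                       scale = sqrt(colMeans(scale(Xp, scale = FALSE)^2))))
  wp <- solve(G + 2 * 0.5 * diag(30), crossprod(
    scale(Xp, center = TRUE, scale = sqrt(colMeans(scale(Xp, scale = FALSE)^2))),
    yp - mean(yp)))
  sds <- sqrt(colMeans(scale(Xp, scale = FALSE)^2))
  expect_equal(unname(fd$weights), drop(wp) / sds, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("the elastic-net solution satisfies the KKT conditions", {
  set.seed(5)
  X <- matrix(rnorm(80 * 20), 80, 20)
  y <- drop(X[, 1:3] %*% c(2, -1, 1)) + rnorm(80, sd = 0.5)
  l1 <- 15; l2 <- 0.01
  f <- fit_penalized(X, y, penalty_spec(l2 = l2, l1 = l1))
  # reconstruct the standardized problem the penalties act on
  Xc <- scale(X, scale = FALSE)
  sds <- sqrt(colMeans(Xc^2))
  Xs <- sweep(Xc, 2, sds, "/")
  ws <- f$weights * sds
  g <- drop(crossprod(Xs, (y - mean(y)) - Xs %*% ws)) - 2 * l2 * ws
  active <- abs(ws) > 1e-8
  expect_true(all(abs(g[active] - l1 * sign(ws[active])) < 1e-3 * l1))
  expect_true(all(abs(g[!active]) <= l1 * (1 + 1e-3)))
})

test_that("prediction matches hand arithmetic and validates labels", {
  X <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2, dimnames = list(NULL, c("p", "q")))
  f <- structure(list(intercept = 0.5, weights = c(p = 2, q = -1),
                      labels = c("p", "q"),
                      penalty = penalty_spec()), class = "srm_fit")
  expect_equal(predict(f, X), 0.5 + c(1 * 2 - 4, 2 * 2 - 5, 3 * 2 - 6))
  f0 <- f; f0$weights[] <- 0
  expect_equal(predict(f0, X), rep(0.5, 3))
  colnames(X) <- c("p", "wrong")
  expect_error(predict(f, X), "do not match")
})

test_that("nonzero counting respects the zero tolerance", {
  f <- structure(list(weights = c(0, 1e-12, 3), penalty = penalty_spec()),
                 class = "srm_fit")
  expect_equal(count_nonzero(f), 1)
  expect_equal(count_nonzero(f, zero_tol = 1e-13), 2)
  set.seed(6)
  w <- rnorm(50) * rbinom(50, 1, 0.4)
  f$weights <- w
  expect_equal(count_nonzero(f), sum(abs(w) > 1e-8))
})

test_that("nonzero count decreases along increasing L1 strength", {
  set.seed(7)
  X <- matrix(rnorm(100 * 50), 100, 50)
  y <- drop(X[, 1:10] %*% rnorm(10)) + rnorm(100, sd = 0.3)
  l1s <- exp(seq(log(0.1), log(200), length.out = 12))
  counts <- vapply(l1s, function(l1)
    count_nonzero(fit_penalized(X, y, penalty_spec(l2 = 0.01, l1 = l1))),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("L1 bisection reaches requested coefficient counts", {
  set.seed(8)
  X <- matrix(rnorm(120 * 50), 120, 50)
  y <- drop(X %*% (rnorm(50) * rbinom(50, 1, 0.5))) + rnorm(120, sd = 0.5)
  # full-width target is the unpenalized model
  full <- tune_l1_for_count(X, y, 50)
  expect_equal(full$l1, 0)
  expect_equal(full$achieved, 50)
  # near-saturation target engages the large-l1 branch
  one <- tune_l1_for_count(X, y, 1)
  expect_lte(one$achieved, 2)
  expect_gte(one$achieved, 1)
  mid <- tune_l1_for_count(X, y, 20)
  expect_lte(abs(mid$achieved - 20), 1)
  expect_equal(count_nonzero(mid$fit), mid$achieved)
})
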