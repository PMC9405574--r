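# Penalized least-squares fitting of membrane potentials: exact ridge
# solves for the unpruned models, coordinate-descent elastic net (glmnet)
# when an L1 term prunes coefficients, and a bisection search of the L1
# strength that hits a target nonzero-coefficient count.

#' Penalty specification
#'
#' The fitting objective is
#' `0.5 * sum((y - yhat)^2) + l1 * sum(|w|) + l2 * sum(w^2)`,
#' with the intercept (resting potential) always unpenalized.  Penalties
#' act on the internally standardized coefficients (see [fit_penalized()]).
#'
#' @param l2 ridge strength (>= 0); every benchmark model uses 0.01.
#' @param l1 lasso strength (>= 0); 0 disables pruning.
#' @param zero_tol magnitude below which a back-transformed weight counts
#'   as zero.
#' @return object of class `penalty_spec`.
#' @export
penalty_spec <- function(l2 = 0.01, l1 = 0, zero_tol = 1e-8) {
  stopifnot(l2 >= 0, l1 >= 0, zero_tol > 0)
  structure(list(l2 = l2, l1 = l1, zero_tol = zero_tol),
            class = "penalty_spec")
}

.design_X <- function(design) {
  if (inherits(design, "design_matrix")) design$X
  else as.matrix(design)
}

#' Fit membrane potentials by penalized least squares
#'
#' Minimizes `0.5 * RSS + l1 * ||w||_1 + l2 * ||w||_2^2` with an unpenalized
#' intercept.  Columns are centered and (optionally) scaled to unit variance
#' internally; penalties apply to the standardized coefficients and the
#' returned weights are back-transformed to the original column scale.
#' With `l1 = 0` the solution is the exact (closed-form) ridge estimate,
#' solved in the primal or dual depending on the design shape; with
#' `l1 > 0` the elastic-net objective is solved by cyclic coordinate
#' descent via \pkg{glmnet}.
#'
#' @param design a `design_matrix` or plain numeric matrix.
#' @param y response (membrane potentials aligned with the design rows).
#' @param penalty a [penalty_spec()].
#' @param standardize scale columns to unit variance internally (default
#'   TRUE; constant columns get weight 0).
#' @param thresh coordinate-descent convergence threshold.
#' @return object of class `srm_fit` with fields `intercept`, `weights`
#'   (original scale, named by column label), `penalty`, `nonzero_count`,
#'   `objective_value` (on the standardized problem) and bookkeeping.
#' @export
fit_penalized <- function(design, y, penalty = penalty_spec(),
                          standardize = TRUE, thresh = 1e-9) {
  X <- .design_X(design)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, inherits(penalty, "penalty_spec"))
  centers <- colMeans(X)
  Xc <- sweep(X, 2, centers, "-")
  sds <- if (standardize) sqrt(colMeans(Xc^2)) else rep(1, p)
  ok <- sds > 1e-12
  sds[!ok] <- 1
  Xs <- sweep(Xc, 2, sds, "/")
  ym <- mean(y)
  yc <- y - ym
  w_std <- numeric(p)
  if (any(ok)) {
    A <- Xs[, ok, drop = FALSE]
    if (penalty$l1 == 0) {
      w_std[ok] <- .ridge_exact(A, yc, penalty$l2)
    } else {
      w_std[ok] <- .enet_glmnet(A, yc, penalty$l1, penalty$l2, thresh)
    }
  }
  w <- w_std / sds
  w[!ok] <- 0
  names(w) <- colnames(X)
  obj <- 0.5 * sum((yc - Xs %*% w_std)^2) +
    penalty$l1 * sum(abs(w_std)) + penalty$l2 * sum(w_std^2)
  fit <- structure(list(
    intercept = ym - sum(w * centers),
    weights = w,
    penalty = penalty,
    nonzero_count = sum(abs(w) > penalty$zero_tol),
    objective_value = obj,
    labels = colnames(X),
    standardized = standardize,
    n_obs = n), class = "srm_fit")
  fit
}

# exact ridge: argmin 0.5*||y - A w||^2 + l2*||w||^2
.ridge_exact <- function(A, y, l2) {
  n <- nrow(A); p <- ncol(A)
  if (l2 > 0) {
    if (p <= n) {
      G <- crossprod(A)
      diag(G) <- diag(G) + 2 * l2
      drop(solve(G, crossprod(A, y)))
    } else {
      K <- tcrossprod(A)
      diag(K) <- diag(K) + 2 * l2
      drop(crossprod(A, solve(K, y)))
    }
  } else {
    # minimum-norm least squares via SVD
    sv <- svd(A)
    keep <- sv$d > max(dim(A)) * .Machine$double.eps * sv$d[1]
    drop(sv$v[, keep, drop = FALSE] %*%
           ((crossprod(sv$u[, keep, drop = FALSE], y)) / sv$d[keep]))
  }
}

# elastic net at one exact (l1, l2) pair on a pre-standardized design.
# glmnet minimizes RSS/(2n) + lam * (alpha*||w||_1 + (1-alpha)/2*||w||_2^2);
# alpha = l1/(l1 + 2*l2), lam = (l1 + 2*l2)/n recovers
# 0.5*RSS + l1*||w||_1 + l2*||w||_2^2 at the final lambda of the path.
# glmnet normalizes the response internally by its 1/n standard deviation,
# which rescales the quadratic (ridge) term but not the L1 term; the ridge
# strength is pre-multiplied by sd(y) to compensate exactly.
.enet_glmnet <- function(A, y, l1, l2, thresh = 1e-9) {
  n <- nrow(A)
  sy <- sqrt(mean(y^2))
  if (sy > 0) l2 <- l2 * sy
  alpha <- l1 / (l1 + 2 * l2)
  lam <- (l1 + 2 * l2) / n
  path <- lam * c(64, 16, 4, 1)
  fit <- glmnet::glmnet(A, y, family = "gaussian", alpha = alpha,
                        lambda = path, standardize = FALSE,
                        intercept = FALSE, thresh = thresh, maxit = 1e6)
  as.numeric(fit$beta[, length(path)])
}

#' @export
print.srm_fit <- function(x, ...) {
  cat(sprintf("srm_fit: %d coefficients (%d nonzero), intercept %.3f, l1=%g l2=%g\n",
              length(x$weights), x$nonzero_count, x$intercept,
              x$penalty$l1, x$penalty$l2))
  invisible(x)
}

#' Predict membrane potentials from a fit
#'
#' `yhat = intercept + X w`.  Spike-history regressors in the design are the
#' ground-truth history (teacher forcing), both at fit and predict time.
#'
#' @param object an `srm_fit`.
#' @param design a `design_matrix` (or matrix) with the same columns as the
#'   fit.
#' @param ... unused.
#' @return numeric vector of predicted potentials.
#' @export
predict.srm_fit <- function(object, design, ...) {
  X <- .design_X(design)
  if (!is.null(colnames(X)) && !identical(colnames(X), object$labels))
    stop("design columns do not match the fitted weights")
  if (ncol(X) != length(object$weights))
    stop("design has ", ncol(X), " columns; fit has ", length(object$weights))
  drop(object$intercept + X %*% object$weights)
}

#' Count nonzero coefficients of a fit
#'
#' Counts weights with `|w| > zero_tol`, excluding the intercept.
#'
#' @param fit an `srm_fit`.
#' @param zero_tol overrides the fit's stored tolerance if given.
#' @return integer count.
#' @export
count_nonzero <- function(fit, zero_tol = fit$penalty$zero_tol) {
  sum(abs(fit$weights) > zero_tol)
}

#' Tune the L1 strength to a target nonzero-coefficient count
#'
#' Bisects on `log(l1)` until the nonzero count of the elastic-net fit is
#' within `slack` of `target_count` or the bracket collapses, returning the
#' closest achieved fit.  An initial lasso path bounds the bracket so the
#' bisection starts near the target.
#'
#' @param design a `design_matrix` or matrix.
#' @param y response vector.
#' @param target_count desired number of nonzero coefficients.
#' @param l2 fixed ridge strength (default 0.01).
#' @param zero_tol zero threshold for counting.
#' @param slack relative tolerance on the achieved count (default 0.02);
#'   counts within `max(target_count * slack, 0)` of the target stop the
#'   search early.
#' @param max_iter maximum bisection steps.
#' @param refit after the L1 search has selected the surviving columns,
#'   refit them by ridge (`l2` only) so the pruned model's coefficients are
#'   free of the large L1 shrinkage bias (default TRUE; this makes the
#'   pruned model directly comparable to fixed-width designs of the same
#'   size fitted by ridge).  The selection itself is always the elastic-net
#'   solution.
#' @return list with `l1`, `fit` (an `srm_fit`), `achieved` (count),
#'   `converged` (TRUE if within slack).
#' @export
tune_l1_for_count <- function(design, y, target_count, l2 = 0.01,
                              zero_tol = 1e-8, slack = 0.02, max_iter = 30,
                              refit = TRUE) {
  X <- .design_X(design)
  p <- ncol(X)
  stopifnot(target_count >= 1, target_count <= p)
  tol <- target_count * slack
  fit_at <- function(l1) fit_penalized(design, y,
                                       penalty_spec(l2 = l2, l1 = l1,
                                                    zero_tol = zero_tol))
  # a target at (or above) the design width is the l1 = 0 full model
  if (target_count + tol >= p) {
    f0 <- fit_at(0)
    return(list(l1 = 0, fit = f0, achieved = count_nonzero(f0),
                converged = abs(count_nonzero(f0) - target_count) <= tol))
  }

  # bracket from a quick lasso path (the tiny fixed l2 barely moves the
  # df-vs-lambda curve; exact fits below decide)
  centers <- colMeans(X); Xc <- sweep(X, 2, centers, "-")
  sds <- sqrt(colMeans(Xc^2)); sds[sds <= 1e-12] <- 1
  Xs <- sweep(Xc, 2, sds, "/")
  yc <- y - mean(y)
  n <- nrow(X)
  l1_max <- max(abs(crossprod(Xs, yc)))   # KKT bound: all-zero solution
  path <- glmnet::glmnet(Xs, yc, alpha = 1, nlambda = 60,
                         lambda.min.ratio = 1e-4, standardize = FALSE,
                         intercept = FALSE)
  dfs <- path$df
  lams <- path$lambda * n
  lo <- if (any(dfs > target_count)) max(lams[dfs > target_count] * 0.5,
                                         l1_max * 1e-8)
        else l1_max * 1e-8
  hi <- if (any(dfs < target_count)) min(lams[dfs < target_count] * 2,
                                         l1_max * 1.05)
        else l1_max * 1.05
  lo <- min(lo, hi / 2)

  best <- NULL
  consider <- function(l1, fit) {
    cnt <- count_nonzero(fit)
    if (is.null(best) || abs(cnt - target_count) < abs(best$achieved - target_count))
      best <<- list(l1 = l1, fit = fit, achieved = cnt,
                    converged = abs(cnt - target_count) <= tol)
    cnt
  }
  for (iter in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    cnt <- consider(mid, fit_at(mid))
    if (abs(cnt - target_count) <= tol) break
    if (cnt > target_count) lo <- mid else hi <- mid
    if (hi / lo < 1 + 1e-4) break
  }
  if (!best$converged)
    warning(sprintf("target count %d not reached exactly; closest achieved %d",
                    target_count, best$achieved))
  if (refit && best$achieved > 0 && best$l1 > 0) {
    active <- which(abs(best$fit$weights) > zero_tol)
    sub <- X[, active, drop = FALSE]
    rf <- fit_penalized(sub, y, penalty_spec(l2 = l2, l1 = 0,
                                             zero_tol = zero_tol))
    w <- stats::setNames(numeric(p), colnames(X))
    w[active] <- rf$weights
    fit <- best$fit
    fit$weights <- w
    fit$intercept <- rf$intercept
    fit$nonzero_count <- sum(abs(w) > zero_tol)
    fit$objective_value <- NA_real_   # objective of the selection step only
    fit$refitted <- TRUE
    best$fit <- fit
    best$achieved <- fit$nonzero_count
  }
  best
}
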