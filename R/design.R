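# Design-matrix builders for the six model families: lagged filters
# (SRM/RSRM), Fourier features (SSRM/RSSRM), principal components (PCR) and
# raised-cosine features (RCR).

new_design_matrix <- function(X, labels, target_rows, family) {
  stopifnot(ncol(X) == length(labels), !anyDuplicated(labels))
  colnames(X) <- labels
  structure(list(X = X, labels = labels, target_rows = as.integer(target_rows),
                 family = family),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design_matrix (%s): %d rows x %d cols, target rows %d..%d\n",
              x$family, nrow(x$X), ncol(x$X),
              min(x$target_rows), max(x$target_rows)))
  invisible(x)
}

#' Lagged design for the classic spike response model
#'
#' One column per injected-current lag `s = 0..J` and per spike-history lag
#' `q = 1..Q`; rows are restricted to samples where every lag exists, i.e.
#' target samples `t = max(J, Q) + 1, ..., n` (1-based).
#'
#' @param I injected-current sequence.
#' @param S spike-indicator sequence (0/1), same length.
#' @param J number of current lags beyond lag 0 (J >= 0).
#' @param Q number of spike-history lags (Q >= 1).
#' @return a `design_matrix` with `J + 1 + Q` columns.
#' @export
lagged_design <- function(I, S, J, Q) {
  n <- length(I)
  stopifnot(length(S) == n, J >= 0, Q >= 1)
  m <- max(J, Q)
  if (m >= n) stop("lags must be smaller than the sequence length")
  rows <- (m + 1L):n
  Xi <- vapply(0:J, function(s) I[rows - s], numeric(length(rows)))
  Xs <- vapply(1:Q, function(q) S[rows - q], numeric(length(rows)))
  new_design_matrix(cbind(Xi, Xs),
                    c(paste0("I_lag", 0:J), paste0("S_lag", 1:Q)),
                    rows, "lagged")
}

#' Number of columns of the full Fourier feature design
#'
#' Each channel contributes every Fourier basis column except the constant:
#' `n - 1` columns per channel for either parity of `n`, so the two-channel
#' full design has `2 (n - 1)` columns.
#'
#' @param n sample count (>= 2).
#' @param channels number of input channels (default 2: current and lagged
#'   spike history).
#' @return integer column count.
#' @export
n_fourier_columns <- function(n, channels = 2) {
  stopifnot(n >= 2)
  as.integer(channels * (n - 1))
}

#' Orthogonal Fourier basis matrix
#'
#' Returns the `n x n` orthogonal trigonometric basis on `t = 1..n`:
#' a constant column, sine/cosine pairs at frequencies `i = 1, 2, ...`, and
#' for even `n` a final alternating column `(-1)^t` at the Nyquist frequency.
#' Columns are mutually orthogonal (not normalized): `t(F) %*% F` is diagonal
#' with entries `n` (constant and alternating) and `n/2` (pairs).
#'
#' @param n sample count (>= 2).
#' @return `n x n` matrix with labelled columns.
#' @export
fourier_basis <- function(n) {
  stopifnot(n >= 2)
  t <- seq_len(n)
  m <- if (n %% 2 == 0) n / 2 - 1 else (n - 1) / 2
  cols <- list(const = rep(1, n))
  for (i in seq_len(m)) {
    w <- 2 * pi * i * t / n
    cols[[paste0("cos", i)]] <- cos(w)
    cols[[paste0("sin", i)]] <- sin(w)
  }
  if (n %% 2 == 0) cols[["alt"]] <- (-1)^t
  do.call(cbind, cols)
}

#' Fourier feature design for the spectral spike response model
#'
#' Multiplies each input channel elementwise with the non-constant columns
#' of the Fourier basis [fourier_basis()], giving regressors
#' `cos(i w t) x(t)` and `sin(i w t) x(t)` (plus the alternating-sign
#' regressor for even `n`).  With `n_freq = "full"` each channel contributes
#' `n - 1` columns, so the two-channel design has `2 (n - 1)` columns,
#' enough to interpolate the training signal on the channels' support.
#'
#' @param I injected-current sequence (length n).
#' @param S_prev spike indicator lagged by one sample: `S_prev[t] = S[t-1]`,
#'   with `S_prev[1] = 0`.  Use [lag_indicator()] to build it.
#' @param n_freq number of sine/cosine frequencies per channel, or `"full"`
#'   for the complete basis up to Nyquist.
#' @return a `design_matrix` whose rows cover all n samples.
#' @export
fourier_feature_design <- function(I, S_prev, n_freq = "full") {
  n <- length(I)
  stopifnot(length(S_prev) == n, n >= 2)
  nyq <- if (n %% 2 == 0) n / 2 else (n - 1) / 2
  full <- identical(n_freq, "full")
  if (!full) {
    stopifnot(is.numeric(n_freq), n_freq >= 1)
    if (n_freq > nyq)
      stop("n_freq exceeds the Nyquist bound of ", nyq, " for n = ", n)
  }
  B <- fourier_basis(n)
  nm <- colnames(B)
  freq <- numeric(length(nm))
  pair <- grepl("^(cos|sin)", nm)
  freq[pair] <- as.numeric(sub("^(cos|sin)", "", nm[pair]))
  freq[nm == "alt"] <- nyq
  keep <- if (full) freq > 0 else freq > 0 & freq <= n_freq
  B <- B[, keep, drop = FALSE]
  X <- cbind(B * I, B * S_prev)
  new_design_matrix(X,
                    c(paste0("I_", colnames(B)), paste0("S_", colnames(B))),
                    seq_len(n), "fourier")
}

#' Lag a spike indicator by one sample
#'
#' @param S 0/1 spike indicator.
#' @return `S_prev` with `S_prev[t] = S[t-1]` and `S_prev[1] = 0`.
#' @export
lag_indicator <- function(S) c(0, S[-length(S)])

#' Raised-cosine temporal basis
#'
#' `k` half-period cosine bumps with log-stretched centers covering
#' `t = 1..n`: with `phi(t) = log(t + psi)`, bump `j` is
#' `0.5 (1 + cos(pi (phi - c_j) / (2 delta)))` on `|phi - c_j| <= 2 delta`
#' and 0 outside, where the centers `c_j` are equally spaced by `delta` in
#' the stretched coordinate.  Neighbouring bumps overlap so that their sum
#' is constant on the interior of the span.
#'
#' @param n sample count.
#' @param k number of bumps (>= 1).
#' @param psi log-stretch offset in samples (> 0); small values concentrate
#'   bumps at early times.  Default `n / 50`.
#' @return `n x k` matrix of bump values.
#' @export
raised_cosine_basis <- function(n, k, psi = n / 50) {
  stopifnot(k >= 1, psi > 0, n >= 2)
  phi <- log(seq_len(n) + psi)
  lo <- phi[1]; hi <- phi[n]
  if (k == 1) {
    centers <- (lo + hi) / 2
    delta <- (hi - lo) / 2
  } else {
    delta <- (hi - lo) / (k + 3)   # support 4*delta; ends anchored inside
    centers <- seq(lo + 2 * delta, hi - 2 * delta, length.out = k)
  }
  B <- vapply(centers, function(cj) {
    x <- (phi - cj) / (2 * delta)
    ifelse(abs(x) <= 1, 0.5 * (1 + cos(pi * x)), 0)
  }, numeric(n))
  colnames(B) <- paste0("rc", seq_len(k))
  B
}

#' Raised-cosine feature design
#'
#' Expands the injected-current and lagged-spike-history channels in
#' raised-cosine bumps: each column is a bump multiplied elementwise with a
#' channel, `k_I + k_S` columns in total.
#'
#' @param I injected-current sequence.
#' @param S_prev spike indicator lagged by one sample.
#' @param k_bumps total number of bumps over the two channels, or a length-2
#'   vector `c(k_I, k_S)`.  An odd total is split as `ceiling/floor`.
#' @param psi log-stretch offset passed to [raised_cosine_basis()].
#' @return a `design_matrix` covering all n samples.
#' @export
raised_cosine_design <- function(I, S_prev, k_bumps, psi = length(I) / 50) {
  n <- length(I)
  stopifnot(length(S_prev) == n)
  if (length(k_bumps) == 1) {
    stopifnot(k_bumps >= 2)
    k_bumps <- c(ceiling(k_bumps / 2), floor(k_bumps / 2))
  }
  Bi <- raised_cosine_basis(n, k_bumps[1], psi)
  Bs <- raised_cosine_basis(n, k_bumps[2], psi)
  X <- cbind(Bi * I, Bs * S_prev)
  new_design_matrix(X,
                    c(paste0("I_", colnames(Bi)), paste0("S_", colnames(Bs))),
                    seq_len(n), "raised-cosine")
}

#' Principal-component design from a lagged design
#'
#' Centers the columns of a lagged design and projects onto the first `k`
#' principal components (ordered by explained variance).  The cumulative
#' explained-variance fraction is attached as attribute
#' `"explained_variance"`.
#'
#' @param lagged a `design_matrix` from [lagged_design()].
#' @param k number of components, `1 <= k <= min(dim)`.
#' @return a `design_matrix` with columns `PC1..PCk`.
#' @export
pca_design <- function(lagged, k) {
  stopifnot(inherits(lagged, "design_matrix"))
  X <- lagged$X
  rk <- min(nrow(X) - 1L, ncol(X))
  if (k < 1 || k > rk)
    stop("k must lie in 1..", rk, " (rank bound of the lagged design)")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = k)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  ev <- pc$sdev^2
  out <- new_design_matrix(scores, paste0("PC", seq_len(k)),
                           lagged$target_rows, "pca")
  attr(out, "explained_variance") <- cumsum(ev)[seq_len(k)] / sum(ev)
  out
}
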