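#' Stationary covariance of a first-order autoregressive network
#'
#' The lag-tau empirical Phi works on the generative model
#' `X_t = X_{t-1} %*% A1 + E_t` (row-vector convention, so the same
#' column-normalized connection matrix drives both Phi measures), with
#' `E_t` stationary Gaussian noise of covariance `noise_cov` (identity
#' by default) and vanishing autocovariance.  The stationary covariance
#' solves the discrete Lyapunov equation
#' `S = t(A1) S A1 + noise_cov`.
#'
#' @param a1 connection matrix acting at lag 1; spectral radius < 1.
#' @param noise_cov innovation covariance (default identity).
#' @return symmetric positive-definite stationary covariance.
#' @export
ar1_stationary_cov <- function(a1, noise_cov = diag(nrow(a1))) {
  n <- nrow(a1)
  stopifnot(ncol(a1) == n, all(dim(noise_cov) == n))
  rho <- max(Mod(eigen(a1, only.values = TRUE)$values))
  if (rho >= 1) {
    stop("non-stationary system: spectral radius ", format(rho), " >= 1",
         call. = FALSE)
  }
  s <- dlyap(t(a1), noise_cov)
  (s + t(s)) / 2
}

#' Lag-tau cross-covariance of the AR(1) network
#'
#' `cov(X_{t-tau}, X_t) = S %*% A1^tau` under the row-vector
#' convention (`S` the stationary covariance): rows index the past
#' state, columns the present.
#'
#' @inheritParams ar1_stationary_cov
#' @param tau positive integer lag.
#' @param sigma optional precomputed stationary covariance.
#' @return `n x n` cross-covariance matrix.
#' @export
ar1_lagged_cov <- function(a1, tau = 1, noise_cov = diag(nrow(a1)),
                           sigma = NULL) {
  stopifnot(tau >= 1, tau == floor(tau))
  if (is.null(sigma)) sigma <- ar1_stationary_cov(a1, noise_cov)
  m_tau <- t(a1)
  if (tau > 1) for (i in seq_len(tau - 1)) m_tau <- m_tau %*% t(a1)
  sigma %*% t(m_tau)
}

# 0.5 * log det via Cholesky (shared by the empirical-Phi formulas)
half_logdet_chol <- function(s) {
  sum(log(diag(chol((s + t(s)) / 2))))
}

# 0.5*log[det S / det cov(past | present)] for the block `idx`, given
# stationary covariance `sigma` and lag cross-covariance `p`
conditional_term <- function(sigma, p, idx) {
  ss <- sigma[idx, idx, drop = FALSE]
  pp <- p[idx, idx, drop = FALSE]
  cond <- ss - pp %*% solve(ss, t(pp))
  half_logdet_chol(ss) - half_logdet_chol(cond)
}

#' Empirical effective information across a bipartition
#'
#' The lag-tau effective information of Barrett and Seth for a
#' stationary Gaussian system: the information the present state
#' carries about the state tau steps back, minus the same quantity
#' computed within each part on its own,
#' `EI = 0.5 log[det cov(X) / det cov(X_{t-tau} | X_t)] -
#'  sum_k 0.5 log[det cov(M_k) / det cov(M_k,t-tau | M_k,t)]`,
#' with conditional covariances via Schur complements.  The
#' normalization factor is `K = min_k H(M_k)`, the smaller part
#' entropy.
#'
#' @inheritParams ar1_stationary_cov
#' @param m1,m2 index vectors forming a bipartition of `1:nrow(a1)`.
#' @param tau integer lag.
#' @return list with `ei` (nats) and `k_norm`.
#' @export
ei_empirical <- function(a1, m1, m2, tau = 1, noise_cov = diag(nrow(a1))) {
  n <- nrow(a1)
  if (!setequal(c(m1, m2), seq_len(n)) || length(intersect(m1, m2)) > 0) {
    stop("`m1` and `m2` must partition 1:", n, call. = FALSE)
  }
  sigma <- ar1_stationary_cov(a1, noise_cov)
  p <- ar1_lagged_cov(a1, tau, sigma = sigma)
  ei_empirical_from_cov(sigma, p, m1, m2)
}

# core formula on (stationary covariance, lagged cross-covariance); the
# split lets simulation-estimated covariances reuse the same code path
ei_empirical_from_cov <- function(sigma, p, m1, m2) {
  n <- nrow(sigma)
  whole <- conditional_term(sigma, p, seq_len(n))
  t1 <- conditional_term(sigma, p, m1)
  t2 <- conditional_term(sigma, p, m2)
  h1 <- 0.5 * length(m1) * log(2 * pi * exp(1)) +
        half_logdet_chol(sigma[m1, m1, drop = FALSE])
  h2 <- 0.5 * length(m2) * log(2 * pi * exp(1)) +
        half_logdet_chol(sigma[m2, m2, drop = FALSE])
  list(ei = whole - t1 - t2, k_norm = min(h1, h2))
}

# minimize EI/K over all whole-system bipartitions for given
# (sigma, p); returns ei at the MIB plus the cut
phi_empirical_from_cov <- function(sigma, p) {
  n <- nrow(sigma)
  # per-subset quantities; bipartitions combine a subset and complement
  n_bi <- 2^(n - 1) - 1
  best <- NULL
  term_cache <- new.env(parent = emptyenv())
  subset_term <- function(idx) {
    key <- paste(idx, collapse = ",")
    v <- term_cache[[key]]
    if (is.null(v)) {
      v <- list(
        t = conditional_term(sigma, p, idx),
        h = 0.5 * length(idx) * log(2 * pi * exp(1)) +
            half_logdet_chol(sigma[idx, idx, drop = FALSE]))
      term_cache[[key]] <- v
    }
    v
  }
  whole <- conditional_term(sigma, p, seq_len(n))
  for (t in 0:(n_bi - 1)) {
    mask <- c(TRUE, as.logical(bitwAnd(t, 2^(seq_len(n - 1) - 1)) > 0))
    m1 <- which(mask)
    m2 <- which(!mask)
    s1 <- subset_term(m1)
    s2 <- subset_term(m2)
    ei <- whole - s1$t - s2$t
    k_norm <- min(s1$h, s2$h)
    score <- ei / k_norm
    if (is.null(best) || score < best$score) {
      best <- list(score = score, ei = ei, k_norm = k_norm,
                   m1 = m1, m2 = m2)
    }
  }
  best
}

#' Lag-tau empirical Phi of a stationary Gaussian network
#'
#' For each requested lag, minimizes the normalized empirical effective
#' information `EI/K` over all whole-system bipartitions; Phi at that
#' lag is the unnormalized EI at the minimizing cut.  The sum over the
#' requested lags is reported alongside the per-lag values.
#'
#' @inheritParams ar1_stationary_cov
#' @param taus integer lags to evaluate (default 1:4).
#' @param max_n refuse systems larger than this (bipartition count
#'   doubles per node).
#' @return object of class `"phi_empirical_result"`: list with
#'   `per_tau` (named numeric vector of Phi values), `mib` (list of
#'   cuts per lag), `k_norm` per lag, and `phi_sum`.
#' @examples
#' a1 <- normalize_columns(rbind(c(0, 1), c(1, 0)), 0.5)
#' phi_empirical(a1, taus = 1)
#' @export
phi_empirical <- function(a1, taus = 1:4, noise_cov = diag(nrow(a1)),
                          max_n = 16) {
  n <- nrow(a1)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  if (n > max_n) {
    stop("bipartition search refused for n = ", n, " > max_n = ", max_n,
         call. = FALSE)
  }
  sigma <- ar1_stationary_cov(a1, noise_cov)
  per_tau <- numeric(length(taus))
  names(per_tau) <- paste0("tau", taus)
  mib <- vector("list", length(taus))
  names(mib) <- names(per_tau)
  k_norm <- per_tau
  for (i in seq_along(taus)) {
    p <- ar1_lagged_cov(a1, taus[i], sigma = sigma)
    best <- phi_empirical_from_cov(sigma, p)
    per_tau[i] <- best$ei
    k_norm[i] <- best$k_norm
    mib[[i]] <- list(m1 = best$m1, m2 = best$m2)
  }
  structure(list(per_tau = per_tau, mib = mib, k_norm = k_norm,
                 phi_sum = sum(per_tau), taus = taus),
            class = "phi_empirical_result")
}

#' @export
print.phi_empirical_result <- function(x, ...) {
  cat("Empirical Phi (nats)\n")
  for (i in seq_along(x$per_tau)) {
    cat(sprintf("  tau = %d: Phi = %g  MIB {%s} | {%s}\n", x$taus[i],
                x$per_tau[i], paste(x$mib[[i]]$m1, collapse = " "),
                paste(x$mib[[i]]$m2, collapse = " ")))
  }
  cat("  sum over lags:", format(x$phi_sum), "\n")
  invisible(x)
}

#' Simulate the AR(1) network dynamics
#'
#' Draws a trajectory of the generative recursion
#' `X_t = X_{t-1} %*% A1 + E_t` after a burn-in, for use as a
#' Monte-Carlo cross-check of the analytic covariances.
#'
#' @inheritParams ar1_stationary_cov
#' @param steps number of retained time steps.
#' @param burn_in discarded initial steps.
#' @return `steps x n` matrix of states (rows = time).
#' @export
simulate_ar1 <- function(a1, steps = 10000, burn_in = 500,
                         noise_cov = diag(nrow(a1))) {
  n <- nrow(a1)
  ch <- chol(noise_cov)
  x <- numeric(n)
  out <- matrix(0, steps, n)
  m <- t(a1)
  for (t in seq_len(burn_in + steps)) {
    x <- as.vector(m %*% x) + as.vector(crossprod(ch, stats::rnorm(n)))
    if (t > burn_in) out[t - burn_in, ] <- x
  }
  out
}
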