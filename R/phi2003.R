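#' Stationary covariance of the linear Gaussian network dynamics
#'
#' The activity row vector F of a system with normalized connection
#' matrix `con` (rows = outputs, columns = inputs) evolves as
#' `F <- F %*% con + c * R`, with `R` unit Gaussian noise and `c` the
#' per-node noise magnitudes.  Two solutions for the stationary
#' covariance are provided:
#'
#' * `"reference"` (default): the closed form of the original 2003
#'   integrated-information toolbox, `Q = (I - con)^-1`,
#'   `COV = t(Q) diag(c^2) Q`.  This treats the noise as held fixed
#'   while the activity settles to its fixed point.  The derivation was
#'   later shown not to be the stationary covariance of the time-stepped
#'   recursion, but it is the quantity the 2003 Phi literature computes,
#'   so it is reproduced deliberately and used by default.
#' * `"corrected"`: the discrete-Lyapunov solution of the time-stepped
#'   recursion, `S = t(con) S con + diag(c^2)`, for sensitivity
#'   analyses.
#'
#' @param con square connection matrix with spectral radius < 1.
#' @param noise per-node noise magnitudes (standard deviations);
#'   recycled to length `n`.
#' @param mode `"reference"` or `"corrected"`.
#' @return symmetric positive-definite covariance matrix.
#' @export
stationary_covariance <- function(con, noise = 1,
                                  mode = c("reference", "corrected")) {
  mode <- match.arg(mode)
  n <- nrow(con)
  stopifnot(ncol(con) == n)
  rho <- max(Mod(eigen(con, only.values = TRUE)$values))
  if (rho >= 1) {
    stop("non-stationary system: spectral radius ", format(rho), " >= 1",
         call. = FALSE)
  }
  noise <- rep_len(noise, n)
  if (mode == "reference") {
    imc <- diag(n) - con
    rc <- rcond(imc)
    if (rc < .Machine$double.eps * 100) {
      stop("(I - con) numerically singular; reciprocal condition number ",
           format(rc), call. = FALSE)
    }
    q <- solve(imc)
    cov <- crossprod(noise * q)          # t(Q) diag(noise^2) Q
  } else {
    cov <- dlyap(t(con), diag(noise^2, n))
  }
  (cov + t(cov)) / 2
}

# discrete Lyapunov: S = M S t(M) + V, solved by vectorization
dlyap <- function(m, v) {
  n <- nrow(m)
  s <- solve(diag(n * n) - kronecker(m, m), as.vector(v))
  matrix(s, n, n)
}

#' Differential entropy of a multivariate Gaussian
#'
#' `H = 0.5 * ln((2 pi e)^n det(cov))` in nats.  The determinant is
#' taken in log space through a Cholesky factorization, which keeps the
#' severely scaled covariances produced by tiny intrinsic noise
#' (variances near 1e-10) well behaved.
#'
#' @param cov symmetric positive-definite covariance matrix.
#' @return entropy in nats.
#' @examples
#' gaussian_entropy(matrix(1)) # 0.5 * log(2 * pi * exp(1))
#' @export
gaussian_entropy <- function(cov) {
  cov <- as.matrix(cov)
  ch <- tryCatch(chol(cov), error = function(e) {
    ev <- min(eigen((cov + t(cov)) / 2, only.values = TRUE)$values)
    stop("covariance not positive definite (smallest eigenvalue ",
         format(ev), ")", call. = FALSE)
  })
  n <- nrow(cov)
  0.5 * n * log(2 * pi * exp(1)) + sum(log(diag(ch)))
}

#' Gaussian mutual information between two node groups
#'
#' `MI(A : B) = H(A) + H(B) - H(A, B)` from the marginal blocks of a
#' joint covariance matrix.
#'
#' @param cov joint covariance matrix.
#' @param a,b disjoint index vectors into `cov`.
#' @return mutual information in nats (symmetric in `a`, `b`).
#' @export
gaussian_mutual_information <- function(cov, a, b) {
  if (length(intersect(a, b)) > 0) stop("`a` and `b` must be disjoint",
                                        call. = FALSE)
  ab <- c(a, b)
  gaussian_entropy(cov[a, a, drop = FALSE]) +
    gaussian_entropy(cov[b, b, drop = FALSE]) -
    gaussian_entropy(cov[ab, ab, drop = FALSE])
}

#' Directional effective information EI(A -> B)
#'
#' The mutual information between A and B when the elements of A are
#' driven by independent maximum-variance perturbation noise (magnitude
#' `cp`) while B keeps only its intrinsic noise (magnitude `ci`): the
#' stationary covariance is recomputed with that noise assignment and
#' `MI(A : B)` evaluated on it.  `{a, b}` must partition the rows of
#' `con`; analyze a subset by passing the induced submatrix.
#'
#' @param con connection matrix of the (sub)system under analysis.
#' @param a,b index vectors partitioning `1:nrow(con)`.
#' @param cp perturbation-noise magnitude applied to `a`.
#' @param ci intrinsic-noise magnitude applied to `b`.
#' @inheritParams stationary_covariance
#' @return effective information A -> B in nats.
#' @export
effective_information <- function(con, a, b, cp = 1, ci = 1e-5,
                                  mode = c("reference", "corrected")) {
  mode <- match.arg(mode)
  n <- nrow(con)
  if (!setequal(c(a, b), seq_len(n)) || length(intersect(a, b)) > 0) {
    stop("`a` and `b` must partition 1:", n, call. = FALSE)
  }
  noise <- numeric(n)
  noise[a] <- cp
  noise[b] <- ci
  cov <- stationary_covariance(con, noise, mode = mode)
  gaussian_mutual_information(cov, a, b)
}

#' Minimum information bipartition of a node subset
#'
#' Enumerates all `2^(k-1) - 1` unordered bipartitions {A, B} of the
#' subset, scores each by the normalized bidirectional effective
#' information `EI(A <-> B) / min(Hmax(A), Hmax(B))` where
#' `EI(A <-> B) = EI(A -> B) + EI(B -> A)` and
#' `Hmax(A) = |A| * 0.5 * ln(2 pi e cp^2)` is the maximum entropy
#' available to A under the perturbation noise, and returns the
#' minimizing cut.  Phi for the subset is the *unnormalized* EI at that
#' cut.  Ties resolve to the first bipartition in mask order (part A
#' biased toward low node indices), making the output deterministic.
#'
#' @param con connection matrix of the full system.
#' @param subset node indices to analyze (default: all); the induced
#'   subsystem `con[subset, subset]` is used.
#' @inheritParams effective_information
#' @param use_cpp use the compiled search kernel (identical result;
#'   the pure-R path exists for cross-checking).
#' @return object of class `"phi_result"`: list with `subset`,
#'   `part_a`, `part_b` (node ids in the original system), `ei`
#'   (unnormalized, nats), `ei_normalized`, and `phi = ei`.
#' @export
minimum_information_bipartition <- function(con, subset = seq_len(nrow(con)),
                                            cp = 1, ci = 1e-5,
                                            mode = c("reference", "corrected"),
                                            use_cpp = TRUE) {
  mode <- match.arg(mode)
  k <- length(subset)
  if (k < 2) stop("subset must contain at least 2 nodes", call. = FALSE)
  cs <- con[subset, subset, drop = FALSE]
  if (use_cpp) {
    r <- phi_mib_cpp(cs, cp, ci, mode == "corrected")
    a_loc <- which(r$a_mask == 1)
  } else {
    hmax1 <- 0.5 * log(2 * pi * exp(1) * cp^2)
    best <- NULL
    for (t in 0:(2^(k - 1) - 2)) {
      a_mask <- c(TRUE, as.logical(bitwAnd(t, 2^(seq_len(k - 1) - 1)) > 0))
      a <- which(a_mask)
      b <- which(!a_mask)
      ei <- effective_information(cs, a, b, cp, ci, mode) +
            effective_information(cs, b, a, cp, ci, mode)
      norm <- ei / (min(length(a), length(b)) * hmax1)
      if (is.null(best) || norm < best$norm) {
        best <- list(a = a, b = b, ei = ei, norm = norm)
      }
    }
    r <- list(ei = best$ei, ei_norm = best$norm)
    a_loc <- best$a
  }
  structure(list(subset = subset,
                 part_a = subset[a_loc],
                 part_b = setdiff(subset, subset[a_loc]),
                 ei = r$ei, ei_normalized = r$ei_norm, phi = r$ei),
            class = "phi_result")
}

#' 2003 integrated information of a system
#'
#' Phi of a subset is the unnormalized effective information at its
#' minimum information bipartition; the system's information capacity
#' is the maximum Phi over all subsets of size >= 2 (the default
#' `search = "subsets"`).  `search = "whole"` skips the subset scan and
#' analyzes the full system only.  The cost grows roughly like 3^n, so
#' the search refuses systems above `max_n` nodes.
#'
#' @inheritParams minimum_information_bipartition
#' @param search `"subsets"` (maximize over all subsets) or `"whole"`.
#' @param max_n refuse the subset search beyond this size (default 12).
#' @return `"phi_result"` for the winning subset.
#' @examples
#' con <- normalize_columns(rbind(c(0, 1), c(1, 0)), 0.5)
#' phi_2003(con)
#' @export
phi_2003 <- function(con, cp = 1, ci = 1e-5,
                     mode = c("reference", "corrected"),
                     search = c("subsets", "whole"),
                     max_n = 12, use_cpp = TRUE) {
  mode <- match.arg(mode)
  search <- match.arg(search)
  n <- nrow(con)
  validate_digraph(con, weighted = TRUE)
  if (search == "whole" || n == 2) {
    return(minimum_information_bipartition(con, seq_len(n), cp, ci, mode,
                                           use_cpp = use_cpp))
  }
  if (n > max_n) {
    stop("subset search refused for n = ", n, " > max_n = ", max_n,
         ": cost ~ ", format(3^n, big.mark = ","),
         " bipartition evaluations; raise `max_n` deliberately or use ",
         "search = \"whole\"", call. = FALSE)
  }
  best <- NULL
  for (size in 2:n) {
    combs <- utils::combn(n, size)
    for (j in seq_len(ncol(combs))) {
      r <- minimum_information_bipartition(con, combs[, j], cp, ci, mode,
                                           use_cpp = use_cpp)
      if (is.null(best) || r$phi > best$phi) best <- r
    }
  }
  best
}

#' @export
print.phi_result <- function(x, ...) {
  cat("2003 Phi result\n")
  cat("  subset:", paste(x$subset, collapse = " "), "\n")
  cat("  MIB:   {", paste(x$part_a, collapse = " "), "} | {",
      paste(x$part_b, collapse = " "), "}\n")
  cat("  EI (unnormalized):", format(x$ei), "nats\n")
  cat("  EI (normalized):  ", format(x$ei_normalized), "\n")
  cat("  Phi:", format(x$phi), "nats\n")
  invisible(x)
}
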