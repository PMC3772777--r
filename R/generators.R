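#' Bernoulli random weighted digraph
#'
#' Every off-diagonal cell independently receives weight `weight` with
#' probability `p` and zero otherwise.  This is the scheme used to
#' compare Average Connectedness with SD during measure development.
#'
#' @param n number of nodes (>= 2).
#' @param p connection probability, strictly between 0 and 1 at the
#'   defaults of interest (0 and 1 are allowed as degenerate limits).
#' @param weight weight assigned to present connections.
#' @return weighted adjacency matrix (zero diagonal).
#' @export
gen_bernoulli <- function(n, p = 0.5, weight = 0.5) {
  stopifnot(n >= 2, p >= 0, p <= 1)
  m <- matrix(0, n, n)
  off <- which(row(m) != col(m))
  m[off] <- weight * (stats::runif(length(off)) < p)
  m
}

#' Fixed-column-count normalized random digraph
#'
#' One count `c` is drawn uniformly from `1..n-1` per matrix; every
#' column then receives exactly `c` nonzero entries at uniformly random
#' off-diagonal positions, each of weight `k/c`.  Every nonzero column
#' therefore sums to `k` and the matrix is already normalized
#' (binarize-then-normalize returns it unchanged), while carrying a
#' single weight value.
#'
#' @param n number of nodes (>= 2).
#' @param k column normalization constant, `0 < k < 1`.
#' @return weighted adjacency matrix whose columns each sum to `k`, with
#'   attribute `"c"` recording the per-column connection count.
#' @export
gen_fixed_column <- function(n, k = 0.5) {
  stopifnot(n >= 2, k > 0, k < 1)
  cc <- sample.int(n - 1L, 1L)
  m <- matrix(0, n, n)
  for (j in seq_len(n)) {
    rows <- setdiff(seq_len(n), j)
    m[rows[sample.int(length(rows), cc)], j] <- k / cc
  }
  attr(m, "c") <- cc
  m
}

#' Uniform-over-density random binary digraph
#'
#' Draws a target density `u ~ Uniform(0, 1)`, then adds distinct
#' off-diagonal edges one at a time in uniformly random order until the
#' density reaches or just exceeds `u`.  The resulting density is
#' `ceiling(u * M) / M` with `M = n^2 - n`, i.e. (almost) uniform on
#' (0, 1].  Output is unweighted.
#'
#' @param n number of nodes (>= 2).
#' @return binary adjacency matrix with attribute `"target_density"`.
#' @export
gen_uniform_density <- function(n) {
  stopifnot(n >= 2)
  u <- stats::runif(1)
  m <- matrix(0, n, n)
  off <- which(row(m) != col(m))
  n_edges <- min(length(off), ceiling(u * length(off)))
  m[off[sample.int(length(off), n_edges)]] <- 1
  attr(m, "target_density") <- u
  m
}

#' Column-normalize a connection matrix
#'
#' Rescales each column so it sums to the constant `k < 1`:
#' `C[i, j] = k * A[i, j] / colsum(j)`.  Normalization separates weight
#' magnitude from structure and guarantees stationarity of the linear
#' Gaussian dynamics used by the Phi measures (spectral radius < 1).
#' Zero columns are left zero.
#'
#' @param adj binary or weighted adjacency matrix.
#' @param k normalization constant, `0 < k < 1`.
#' @return weighted matrix whose nonzero columns each sum to `k`.
#' @export
normalize_columns <- function(adj, k = 0.5) {
  stopifnot(k > 0, k < 1)
  validate_digraph(adj, weighted = TRUE)
  cs <- colSums(adj)
  scale <- ifelse(cs > 0, k / cs, 0)
  sweep(adj, 2, scale, `*`)
}

#' Sample a population of random weakly connected digraphs
#'
#' Repeatedly draws candidate graphs from one of the three generation
#' schemes and applies the detection filters: candidates that are not
#' weakly connected, or that are isomorphic to any previously accepted
#' graph in the same population (when `reject_isomorphs`), are discarded
#' and regenerated.  Self-loops never occur by construction.  Isomorph
#' rejection hashes a canonical labeling of each accepted graph, so each
#' candidate costs one canonical-form computation rather than a pairwise
#' scan.
#'
#' @param n number of nodes.
#' @param count number of graphs to return.
#' @param scheme `"bernoulli"`, `"fixed_column"` or `"uniform_density"`.
#' @param seed optional integer seed; when given, the population is a
#'   pure function of `(n, count, scheme, parameters, seed)` and the
#'   caller's RNG state is untouched.
#' @param p Bernoulli connection probability.
#' @param k normalization constant for the fixed-column scheme.
#' @param reject_isomorphs discard candidates isomorphic to an already
#'   accepted graph.
#' @param require_weak_connectivity discard candidates that are not
#'   weakly connected.
#' @param max_attempts rejection budget; exceeding it raises an error
#'   naming the attempts made (this happens when more non-isomorphic
#'   graphs are requested than exist at small `n`).
#' @return list of `count` adjacency matrices.
#' @examples
#' pop <- sample_population(5, 10, scheme = "fixed_column", seed = 1)
#' all(vapply(pop, is_weakly_connected, logical(1)))
#' @export
sample_population <- function(n, count,
                              scheme = c("fixed_column", "bernoulli",
                                         "uniform_density"),
                              seed = NULL, p = 0.5, k = 0.5,
                              reject_isomorphs = TRUE,
                              require_weak_connectivity = TRUE,
                              max_attempts = max(10000L, 100L * count)) {
  scheme <- match.arg(scheme)
  stopifnot(count >= 1)
  draw <- switch(scheme,
    bernoulli       = function() gen_bernoulli(n, p = p),
    fixed_column    = function() gen_fixed_column(n, k = k),
    uniform_density = function() gen_uniform_density(n)
  )
  run <- function() {
    accepted <- vector("list", count)
    seen <- new.env(parent = emptyenv())
    n_acc <- 0L
    attempts <- 0L
    while (n_acc < count) {
      if (attempts >= max_attempts) {
        stop("rejection budget exhausted: ", attempts, " attempts yielded ",
             n_acc, " of ", count, " requested graphs (n = ", n,
             ", scheme = ", scheme, ")", call. = FALSE)
      }
      attempts <- attempts + 1L
      g <- draw()
      if (require_weak_connectivity && !is_weakly_connected(g)) next
      if (reject_isomorphs) {
        key <- canonical_key(g)
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
      }
      n_acc <- n_acc + 1L
      accepted[[n_acc]] <- g
    }
    accepted
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
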