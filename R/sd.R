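#' Non-overlap (symmetric-difference size) of two node sets
#'
#' The numerator of the Jaccard distance: the number of elements in the
#' union that are not in the intersection, `|A U B| - |A n B|`.
#'
#' @param a,b vectors of node ids (treated as sets).
#' @return nonnegative integer.
#' @examples
#' non_overlap(c(1, 2), c(2, 3)) # 2
#' @export
non_overlap <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  length(union(a, b)) - length(intersect(a, b))
}

#' System Difference, set formulation
#'
#' SD measures node specialization as the average difference in
#' connection pattern over all unordered node pairs.  Each node `x`
#' carries an output set `Out(x)` (successors) and an input set `In(x)`
#' (predecessors); SD sums the non-overlap of the output sets and of the
#' input sets over all pairs `a < b` and divides by the `n(n-1)/2`
#' comparisons.
#'
#' @param adj adjacency matrix (weighted matrices are binarized: SD reads
#'   only the zero/nonzero pattern).
#' @return nonnegative number in `[0, n^2/(n-1)]`.
#' @seealso [sd_degree_form()] for the equivalent O(n^2) formulation.
#' @export
sd_set_form <- function(adj) {
  b <- binarize(adj)
  n <- nrow(b)
  if (n < 2) stop("SD undefined for n < 2", call. = FALSE)
  out_sets <- lapply(seq_len(n), function(i) which(b[i, ] > 0))
  in_sets  <- lapply(seq_len(n), function(j) which(b[, j] > 0))
  total <- 0L
  for (a in seq_len(n - 1L)) {
    for (bb in seq.int(a + 1L, n)) {
      total <- total + non_overlap(out_sets[[a]], out_sets[[bb]]) +
                       non_overlap(in_sets[[a]],  in_sets[[bb]])
    }
  }
  total / (n * (n - 1) / 2)
}

#' System Difference, degree formulation
#'
#' Algebraically identical to [sd_set_form()] but computed from the
#' degree distribution alone:
#' `SD = sum_t [ in(t)(n - in(t)) + out(t)(n - out(t)) ] / (n(n-1)/2)`.
#' The numerator is accumulated in exact integer arithmetic; the single
#' division happens last.
#'
#' @inheritParams sd_set_form
#' @return nonnegative number in `[0, n^2/(n-1)]`.
#' @examples
#' cyc <- matrix(0, 4, 4); cyc[cbind(1:4, c(2, 3, 4, 1))] <- 1
#' sd_degree_form(cyc) # 4
#' @export
sd_degree_form <- function(adj) {
  sd_numerator(adj) / (nrow(adj) * (nrow(adj) - 1) / 2)
}

# exact integer numerator shared by sd_degree_form() and the equivalence
# tests; sum_t in(t)(n-in(t)) + out(t)(n-out(t))
sd_numerator <- function(adj) {
  b <- binarize(adj)
  n <- nrow(b)
  if (n < 2) stop("SD undefined for n < 2", call. = FALSE)
  d <- in_out_degrees(b)
  sum(d$in_deg * (n - d$in_deg)) + sum(d$out_deg * (n - d$out_deg))
}

#' System Difference
#'
#' User-facing entry point; uses the degree formulation.
#'
#' @inheritParams sd_set_form
#' @return SD value.
#' @export
system_difference <- function(adj) sd_degree_form(adj)

#' Per-node contribution to System Difference
#'
#' The specialization contribution of a single node:
#' `in(t)(n - in(t)) + out(t)(n - out(t))`, maximized when both degrees
#' equal `n/2`.  Reported unnormalized by default; with
#' `normalized = TRUE` the value is divided by the `n(n-1)/2` pair count
#' so the per-node values sum to the graph SD.
#'
#' @inheritParams sd_set_form
#' @param t node index (1-based) or vector of indices; defaults to all
#'   nodes.
#' @param normalized divide by the number of pairwise comparisons.
#' @return numeric vector of per-node contributions.
#' @export
sd_node <- function(adj, t = seq_len(nrow(adj)), normalized = FALSE) {
  b <- binarize(adj)
  n <- nrow(b)
  if (any(t < 1L) || any(t > n) || any(t != floor(t))) {
    stop("node index out of range 1..", n, call. = FALSE)
  }
  d <- in_out_degrees(b)
  v <- d$in_deg[t] * (n - d$in_deg[t]) + d$out_deg[t] * (n - d$out_deg[t])
  if (normalized) v / (n * (n - 1) / 2) else v
}

#' Average Connectedness
#'
#' The mean of the transitive reachability matrix: the number of ordered
#' node pairs (i, j) such that j is reachable from i along a directed
#' path, divided by `n^2`.  Under the cycle-diagonal convention AC = 1
#' exactly for strongly connected graphs and AC = 0 for edgeless ones.
#'
#' @inheritParams sd_set_form
#' @param diag_cycles passed to [reachability_matrix()].
#' @return number in \[0, 1\].
#' @export
average_connectedness <- function(adj, diag_cycles = TRUE) {
  b <- binarize(adj)
  sum(reachability_matrix(b, diag_cycles = diag_cycles)) / nrow(b)^2
}
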