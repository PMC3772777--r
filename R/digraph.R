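#' Validate a directed-graph adjacency matrix
#'
#' All functions in sdnet represent a directed graph of `n` nodes as an
#' `n x n` matrix whose rows are outputs and whose columns are inputs:
#' `adj[i, j] != 0` means an edge from node `i` to node `j`.  Self-loops
#' (nonzero diagonal) are never allowed.  A *binary* digraph additionally
#' restricts entries to exactly 0 or 1; a *weighted* digraph allows any
#' nonnegative weights (e.g. a column-normalized connection matrix).
#'
#' @param adj square numeric matrix.
#' @param weighted if `FALSE` (default), entries must be exactly 0 or 1.
#' @return `adj`, invisibly, after validation.
#' @examples
#' validate_digraph(rbind(c(0, 1), c(0, 0)))
#' @export
validate_digraph <- function(adj, weighted = FALSE) {
  if (!is.matrix(adj) || !is.numeric(adj)) {
    stop("`adj` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(adj) != ncol(adj)) {
    stop("`adj` must be square; got ", nrow(adj), " x ", ncol(adj), call. = FALSE)
  }
  if (anyNA(adj)) stop("`adj` contains missing values", call. = FALSE)
  if (any(diag(adj) != 0)) {
    stop("self-loops are not allowed: nonzero diagonal at node(s) ",
         paste(which(diag(adj) != 0), collapse = ", "), call. = FALSE)
  }
  if (any(adj < 0)) stop("`adj` contains negative weights", call. = FALSE)
  if (!weighted && !all(adj %in% c(0, 1))) {
    stop("binary digraph required: entries must be exactly 0 or 1 ",
         "(use `binarize()` for weighted matrices)", call. = FALSE)
  }
  invisible(adj)
}

#' Binarize a weighted connection matrix
#'
#' Any strictly positive weight becomes an edge.  SD, AC and all graph
#' metrics read only the zero/nonzero pattern, so column normalization
#' never changes their values.
#'
#' @param adj square numeric matrix with zero diagonal.
#' @return 0/1 matrix of the same dimension.
#' @export
binarize <- function(adj) {
  validate_digraph(adj, weighted = TRUE)
  out <- (adj > 0) + 0
  dimnames(out) <- NULL
  out
}

#' In- and out-degrees of every node
#'
#' The in-degree of node `t` is the number of nonzero entries in column
#' `t` (its inputs); the out-degree is the row count (its outputs).
#'
#' @param adj adjacency matrix (weighted matrices are binarized first).
#' @return list with integer vectors `in_deg` and `out_deg`.
#' @examples
#' in_out_degrees(rbind(c(0, 1), c(0, 0)))
#' @export
in_out_degrees <- function(adj) {
  b <- binarize(adj)
  list(in_deg = as.integer(colSums(b)), out_deg = as.integer(rowSums(b)))
}

#' Connection density of a digraph
#'
#' Fraction of possible edges present.  Because self-loops are
#' structurally excluded, the denominator is `n^2 - n`, not `n^2`.
#'
#' @inheritParams in_out_degrees
#' @return number in \[0, 1\].
#' @export
connection_density <- function(adj) {
  b <- binarize(adj)
  n <- nrow(b)
  if (n < 2) stop("density undefined for n < 2", call. = FALSE)
  sum(b) / (n^2 - n)
}

#' Transitive reachability matrix
#'
#' `reach[i, j] = 1` iff a directed path of length >= 1 runs from `i` to
#' `j`.  Under this strict path definition the diagonal entry
#' `reach[i, i]` is 1 exactly when `i` lies on a directed cycle; set
#' `diag_cycles = FALSE` to force the diagonal to zero instead.
#'
#' @inheritParams in_out_degrees
#' @param diag_cycles keep cycle-induced self-reachability on the
#'   diagonal (default `TRUE`).
#' @return 0/1 matrix of the same dimension as `adj`.
#' @export
reachability_matrix <- function(adj, diag_cycles = TRUE) {
  b <- binarize(adj)
  n <- nrow(b)
  reach <- b
  # closure by repeated squaring: after k rounds covers paths up to 2^k
  for (i in seq_len(max(1L, ceiling(log2(max(n, 2L)))))) {
    nxt <- ((reach + reach %*% reach) > 0) + 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  if (!diag_cycles) diag(reach) <- 0
  reach
}

#' Weak connectivity test
#'
#' A directed graph is weakly connected when every node can reach every
#' other along paths that ignore edge direction.  A single node counts
#' as connected.
#'
#' @inheritParams in_out_degrees
#' @return `TRUE` or `FALSE`.
#' @export
is_weakly_connected <- function(adj) {
  b <- binarize(adj)
  if (nrow(b) == 1) return(TRUE)
  igraph::is_connected(as_igraph(b), mode = "weak")
}

#' Directed-graph isomorphism
#'
#' Two digraphs are isomorphic when a relabeling of the nodes of one
#' yields exactly the edge set of the other (VF2 exact test).
#'
#' @param a,b adjacency matrices of the same order.
#' @return `TRUE` or `FALSE`.
#' @export
are_isomorphic <- function(a, b) {
  ga <- as_igraph(binarize(a))
  gb <- as_igraph(binarize(b))
  if (igraph::vcount(ga) != igraph::vcount(gb) ||
      igraph::ecount(ga) != igraph::ecount(gb)) {
    return(FALSE)
  }
  igraph::isomorphic(ga, gb, method = "vf2")
}

#' Convert an adjacency matrix to an igraph object
#'
#' @inheritParams in_out_degrees
#' @return directed `igraph` graph.
#' @export
as_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(binarize(adj), mode = "directed")
}

# canonical-form string used to hash isomorphism classes (bliss canonical
# labeling; exact for directed graphs without self-loops)
canonical_key <- function(adj) {
  g <- as_igraph(adj)
  lab <- igraph::canonical_permutation(g)$labeling
  gc <- igraph::permute(g, lab)
  m <- igraph::as_adjacency_matrix(gc, sparse = FALSE)
  paste(as.integer(m), collapse = "")
}
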