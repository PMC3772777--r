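# Fixtures and independent oracles shared across the suite.

empty_adj <- function(n) matrix(0, n, n)

complete_adj <- function(n) {
  m <- matrix(1, n, n)
  diag(m) <- 0
  m
}

cycle_adj <- function(n) {
  m <- matrix(0, n, n)
  m[cbind(seq_len(n), c(seq_len(n)[-1], 1L))] <- 1
  m
}

chain_adj <- function(n) {
  m <- matrix(0, n, n)
  if (n > 1) m[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- 1
  m
}

edges_adj <- function(n, from, to) {
  m <- matrix(0, n, n)
  m[cbind(from, to)] <- 1
  m
}

random_adj <- function(n, p = 0.4) {
  m <- matrix(stats::rbinom(n * n, 1, p), n, n)
  diag(m) <- 0
  m
}

# breadth-first-search reachability oracle, independent of the
# matrix-closure implementation
bfs_reachability <- function(adj) {
  n <- nrow(adj)
  reach <- matrix(0, n, n)
  for (s in seq_len(n)) {
    frontier <- which(adj[s, ] > 0)
    visited <- logical(n)
    while (length(frontier)) {
      new <- frontier[!visited[frontier]]
      visited[new] <- TRUE
      frontier <- unique(unlist(lapply(new, function(v) which(adj[v, ] > 0))))
    }
    reach[s, visited] <- 1
  }
  reach
}

# brute-force motif census: classify every induced size-k subgraph by
# pairwise VF2 comparison (no canonical-class shortcut)
brute_motif_census <- function(adj, size) {
  n <- nrow(adj)
  reps <- list()
  counts <- integer(0)
  total <- 0L
  combs <- utils::combn(n, size)
  for (j in seq_len(ncol(combs))) {
    idx <- combs[, j]
    sub <- adj[idx, idx, drop = FALSE]
    if (!is_weakly_connected(sub)) next
    total <- total + 1L
    hit <- FALSE
    for (r in seq_along(reps)) {
      if (are_isomorphic(sub, reps[[r]])) {
        counts[r] <- counts[r] + 1L
        hit <- TRUE
        break
      }
    }
    if (!hit) {
      reps[[length(reps) + 1L]] <- sub
      counts[length(reps)] <- 1L
    }
  }
  list(motif_number = total, class_sizes = sort(counts, decreasing = TRUE))
}

# all 3-node digraphs without self-loops, as adjacency matrices
all_triad_digraphs <- function() {
  cells <- rbind(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))
  lapply(0:63, function(bits) {
    m <- matrix(0, 3, 3)
    on <- which(bitwAnd(bits, 2^(0:5)) > 0)
    m[cells[on, , drop = FALSE]] <- 1
    m
  })
}

# permute node labels of an adjacency matrix
relabel_adj <- function(adj, perm) adj[perm, perm, drop = FALSE]
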