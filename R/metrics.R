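#' Maximum total degree
#'
#' The maximum over nodes of in-degree plus out-degree.
#'
#' @inheritParams in_out_degrees
#' @return integer.
#' @export
max_total_degree <- function(adj) {
  d <- in_out_degrees(adj)
  max(d$in_deg + d$out_deg)
}

#' Maximal-clique summary of a digraph
#'
#' Cliques are taken on the OR-symmetrized undirected graph: an edge in
#' either direction makes the pair adjacent.  All maximal cliques are
#' enumerated (Bron-Kerbosch) and summarized by omega (the largest
#' clique size), their number, and their mean size.
#'
#' @inheritParams in_out_degrees
#' @return list with `omega`, `n_maximal`, `avg_maximal_size`.
#' @export
clique_summary <- function(adj) {
  und <- igraph::as_undirected(as_igraph(adj), mode = "collapse")
  cl <- igraph::max_cliques(und)
  sizes <- lengths(cl)
  list(omega = max(sizes), n_maximal = length(sizes),
       avg_maximal_size = mean(sizes))
}

#' Average directed path length
#'
#' Mean geodesic distance over ordered node pairs `(a, b)`, `a != b`,
#' for which a directed path exists.  By default unreachable pairs are
#' excluded from the mean, matching the usual graph-library convention
#' for weakly (not strongly) connected graphs; `strict = TRUE` errors
#' when any pair is unreachable.
#'
#' @inheritParams in_out_degrees
#' @param strict error on unreachable pairs instead of dropping them.
#' @return mean geodesic distance; `NaN` with a warning for an edgeless
#'   graph.
#' @export
average_path_length <- function(adj, strict = FALSE) {
  d <- igraph::distances(as_igraph(adj), mode = "out")
  d <- d[row(d) != col(d)]
  if (strict && any(is.infinite(d))) {
    stop("graph has unreachable ordered pairs and `strict = TRUE`",
         call. = FALSE)
  }
  d <- d[is.finite(d)]
  if (length(d) == 0) {
    warning("no reachable pairs: average path length undefined")
    return(NaN)
  }
  mean(d)
}

#' Motif census of size 3 or 4
#'
#' Classifies every induced subgraph on `size` nodes by directed
#' isomorphism class and counts the weakly connected classes; their
#' total is the *motif number*.  Class identifiers follow igraph's
#' isomorphism-class numbering (0-based), the convention used throughout
#' the motif literature; disconnected classes are reported as `NA`
#' counts and excluded from the motif number.  Size 3 has exactly 13
#' weakly connected classes.
#'
#' @inheritParams in_out_degrees
#' @param size motif size, 3 or 4.
#' @return list with `size`, `class_counts` (named by 0-based class id,
#'   `NA` for disconnected classes) and `motif_number`.
#' @export
motif_census <- function(adj, size = 3) {
  stopifnot(size %in% c(3, 4))
  b <- binarize(adj)
  if (nrow(b) < size) stop("graph has fewer than ", size, " nodes", call. = FALSE)
  counts <- igraph::motifs(as_igraph(b), size)
  names(counts) <- as.character(seq_along(counts) - 1L)
  list(size = size, class_counts = counts,
       motif_number = sum(counts, na.rm = TRUE))
}

#' Density group of a size-3 motif class
#'
#' Weakly connected triads fall into four groups by edge count, which
#' is how their frequency trends against SD organize: group 1 holds the
#' 2- and 4-edge motifs (densities 1/3 and 2/3, equally far from 0.5),
#' group 2 the 3-edge motifs (density 0.5), group 3 the 5-edge motif,
#' group 4 the complete 6-edge triad.
#'
#' @param class_id 0-based igraph isomorphism-class id of a size-3
#'   directed motif.
#' @param size motif size; only 3 is defined.
#' @return integer group label in 1..4.
#' @export
motif_density_group <- function(class_id, size = 3) {
  if (size != 3) stop("density groups are defined for size-3 motifs only",
                      call. = FALSE)
  stopifnot(length(class_id) == 1, class_id >= 0, class_id <= 15)
  g <- igraph::graph_from_isomorphism_class(3, class_id, directed = TRUE)
  if (!igraph::is_connected(g, mode = "weak")) {
    stop("class ", class_id, " is not weakly connected; no density group",
         call. = FALSE)
  }
  e <- igraph::ecount(g)
  switch(as.character(e), "2" = 1L, "4" = 1L, "3" = 2L, "5" = 3L, "6" = 4L,
         stop("unexpected edge count ", e, call. = FALSE))
}

#' Compute a row of comparison metrics for one graph
#'
#' Convenience wrapper bundling the metrics SD is compared against.
#'
#' @inheritParams in_out_degrees
#' @param select character vector of metric names among `"sd"`, `"ac"`,
#'   `"density"`, `"max_degree"`, `"omega"`, `"n_maximal_cliques"`,
#'   `"avg_maximal_clique"`, `"avg_path_length"`, `"motif_number3"`,
#'   `"motif_number4"`.
#' @return one-row data frame.
#' @export
graph_metric_row <- function(adj, select = c("sd", "ac", "density",
                                             "max_degree", "omega",
                                             "avg_path_length")) {
  known <- c("sd", "ac", "density", "max_degree", "omega",
             "n_maximal_cliques", "avg_maximal_clique", "avg_path_length",
             "motif_number3", "motif_number4")
  bad <- setdiff(select, known)
  if (length(bad)) stop("unknown metric(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (length(select) == 0) stop("empty metric selection", call. = FALSE)
  cl <- if (any(c("omega", "n_maximal_cliques", "avg_maximal_clique")
                %in% select)) clique_summary(adj)
  vals <- lapply(select, function(m) {
    switch(m,
      sd = sd_degree_form(adj),
      ac = average_connectedness(adj),
      density = connection_density(adj),
      max_degree = max_total_degree(adj),
      omega = cl$omega,
      n_maximal_cliques = cl$n_maximal,
      avg_maximal_clique = cl$avg_maximal_size,
      avg_path_length = average_path_length(adj),
      motif_number3 = motif_census(adj, 3)$motif_number,
      motif_number4 = motif_census(adj, 4)$motif_number)
  })
  names(vals) <- select
  as.data.frame(vals)
}
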