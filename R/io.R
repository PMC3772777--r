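#' Read a directed graph from disk
#'
#' Supported formats:
#' * `adjacency`: header-less CSV/TSV of `n` rows by `n` numeric values,
#'   row = source node (the delimiter is sniffed);
#' * `edgelist`: two tab-separated columns with header
#'   `source<TAB>target`, 1-based node ids;
#' * `graphml`: GraphML interchange (edge attribute `weight` preserved
#'   when present).
#'
#' `format = "auto"` dispatches on the file extension (`.graphml`) or,
#' for text tables, on the presence of the edge-list header.  The
#' result always has a zero diagonal; a nonzero diagonal is rejected
#' with the offending line reported.
#'
#' @param path file to read.
#' @param format one of `"auto"`, `"adjacency"`, `"edgelist"`,
#'   `"graphml"`.
#' @return adjacency matrix (weights preserved; use [binarize()] for
#'   the 0/1 view).
#' @export
read_digraph <- function(path, format = c("auto", "adjacency", "edgelist",
                                          "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (ext == "graphml") {
      format <- "graphml"
    } else {
      first <- readLines(path, n = 1L)
      format <- if (grepl("^source[\t,]target$", first)) "edgelist"
                else "adjacency"
    }
  }
  adj <- switch(format,
    adjacency = read_adjacency(path),
    edgelist = read_edgelist(path),
    graphml = read_graphml(path))
  check_read_diagonal(adj, path)
  adj
}

check_read_diagonal <- function(adj, path) {
  bad <- which(diag(adj) != 0)
  if (length(bad)) {
    stop("self-loop in ", path, ": nonzero diagonal entry for node ",
         bad[1], " (line ", bad[1], ")", call. = FALSE)
  }
  validate_digraph(adj, weighted = TRUE)
}

read_adjacency <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  rows <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(rows)
  if (length(unique(widths)) != 1) {
    stop("ragged adjacency file ", path, ": line ",
         which(widths != widths[1])[1], " has ",
         widths[widths != widths[1]][1], " fields, expected ", widths[1],
         call. = FALSE)
  }
  m <- t(vapply(rows, function(r) as.numeric(r), numeric(widths[1])))
  if (anyNA(m)) stop("non-numeric entry in adjacency file ", path,
                     call. = FALSE)
  if (nrow(m) != ncol(m)) {
    stop("nonsquare adjacency in ", path, ": ", nrow(m), " rows x ",
         ncol(m), " columns", call. = FALSE)
  }
  dimnames(m) <- NULL
  m
}

read_edgelist <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          col.names = c("source", "target"))
  if (nrow(df) == 0) stop("empty edge list ", path, call. = FALSE)
  n <- max(df$source, df$target)
  m <- matrix(0, n, n)
  m[cbind(df$source, df$target)] <- 1
  m
}

read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  attr_name <- if ("weight" %in% igraph::edge_attr_names(g)) "weight" else NULL
  m <- igraph::as_adjacency_matrix(g, sparse = FALSE, attr = attr_name)
  dimnames(m) <- NULL
  m
}

#' Write a directed graph to disk
#'
#' @param adj adjacency matrix (binary or weighted).
#' @param path destination; with `format = "auto"` a `.graphml`
#'   extension selects GraphML, `.tsv` an edge list, anything else an
#'   adjacency CSV.
#' @inheritParams read_digraph
#' @return `path`, invisibly.
#' @export
write_digraph <- function(adj, path, format = c("auto", "adjacency",
                                                "edgelist", "graphml")) {
  format <- match.arg(format)
  validate_digraph(adj, weighted = TRUE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, graphml = "graphml", tsv = "edgelist", "adjacency")
  }
  if (format == "adjacency") {
    writeLines(apply(adj, 1, paste, collapse = ","), path)
  } else if (format == "edgelist") {
    idx <- which(adj > 0, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    writeLines(c("source\ttarget",
                 paste(idx[, 1], idx[, 2], sep = "\t")), path)
  } else {
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed",
                                             weighted = TRUE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Write experiment outputs as a reproducible bundle
#'
#' Writes `records.csv` and `fits.csv` (deterministic column order; a
#' header-only CSV for empty tables) plus `manifest.json` recording the
#' configuration, seed and package version, so a run can be
#' reconstructed from its manifest alone.
#'
#' @param result list as returned by the `run_*` experiment functions
#'   (elements `records` and, when present, `fits` / `correlations`).
#' @param outdir output directory (created if needed).
#' @param config named list recording the arguments of the run.
#' @return `outdir`, invisibly.
#' @export
write_experiment_results <- function(result, outdir, config = list()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$records, file.path(outdir, "records.csv"),
                   row.names = FALSE)
  fits <- result$fits
  if (is.null(fits)) fits <- result$correlations
  if (!is.null(fits)) {
    utils::write.csv(fits, file.path(outdir, "fits.csv"), row.names = FALSE)
  }
  manifest <- list(
    package = "sdnet",
    version = as.character(utils::packageVersion("sdnet")),
    config = config,
    extra = setdiff(names(result), c("records", "fits", "correlations")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
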