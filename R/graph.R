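#' Construct a simple directed graph
#'
#' Builds the directed-graph container used throughout the package: a binary
#' directed graph with no self-loops and at most one edge per ordered pair.
#' Internally graphs are `igraph` objects with named vertices.
#'
#' @param edges a two-column matrix or data frame of edges (source, target);
#'   entries are coerced to character node names. May have zero rows.
#' @param nodes optional character vector of node names; must contain every
#'   edge endpoint. Allows isolated nodes.
#' @return an `igraph` directed graph with a `name` vertex attribute.
#' @examples
#' g <- digraph(rbind(c("a", "b"), c("b", "c")))
#' igraph::vcount(g)
#' @export
digraph <- function(edges, nodes = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  }
  if (!is.matrix(edges) || ncol(edges) != 2L)
    stop("'edges' must be a two-column matrix or data frame")
  storage.mode(edges) <- "character"
  loops <- edges[, 1L] == edges[, 2L]
  if (any(loops))
    stop("self-loops are not allowed (found ", sum(loops), ", e.g. '",
         edges[which(loops)[1L], 1L], "')")
  key <- paste(edges[, 1L], edges[, 2L], sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated edges are not allowed (found ",
         sum(duplicated(key)), ")")
  all_nodes <- unique(c(edges[, 1L], edges[, 2L]))
  if (!is.null(nodes)) {
    nodes <- as.character(nodes)
    missing <- setdiff(all_nodes, nodes)
    if (length(missing))
      stop("edge endpoints not in 'nodes': ",
           paste(utils::head(missing, 5L), collapse = ", "))
    all_nodes <- nodes
  }
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, length(all_nodes), name = all_nodes)
  if (nrow(edges) > 0L)
    g <- igraph::add_edges(g, rbind(edges[, 1L], edges[, 2L]))
  g
}

#' Coerce to a simple directed graph
#'
#' Accepts an `igraph` object (checked to be directed, loop-free and without
#' multi-edges) or an edge table, and returns the validated graph.
#'
#' @param x an `igraph` graph or a two-column edge matrix/data frame.
#' @return an `igraph` directed graph with named vertices.
#' @export
as_digraph <- function(x) {
  if (igraph::is_igraph(x)) {
    if (!igraph::is_directed(x)) stop("graph must be directed")
    if (any(igraph::which_loop(x))) stop("self-loops are not allowed")
    if (any(igraph::which_multiple(x))) stop("multi-edges are not allowed")
    if (is.null(igraph::V(x)$name))
      igraph::V(x)$name <- as.character(seq_len(igraph::vcount(x)))
    return(x)
  }
  digraph(x)
}

edge_endpoints <- function(graph) {
  el <- igraph::as_edgelist(graph, names = TRUE)
  storage.mode(el) <- "character"
  el
}

#' Generalised agony penalty
#'
#' The per-edge cost \eqn{f_d(x) = (x+1)^d} for rank difference
#' \eqn{x = r(u) - r(v) \ge 0} (a backward or same-class link) and 0 for
#' \eqn{x < 0} (a forward link). The +1 makes same-class links cost
#' \eqn{f_d(0) = 1}, which is what keeps the trivial one-class ranking from
#' always being optimal.
#'
#' @param x integer rank differences (vectorised).
#' @param d penalty exponent, a single number `>= 0`.
#' @return numeric vector of penalties.
#' @examples
#' agony_penalty(c(-3, 0, 2), d = 1)
#' @export
agony_penalty <- function(x, d = 1) {
  check_d(d)
  ifelse(x >= 0, (x + 1)^d, 0)
}

check_d <- function(d) {
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 0)
    stop("'d' must be a single number >= 0")
  invisible(d)
}

#' Coerce to a ranking
#'
#' A ranking (ordered partition) is represented as a named integer vector
#' mapping node names to class indices. Accepts a named vector or a
#' two-column data frame (node, rank).
#'
#' @param x a named integer-valued vector, or a data frame whose first two
#'   columns are node name and rank.
#' @return named integer vector of ranks.
#' @export
as_ranking <- function(x) {
  if (is.data.frame(x)) {
    if (ncol(x) < 2L) stop("ranking data frame needs two columns")
    r <- as.integer(x[[2L]])
    names(r) <- as.character(x[[1L]])
    x <- r
  }
  if (is.null(names(x)) || any(names(x) == ""))
    stop("a ranking must be a named vector (names are node identifiers)")
  if (anyDuplicated(names(x)))
    stop("duplicated node names in ranking")
  if (any(is.na(x)) || any(x != round(x)))
    stop("ranks must be integers")
  r <- as.integer(round(x))
  names(r) <- names(x)
  r
}

#' Canonicalise a ranking
#'
#' Relabels classes to consecutive integers 1..R, preserving their order and
#' dropping empty class labels. For any penalty exponent the agony of the
#' canonicalised ranking is less than or equal to that of the input, since
#' removing empty levels can only shrink backward rank differences.
#'
#' @param r a ranking (see [as_ranking()]).
#' @return the canonicalised named integer ranking.
#' @examples
#' canonicalize_ranking(c(a = 2, b = 5, c = 5))
#' @export
canonicalize_ranking <- function(r) {
  r <- as_ranking(r)
  lev <- sort(unique(r))
  out <- match(r, lev)
  names(out) <- names(r)
  out
}

#' Number of classes and class sizes of a ranking
#'
#' @param r a ranking.
#' @return integer vector of class sizes named by the canonical class index.
#' @export
class_sizes <- function(r) {
  r <- canonicalize_ranking(r)
  tab <- tabulate(r)
  names(tab) <- seq_along(tab)
  tab
}

ranks_for_edges <- function(graph, ranking) {
  ranking <- as_ranking(ranking)
  el <- edge_endpoints(graph)
  ru <- ranking[el[, 1L]]
  rv <- ranking[el[, 2L]]
  missing <- unique(c(el[, 1L][is.na(ru)], el[, 2L][is.na(rv)]))
  if (length(missing))
    stop("no rank assigned to node(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  list(ru = unname(ru), rv = unname(rv), el = el)
}

#' Agony of a ranking on a graph
#'
#' The agony of graph `G` under ranking `r` is
#' \eqn{A_d(G, r) = \sum_{(u,v) \in E} f_d(r(u) - r(v))}: every backward or
#' same-class link is charged \eqn{(x+1)^d} where `x` is the rank drop.
#'
#' @param graph a directed graph (see [as_digraph()]).
#' @param ranking a ranking assigning a class to every node of `graph`.
#' @param d penalty exponent.
#' @return the non-negative agony value.
#' @examples
#' g <- digraph(rbind(c("a", "b"), c("b", "a")))
#' agony_value(g, c(a = 1, b = 2), d = 1)
#' @export
agony_value <- function(graph, ranking, d = 1) {
  graph <- as_digraph(graph)
  check_d(d)
  rk <- ranks_for_edges(graph, ranking)
  sum(agony_penalty(rk$ru - rk$rv, d))
}

#' Hierarchy of a ranking on a graph
#'
#' `1 - agony/m`. Equals 1 for a perfect hierarchy (a DAG under a
#' topological ranking) and 0 for the trivial one-class ranking; may be
#' negative for non-optimal rankings.
#'
#' @inheritParams agony_value
#' @return the hierarchy value.
#' @export
hierarchy_value <- function(graph, ranking, d = 1) {
  graph <- as_digraph(graph)
  m <- igraph::ecount(graph)
  if (m == 0L) stop("hierarchy is undefined for a graph with no edges")
  1 - agony_value(graph, ranking, d) / m
}

#' Classify edges as forward or backward
#'
#' An edge (u, v) is forward when `r(v) > r(u)` and backward otherwise;
#' same-class links count as backward (they carry penalty \eqn{f_d(0) = 1}).
#'
#' @inheritParams agony_value
#' @return a data frame with columns `from`, `to`, `delta` (rank drop
#'   `r(from) - r(to)`) and `label` (`"forward"` or `"backward"`).
#' @export
classify_edges <- function(graph, ranking) {
  graph <- as_digraph(graph)
  rk <- ranks_for_edges(graph, ranking)
  delta <- rk$ru - rk$rv
  data.frame(from = rk$el[, 1L], to = rk$el[, 2L], delta = delta,
             label = ifelse(delta >= 0, "backward", "forward"),
             stringsAsFactors = FALSE)
}

#' Read a directed graph from a two-column edge list
#'
#' Reads a TSV file with two columns (source, target). Lines starting with
#' `#` and blank lines are skipped. Duplicate edges are removed with a
#' warning; self-loops are dropped with a warning reporting their count.
#'
#' @param path path to the edge-list file.
#' @return a directed graph ([digraph()]).
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx))
    return(digraph(matrix(character(), ncol = 2L)))
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L))
    stop("malformed edge list at line ", idx[which(nf < 2L)[1L]],
         ": expected two tab-separated columns")
  el <- cbind(vapply(parts, `[[`, "", 1L), vapply(parts, `[[`, "", 2L))
  loops <- el[, 1L] == el[, 2L]
  if (any(loops)) {
    warning("dropped ", sum(loops), " self-loop(s)")
    el <- el[!loops, , drop = FALSE]
  }
  key <- paste(el[, 1L], el[, 2L], sep = "\r")
  if (anyDuplicated(key)) {
    warning("removed ", sum(duplicated(key)), " duplicated edge(s)")
    el <- el[!duplicated(key), , drop = FALSE]
  }
  digraph(el)
}

#' Write a directed graph as a two-column edge list
#'
#' @param graph a directed graph.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  graph <- as_digraph(graph)
  el <- edge_endpoints(graph)
  write.table(el, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a ranking from a node/rank TSV file
#'
#' @param path path to a two-column TSV (node, integer rank). `#` comments
#'   and blank lines are skipped.
#' @return a named integer ranking.
#' @export
read_ranking <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) stop("empty ranking file: ", path)
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L))
    stop("malformed ranking at line ", idx[which(nf < 2L)[1L]],
         ": expected two tab-separated columns")
  nodes <- vapply(parts, `[[`, "", 1L)
  ranks <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  if (any(is.na(ranks)))
    stop("malformed ranking at line ", idx[which(is.na(ranks))[1L]],
         ": rank is not an integer")
  as_ranking(structure(ranks, names = nodes))
}

#' Write a ranking as a node/rank TSV file
#'
#' @param ranking a ranking.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  ranking <- as_ranking(ranking)
  write.table(cbind(names(ranking), unname(ranking)), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
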