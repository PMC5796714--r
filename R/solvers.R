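#' Fit an agony-minimising ranking to a directed graph
#'
#' Finds a ranking (ordered partition of the nodes) minimising the
#' generalised agony \eqn{A_d(G, r) = \sum_{(u,v)} f_d(r(u) - r(v))} with
#' \eqn{f_d(x) = (x+1)^d} for \eqn{x \ge 0} and 0 otherwise.
#'
#' Solvers:
#' \describe{
#'   \item{`"flow"`}{exact for `d = 1` at practical scale. The linear agony
#'     LP is totally unimodular and its dual is a maximum circulation with
#'     unit capacities; the solver runs a min-cost-flow routine in C++ and
#'     reads optimal ranks off the residual shortest-path potentials.}
#'   \item{`"brute"`}{exact for any `d` by exhaustive enumeration of all
#'     ordered partitions (ordered Bell number of them), capped at
#'     `max_brute` nodes. Ties are broken towards the fewest classes, then
#'     the lexicographically smallest rank vector over alphabetically
#'     sorted node names.}
#'   \item{`"greedy"`}{deterministic heuristic for `d = 0` (the minimum
#'     feedback arc set problem, NP-hard): repeatedly removes the node with
#'     maximal out-degree minus in-degree, appending it to a linear order,
#'     and places one node per class. The number of backward edges is
#'     guaranteed `<= m/2`. The result is flagged as heuristic.}
#' }
#' `method = "auto"` picks `"flow"` for `d = 1`, otherwise `"brute"` when
#' the graph has at most `max_brute` nodes, otherwise `"greedy"` for
#' `d = 0`; for other `d` at larger sizes no exact solver is available and
#' an error is raised.
#'
#' @param graph a directed graph (see [as_digraph()]).
#' @param d penalty exponent (`>= 0`).
#' @param method `"auto"`, `"flow"`, `"brute"` or `"greedy"`.
#' @param max_brute largest node count accepted by the brute-force solver.
#' @return an object of class `"agony"`: a list with elements `ranking`
#'   (canonical named integer vector), `agony`, `hierarchy` (`NA` when the
#'   graph has no edges), `d`, `method`, `heuristic`, `N`, `m` and `graph`.
#' @examples
#' g <- digraph(rbind(c("a", "b"), c("b", "c"), c("c", "a")))
#' fit <- agony(g, d = 1)
#' coef(fit)
#' @seealso [iterated_agony()], [agony_value()], [hierarchy_value()]
#' @export
agony <- function(graph, d = 1,
                  method = c("auto", "flow", "brute", "greedy"),
                  max_brute = 8L) {
  graph <- as_digraph(graph)
  check_d(d)
  method <- match.arg(method)
  N <- igraph::vcount(graph)
  if (method == "auto") {
    method <- if (d == 1) "flow"
    else if (N <= max_brute) "brute"
    else if (d == 0) "greedy"
    else stop("no solver for d = ", d, " beyond ", max_brute,
              " nodes; use d = 1 (exact flow solver) or d = 0 (greedy)")
  }
  if (method == "flow" && d != 1)
    stop("the flow solver is exact only for d = 1; use method = 'brute'")
  if (method == "greedy" && d != 0)
    stop("the greedy feedback-arc-set heuristic applies only to d = 0")
  fit <- switch(method,
                flow = agony_flow(graph),
                brute = agony_brute(graph, d, max_nodes = max_brute),
                greedy = agony_greedy(graph))
  m <- igraph::ecount(graph)
  structure(list(ranking = fit$ranking,
                 agony = fit$agony,
                 hierarchy = if (m > 0) 1 - fit$agony / m else NA_real_,
                 d = d, method = method,
                 heuristic = identical(method, "greedy"),
                 N = N, m = m, graph = graph,
                 call = match.call()),
            class = "agony")
}

agony_flow <- function(graph) {
  nodes <- igraph::V(graph)$name
  el <- edge_endpoints(graph)
  src <- match(el[, 1L], nodes) - 1L
  dst <- match(el[, 2L], nodes) - 1L
  res <- agony_flow_cpp(as.integer(src), as.integer(dst), length(nodes))
  ranking <- structure(res$rank, names = nodes)
  ranking <- canonicalize_ranking(ranking)
  ag <- agony_value(graph, ranking, d = 1)
  if (ag != res$flow_value)
    stop("internal error: primal agony ", ag,
         " does not match dual circulation value ", res$flow_value)
  list(ranking = ranking, agony = ag)
}

# All ordered partitions of 1..n as an iterator over set partitions
# (restricted growth strings) crossed with permutations of block labels.
rgs_partitions <- function(n) {
  out <- vector("list", 0L)
  assign_next <- function(i, a, k) {
    if (i > n) {
      out[[length(out) + 1L]] <<- list(a = a, k = k)
      return(invisible())
    }
    for (b in seq_len(k + 1L)) {
      a[i] <- b
      assign_next(i + 1L, a, max(k, b))
    }
  }
  assign_next(1L, integer(n), 0L)
  out
}

permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(k - 1L)
  out <- matrix(0L, nrow = k * nrow(sub), ncol = k)
  row <- 1L
  for (pos in seq_len(k)) {
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- append(sub[r, ], k, after = pos - 1L)
      row <- row + 1L
    }
  }
  out
}

lex_less <- function(a, b) {
  i <- which(a != b)
  length(i) > 0L && a[i[1L]] < b[i[1L]]
}

agony_brute <- function(graph, d, max_nodes = 8L) {
  nodes <- sort(igraph::V(graph)$name)
  n <- length(nodes)
  if (n > max_nodes)
    stop("brute-force enumeration is capped at ", max_nodes,
         " nodes (ordered Bell growth); use the flow solver (d = 1) ",
         "or the greedy heuristic (d = 0)")
  if (n == 0L)
    return(list(ranking = structure(integer(0), names = character(0)),
                agony = 0))
  el <- edge_endpoints(graph)
  src <- match(el[, 1L], nodes)
  dst <- match(el[, 2L], nodes)
  m <- length(src)
  perms <- lapply(seq_len(n), permutations)
  best_agony <- Inf
  best_k <- Inf
  best_rank <- NULL
  for (part in rgs_partitions(n)) {
    k <- part$k
    P <- perms[[k]]
    ranks <- P[, part$a, drop = FALSE] # (k! x n) candidate rank vectors
    if (m > 0L) {
      diff <- ranks[, src, drop = FALSE] - ranks[, dst, drop = FALSE]
      cost <- (diff + 1)^d
      cost[diff < 0] <- 0
      ag <- rowSums(cost)
    } else {
      ag <- rep(0, nrow(ranks))
    }
    amin <- min(ag)
    if (amin > best_agony || (amin == best_agony && k > best_k)) next
    cand <- which(ag == amin)
    pick <- cand[1L]
    for (i in cand[-1L])
      if (lex_less(ranks[i, ], ranks[pick, ])) pick <- i
    if (amin < best_agony || k < best_k ||
        lex_less(ranks[pick, ], best_rank)) {
      best_agony <- amin
      best_k <- k
      best_rank <- ranks[pick, ]
    }
  }
  list(ranking = structure(as.integer(best_rank), names = nodes),
       agony = best_agony)
}

agony_greedy <- function(graph) {
  nodes <- igraph::V(graph)$name
  n <- length(nodes)
  if (n == 0L)
    return(list(ranking = structure(integer(0), names = character(0)),
                agony = 0))
  el <- edge_endpoints(graph)
  src <- match(el[, 1L], nodes)
  dst <- match(el[, 2L], nodes)
  outadj <- split(dst, factor(src, levels = seq_len(n)))
  inadj <- split(src, factor(dst, levels = seq_len(n)))
  outdeg <- lengths(outadj)
  indeg <- lengths(inadj)
  alive <- rep(TRUE, n)
  ord <- integer(n)
  name_order <- order(nodes) # deterministic tie-break: first by name
  for (pos in seq_len(n)) {
    score <- outdeg - indeg
    score[!alive] <- -Inf
    cand <- which(score == max(score))
    pick <- cand[which.min(match(cand, name_order))]
    ord[pos] <- pick
    alive[pick] <- FALSE
    for (v in outadj[[pick]]) if (alive[v]) indeg[v] <- indeg[v] - 1L
    for (v in inadj[[pick]]) if (alive[v]) outdeg[v] <- outdeg[v] - 1L
  }
  ranking <- integer(n)
  ranking[ord] <- seq_len(n)
  names(ranking) <- nodes
  list(ranking = canonicalize_ranking(ranking),
       agony = agony_value(graph, ranking, d = 0))
}

#' @export
print.agony <- function(x, ...) {
  cat("Agony-minimising ranking (d = ", x$d, ", method = ", x$method,
      if (x$heuristic) ", heuristic" else "", ")\n", sep = "")
  cat("  nodes: ", x$N, "   edges: ", x$m,
      "   classes: ", length(unique(x$ranking)), "\n", sep = "")
  cat("  agony: ", format(x$agony), "   hierarchy: ",
      format(round(x$hierarchy, 4)), "\n", sep = "")
  invisible(x)
}

#' @export
coef.agony <- function(object, ...) object$ranking

#' Per-edge agony penalties of a fitted ranking
#'
#' @param object an `"agony"` fit.
#' @param ... unused.
#' @return a named numeric vector of penalties, one per edge (`"u->v"`).
#' @export
residuals.agony <- function(object, ...) {
  rk <- ranks_for_edges(object$graph, object$ranking)
  pen <- agony_penalty(rk$ru - rk$rv, object$d)
  names(pen) <- paste0(rk$el[, 1L], "->", rk$el[, 2L])
  pen
}

#' @export
summary.agony <- function(object, ...) {
  cls <- classify_edges(object$graph, object$ranking)
  sizes <- class_sizes(object$ranking)
  structure(list(fit = object, sizes = sizes,
                 n_forward = sum(cls$label == "forward"),
                 n_backward = sum(cls$label == "backward")),
            class = "summary.agony")
}

#' @export
print.summary.agony <- function(x, ...) {
  print(x$fit)
  cat("  forward edges: ", x$n_forward,
      "   backward edges: ", x$n_backward, "\n", sep = "")
  cat("  class sizes:\n")
  print(x$sizes)
  invisible(x)
}

#' Plot the adjacency structure of a fitted ranking
#'
#' Displays the adjacency matrix with nodes ordered by fitted rank, class
#' boundaries drawn as lines. In a strong hierarchy mass concentrates above
#' the diagonal.
#'
#' @param x an `"agony"` fit.
#' @param ... passed to [graphics::image()].
#' @export
plot.agony <- function(x, ...) {
  ord <- order(x$ranking, names(x$ranking))
  A <- as.matrix(igraph::as_adjacency_matrix(x$graph))
  A <- A[ord, ord, drop = FALSE]
  n <- nrow(A)
  image(seq_len(n), seq_len(n), t(A[n:1, , drop = FALSE]),
        col = c("white", "grey20"), xlab = "target (by rank)",
        ylab = "source (by rank)", axes = FALSE, ...)
  bounds <- cumsum(class_sizes(x$ranking))
  abline(v = bounds + 0.5, h = n - bounds + 0.5, col = "red3", lty = 3)
  invisible(x)
}
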