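# Shared fixtures: all graphs are generated in code, seeded by the caller.

# Erdos-Renyi style directed graph on `n` named nodes (no self-loops,
# single edges); uses the current RNG state.
random_digraph <- function(n, p_edge) {
  A <- matrix(stats::runif(n * n) < p_edge, n, n)
  diag(A) <- FALSE
  idx <- which(A, arr.ind = TRUE)
  nodes <- sprintf("n%02d", seq_len(n))
  digraph(cbind(nodes[idx[, 1]], nodes[idx[, 2]]), nodes = nodes)
}

# All tournaments on `n` nodes (every unordered pair gets one direction),
# enumerated by the bits of `code`.
tournament <- function(n, code) {
  pairs <- t(utils::combn(n, 2))
  bits <- as.integer(intToBits(code))[seq_len(nrow(pairs))]
  from <- ifelse(bits == 1L, pairs[, 1], pairs[, 2])
  to <- ifelse(bits == 1L, pairs[, 2], pairs[, 1])
  nodes <- letters[seq_len(n)]
  digraph(cbind(nodes[from], nodes[to]), nodes = nodes)
}

triangle <- function() {
  digraph(rbind(c("a", "b"), c("b", "c"), c("c", "a")))
}

toy_dag <- function() {
  digraph(rbind(c("a", "b"), c("a", "c"), c("b", "d"), c("c", "d")))
}

trivial_ranking <- function(graph) {
  r <- rep(1L, igraph::vcount(graph))
  names(r) <- igraph::V(graph)$name
  r
}
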