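#' Ranked Stochastic Block Model parameters
#'
#' Defines the RSBM(p, q, s, R, \{n_i\}) ensemble: nodes are partitioned into
#' R ordered classes and each ordered pair of distinct nodes carries an edge
#' independently with probability given by the affinity matrix, which has
#' `p` on the first superdiagonal (links to the next class up), `q` above it
#' (links to more distant upper classes) and `s` on and below the diagonal
#' (backward and same-class links). The planted ranking assigns class `i`
#' rank `i`.
#'
#' A parameter set is a valid hierarchy when expected backward links do not
#' exceed expected forward links, i.e. `s <= s_max` (see [s_max()]);
#' violating sets are accepted with a warning so that sweeps can scan `s`
#' up to and beyond the boundary.
#'
#' @param p probability of a forward link to the nearest upper class.
#' @param q probability of a forward link to more distant upper classes.
#' @param s probability of a backward (or same-class) link.
#' @param R number of classes (`>= 1`).
#' @param n class sizes: a single integer for uniform sizes `n_i = n`, or a
#'   vector of length `R`.
#' @return an object of class `"rsbm"` with fields `p`, `q`, `s`, `R`,
#'   `class_sizes`, `N`, `a` (`log2(R)` when `R` is a power of two, else
#'   `NA`), `uniform`, `s_max` (for `R >= 2`) and `valid`.
#' @examples
#' params <- rsbm(p = 0.5, q = 0.5, s = 0.001, R = 8, n = 16)
#' params
#' @export
rsbm <- function(p, q, s, R, n) {
  for (x in list(p = p, q = q, s = s))
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop("'p', 'q' and 's' must be single probabilities in [0, 1]")
  if (!is.numeric(R) || length(R) != 1L || R < 1 || R != round(R))
    stop("'R' must be a single integer >= 1")
  R <- as.integer(R)
  if (length(n) == 1L) n <- rep(n, R)
  if (length(n) != R || any(n < 1) || any(n != round(n)))
    stop("'n' must be a single size or a vector of ", R, " sizes >= 1")
  n <- as.integer(n)
  a <- log2(R)
  obj <- structure(list(p = p, q = q, s = s, R = R,
                        class_sizes = n, N = sum(n),
                        a = if (isTRUE(all.equal(a, round(a)))) as.integer(round(a)) else NA_integer_,
                        uniform = length(unique(n)) == 1L),
                   class = "rsbm")
  obj$s_max <- if (R >= 2L) s_max(obj) else NA_real_
  obj$valid <- is.na(obj$s_max) || s <= obj$s_max + 1e-12
  if (!obj$valid)
    warning("s = ", s, " exceeds s_max = ", signif(obj$s_max, 4),
            ": expected backward links outnumber forward links")
  obj
}

#' @export
print.rsbm <- function(x, ...) {
  cat("Ranked Stochastic Block Model\n")
  cat("  p = ", x$p, "  q = ", x$q, "  s = ", x$s, "\n", sep = "")
  cat("  R = ", x$R, " classes, N = ", x$N, " nodes (",
      if (x$uniform) paste0("uniform n = ", x$class_sizes[1L])
      else "non-uniform sizes", ")\n", sep = "")
  if (!is.na(x$s_max))
    cat("  s_max = ", signif(x$s_max, 4),
        if (x$valid) "  (valid hierarchy)" else "  (constraint violated)",
        "\n", sep = "")
  invisible(x)
}

#' Affinity matrix of an RSBM
#'
#' @param params an [rsbm()] parameter object.
#' @return the `R x R` matrix with `p` on the first superdiagonal, `q`
#'   above it and `s` elsewhere.
#' @examples
#' affinity_matrix(rsbm(0.6, 0.3, 0.01, R = 3, n = 4))
#' @export
affinity_matrix <- function(params) {
  stopifnot(inherits(params, "rsbm"))
  R <- params$R
  i <- row(matrix(0, R, R))
  j <- col(matrix(0, R, R))
  C <- matrix(params$s, R, R)
  C[j == i + 1] <- params$p
  C[j > i + 1] <- params$q
  C
}

# b_k = sum_i n_i n_{i+k}; b_0 = sum n_i^2 (ensemble pair-count convention)
b_counts <- function(sizes) {
  R <- length(sizes)
  vapply(0:(R - 1L), function(k) {
    i <- seq_len(R - k)
    sum(as.numeric(sizes[i]) * sizes[i + k])
  }, numeric(1))
}

#' Largest admissible backward-link probability
#'
#' The hierarchy constraint (expected backward links `<=` expected forward
#' links) bounds `s` by
#' `s_max = (p b_1 + q sum_{k>=2} b_k) / sum_{k=0}^{R-1} b_k` with
#' `b_k = sum_i n_i n_{i+k}`. For uniform class sizes this reduces to the
#' closed form `2(R-1)p/(R(R+1)) + (R-2)(R-1)q/(R(R+1))`.
#'
#' @param params an [rsbm()] parameter object (or any list with fields
#'   `p`, `q`, `class_sizes`).
#' @return the `s_max` bound.
#' @examples
#' s_max(rsbm(0.5, 0, 0, R = 32, n = 128)) # 0.0294
#' @export
s_max <- function(params) {
  sizes <- params$class_sizes
  R <- length(sizes)
  if (R < 2L) stop("s_max requires at least two classes")
  b <- b_counts(sizes)
  fwd <- params$p * b[2L] + if (R >= 3L) params$q * sum(b[3:R]) else 0
  fwd / sum(b)
}

#' Expected block structure of an RSBM
#'
#' Returns the pair counts `b_k = sum_i n_i n_{i+k}` (the ensemble
#' convention with `b_0 = sum n_i^2`) and the exact expected edge
#' count matrix `E[m_ij]`, whose diagonal uses the ordered distinct-pair
#' count `n_i (n_i - 1)`. The two conventions differ by `O(1/n_i)` on the
#' diagonal; the closed-form theory uses the former, the sampler the latter.
#'
#' @param params an [rsbm()] parameter object.
#' @return a list with `b` (length `R`, named `b0..b{R-1}`), `expected_m`
#'   (`R x R` matrix) and `expected_edges` (its sum).
#' @export
block_counts <- function(params) {
  stopifnot(inherits(params, "rsbm"))
  sizes <- params$class_sizes
  C <- affinity_matrix(params)
  pairs <- outer(as.numeric(sizes), as.numeric(sizes))
  diag(pairs) <- as.numeric(sizes) * (sizes - 1)
  em <- pairs * C
  b <- b_counts(sizes)
  names(b) <- paste0("b", seq_along(b) - 1L)
  list(b = b, expected_m = em, expected_edges = sum(em))
}

sample_block_edges <- function(n_from, n_to, prob, same_class) {
  npairs <- if (same_class) n_from * (n_from - 1) else n_from * n_to
  if (npairs == 0 || prob <= 0) return(NULL)
  k <- rbinom(1L, npairs, prob)
  if (k == 0L) return(NULL)
  idx <- if (k < npairs) sample.int(npairs, k) else seq_len(npairs)
  if (same_class) {
    u <- (idx - 1L) %% n_from + 1L
    v <- (idx - 1L) %/% n_from + 1L
    v <- v + (v >= u) # skip the diagonal
  } else {
    u <- (idx - 1L) %% n_from + 1L
    v <- (idx - 1L) %/% n_from + 1L
  }
  cbind(u, v)
}

#' Simulate graphs from an RSBM
#'
#' Draws realisations of the ensemble together with their planted rankings.
#' Each block's edge count is drawn from its binomial distribution and the
#' edges are placed uniformly without replacement within the block, which is
#' distributionally identical to independent per-pair Bernoulli draws.
#' Reciprocal pairs (2-cycles) can occur, as in any directed SBM. No
#' self-loops are generated.
#'
#' @param object an [rsbm()] parameter object.
#' @param nsim number of realisations.
#' @param seed optional integer seed (`set.seed` is called when given).
#' @param ... unused.
#' @return for `nsim = 1` a list with elements `graph` (a [digraph()]) and
#'   `planted` (the planted ranking, a named integer vector); for
#'   `nsim > 1` a list of such lists.
#' @examples
#' sim <- simulate(rsbm(1, 1, 0, R = 2, n = 3), seed = 1)
#' igraph::ecount(sim$graph) # 9: all cross-class pairs, class 1 -> class 2
#' @export
simulate.rsbm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sims <- replicate(nsim, rsbm_draw(object), simplify = FALSE)
  if (nsim == 1L) sims[[1L]] else sims
}

rsbm_draw <- function(params) {
  sizes <- params$class_sizes
  R <- params$R
  N <- params$N
  width <- max(2L, nchar(as.character(N)))
  nodes <- sprintf("v%0*d", width, seq_len(N))
  planted <- rep(seq_len(R), times = sizes)
  names(planted) <- nodes
  offset <- cumsum(c(0L, sizes))[seq_len(R)]
  C <- affinity_matrix(params)
  edges <- vector("list", R * R)
  idx <- 1L
  for (i in seq_len(R)) {
    for (j in seq_len(R)) {
      uv <- sample_block_edges(sizes[i], sizes[j], C[i, j], i == j)
      if (!is.null(uv)) {
        edges[[idx]] <- cbind(nodes[offset[i] + uv[, 1L]],
                              nodes[offset[j] + uv[, 2L]])
        idx <- idx + 1L
      }
    }
  }
  el <- do.call(rbind, edges[seq_len(idx - 1L)])
  if (is.null(el)) el <- matrix(character(), ncol = 2L)
  graph <- digraph(el, nodes = nodes)
  list(graph = graph, planted = planted)
}
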