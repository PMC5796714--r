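test_that("affinity matrix has p on the superdiagonal, q above, s below", {
  pa <- rsbm(p = 0.7, q = 0.2, s = 0.01, R = 3, n = 4)
  expect_equal(affinity_matrix(pa),
               rbind(c(0.01, 0.7, 0.2),
                     c(0.01, 0.01, 0.7),
                     c(0.01, 0.01, 0.01)))
  expect_equal(affinity_matrix(rsbm(0.5, 0.1, 0.3, R = 1, n = 5)),
               matrix(0.3, 1, 1))
  expect_equal(affinity_matrix(rsbm(1, 0, 0, R = 2, n = 2)),
               rbind(c(0, 1), c(0, 0)))
})

test_that("s_max matches the closed form for uniform sizes", {
  expect_equal(s_max(rsbm(0.5, 0, 0, R = 32, n = 128)),
               2 * 31 / (32 * 33) * 0.5)
  # the q term vanishes at R = 2
  expect_equal(s_max(rsbm(0.5, 0.37, 0, R = 2, n = 8)), 0.5 / 3)
  # closed form vs the general b_k inequality, a grid of uniform sets
  for (R in c(2, 4, 8, 16)) for (p in c(0.3, 0.8)) for (q in c(0, 0.25)) {
    pa <- rsbm(p, q, 0, R, 8)
    closed <- 2 * (R - 1) * p / (R * (R + 1)) +
      (R - 2) * (R - 1) * q / (R * (R + 1))
    expect_equal(s_max(pa), closed, tolerance = 1e-14)
  }
  expect_error(s_max(rsbm(0.5, 0, 0, R = 1, n = 4)), "two classes")
})

test_that("s_max handles non-uniform sizes through the b_k sums", {
  pa <- rsbm(0.6, 0.2, 0, R = 3, n = c(4, 2, 2))
  b <- c(sum(c(4, 2, 2)^2), 4 * 2 + 2 * 2, 4 * 2)
  expect_equal(s_max(pa), (0.6 * b[2] + 0.2 * b[3]) / sum(b))
})

test_that("violating the hierarchy constraint warns but does not error", {
  expect_warning(rsbm(0.5, 0, 0.2, R = 8, n = 4), "s_max")
  expect_silent(rsbm(0.5, 0.5, 0.001, R = 8, n = 4))
})

test_that("block counts follow the b_k formula and exact pair counts", {
  pa <- rsbm(0.5, 0.2, 0.01, R = 4, n = 3)
  bc <- block_counts(pa)
  expect_equal(unname(bc$b), c(4 * 9, 3 * 9, 2 * 9, 9))
  expect_equal(unname(block_counts(rsbm(0.5, 0, 0, 32, 128))$b[2]),
               31 * 128^2)
  # uniform sizes: sum b_k = n^2 R (R + 1) / 2
  expect_equal(sum(bc$b), 9 * 4 * 5 / 2)
  # diagonal of E[m] uses ordered distinct pairs
  expect_equal(diag(bc$expected_m), rep(3 * 2 * 0.01, 4))
  expect_equal(bc$expected_m[1, 2], 9 * 0.5)
  expect_equal(bc$expected_m[3, 1], 9 * 0.01)
})

test_that("s = 0 realisations are DAGs with perfect hierarchy", {
  sim <- simulate(rsbm(0.5, 0.5, 0, R = 6, n = 5), seed = 3)
  expect_true(igraph::is_dag(sim$graph))
  expect_equal(agony_value(sim$graph, sim$planted, 1), 0)
})

test_that("deterministic block: p = q = 1, s = 0, R = 2 gives the full bipartite flow", {
  sim <- simulate(rsbm(1, 1, 0, R = 2, n = 3), seed = 1)
  expect_equal(igraph::ecount(sim$graph), 9)
  cls <- classify_edges(sim$graph, sim$planted)
  expect_true(all(cls$label == "forward"))
})

test_that("sampled edge counts match binomial moments", {
  pa <- rsbm(0.5, 0.5, 0.01, R = 8, n = 16)
  bc <- block_counts(pa)
  mu <- bc$expected_edges
  C <- affinity_matrix(pa)
  pairs <- outer(rep(16, 8), rep(16, 8)); diag(pairs) <- 16 * 15
  sigma <- sqrt(sum(pairs * C * (1 - C)))
  set.seed(202)
  ms <- vapply(1:20, function(i)
    igraph::ecount(simulate(pa, seed = 1000 + i)$graph), numeric(1))
  expect_lt(abs(mean(ms) - mu), 4 * sigma / sqrt(20))
})

test_that("sampling is reproducible by seed and varies across seeds", {
  pa <- rsbm(0.4, 0.3, 0.02, R = 4, n = 8)
  g1 <- simulate(pa, seed = 9)
  g2 <- simulate(pa, seed = 9)
  g3 <- simulate(pa, seed = 10)
  el <- function(s) igraph::as_edgelist(s$graph)
  expect_identical(el(g1), el(g2))
  expect_false(identical(el(g1), el(g3)))
  expect_equal(g1$planted, g2$planted)
})

test_that("per-block edge frequencies concentrate around the affinity", {
  pa <- rsbm(0.6, 0.25, 0.05, R = 3, n = 32)
  C <- affinity_matrix(pa)
  counts <- matrix(0, 3, 3)
  set.seed(77)
  nsim <- 50
  for (i in 1:nsim) {
    sim <- simulate(pa)
    el <- igraph::as_edgelist(sim$graph)
    ci <- sim$planted[el[, 1]]
    cj <- sim$planted[el[, 2]]
    counts <- counts + table(factor(ci, 1:3), factor(cj, 1:3))
  }
  pairs <- outer(rep(32, 3), rep(32, 3)); diag(pairs) <- 32 * 31
  phat <- counts / (pairs * nsim)
  expect_lt(max(abs(phat - C)), 0.02)
})

test_that("parameter validation rejects malformed inputs", {
  expect_error(rsbm(1.2, 0, 0, 2, 4), "probabilities")
  expect_error(rsbm(0.5, 0, 0, 2.5, 4), "integer")
  expect_error(rsbm(0.5, 0, 0, 3, c(4, 4)), "sizes")
})
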