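params_grid <- function() {
  grid <- expand.grid(a = 2:5, p = c(0.3, 0.8), q_frac = c(0, 0.5, 1),
                      s = c(0.001, 0.02))
  lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    suppressWarnings(rsbm(g$p, g$p * g$q_frac, g$s, 2^g$a, 8))
  })
}

test_that("planted estimate is 1 at s = 0 and equals the oracle at b = 0", {
  for (d in c(0, 0.5, 1, 2))
    expect_equal(as.numeric(planted_hierarchy(rsbm(0.5, 0.3, 0, 8, 4), d)), 1)
  for (pa in params_grid()[1:12]) {
    for (d in c(0, 1, 2))
      expect_equal(as.numeric(planted_hierarchy(pa, d)),
                   as.numeric(expected_hierarchy(pa, d, b = 0)),
                   tolerance = 1e-12)
  }
})

test_that("the planted-zero root matches an independent numerical solve", {
  pa <- rsbm(0.5, 0, 0.001, 32, 128)
  root <- s_planted_zero(pa, 1)
  expect_equal(root, 6 * 0.5 / (32 * 33), tolerance = 1e-12)
  f <- function(s) as.numeric(planted_hierarchy(
    suppressWarnings(rsbm(0.5, 0, s, 32, 128)), 1))
  num <- stats::uniroot(f, c(1e-5, 0.02), tol = 1e-12)$root
  expect_equal(root, num, tolerance = 1e-8)
  # general-size route: q > 0 and non-uniform sizes still solve cleanly
  pa2 <- rsbm(0.4, 0.2, 0.001, 3, c(6, 4, 2))
  f2 <- function(s) as.numeric(planted_hierarchy(
    suppressWarnings(rsbm(0.4, 0.2, s, 3, c(6, 4, 2))), 2))
  expect_equal(s_planted_zero(pa2, 2),
               stats::uniroot(f2, c(1e-5, 0.5), tol = 1e-12)$root,
               tolerance = 1e-8)
})

test_that("closed-form candidate estimates match the expectation oracle", {
  worst <- 0
  for (pa in params_grid()) {
    for (b in 0:pa$a) for (inv in c(FALSE, TRUE)) for (d in 1:2) {
      delta <- abs(candidate_hierarchy(pa, d, b, inv) -
                     as.numeric(expected_hierarchy(pa, d, b, inv)))
      worst <- max(worst, delta)
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("candidate estimate at b = 0 reproduces the planted estimate", {
  for (pa in params_grid()[seq(1, 48, by = 5)])
    for (d in 1:2)
      expect_equal(candidate_hierarchy(pa, d, 0),
                   as.numeric(planted_hierarchy(pa, d)), tolerance = 1e-12)
})

test_that("full merge gives hierarchy 0 and splits defer to the oracle", {
  pa <- rsbm(0.5, 0.5, 0.01, 16, 16)
  expect_equal(candidate_hierarchy(pa, 1, b = pa$a), 0, tolerance = 1e-12)
  expect_equal(as.numeric(expected_hierarchy(pa, 1, b = pa$a)), 0,
               tolerance = 1e-12)
  expect_equal(candidate_hierarchy(pa, 1, b = -1),
               as.numeric(expected_hierarchy(pa, 1, b = -1)))
  expect_error(candidate_hierarchy(pa, 0.5, 0), "expected_hierarchy")
  expect_error(candidate_hierarchy(pa, 1, b = -0.5), "integer")
  expect_error(expected_hierarchy(rsbm(0.5, 0.2, 0.01, 3, c(4, 2, 2)), 1, 0),
               "uniform")
})

test_that("splitting is never optimal for d = 1", {
  # direct splits always fall below the planted estimate; inverted splits
  # can beat an already-suboptimal planted ranking deep in the inversion
  # regime but are never the family optimum
  for (pa in params_grid()) {
    if (!pa$valid) next
    planted <- as.numeric(planted_hierarchy(pa, 1))
    for (b in -1:-3) {
      if (pa$class_sizes[1] %% 2^(-b) != 0) break
      expect_lt(as.numeric(expected_hierarchy(pa, 1, b)), planted)
    }
    expect_gte(optimal_candidate(pa, 1)$b, 0)
  }
})

test_that("inversion never beats the planted ranking in the twitter regime", {
  for (a in 3:5) for (s in c(0.001, 0.01)) {
    pa <- rsbm(0.6, 0.4, s, 2^a, 8)
    planted <- as.numeric(planted_hierarchy(pa, 1))
    for (b in 0:(pa$a - 1))
      expect_lt(candidate_hierarchy(pa, 1, b, inverted = TRUE), planted)
  }
})

test_that("threshold values reproduce the closed forms' tie points", {
  pa <- function(s, q = 0.5) suppressWarnings(rsbm(0.5, q, s, 32, 128))
  a <- 5
  # twitter d = 1: at s_m the planted ranking ties the R-1 class merge
  th <- resolution_thresholds(pa(0.001), 1)
  b_rm1 <- a - log2(31) # R~ = 31
  expect_equal(candidate_hierarchy(pa(th$values$s_m), 1, b_rm1),
               as.numeric(planted_hierarchy(pa(th$values$s_m), 1)),
               tolerance = 1e-10)
  # at s_2 the 3-class and 2-class merged rankings tie
  p2 <- pa(th$values$s_2)
  expect_equal(candidate_hierarchy(p2, 1, a - log2(3)),
               candidate_hierarchy(p2, 1, a - 1), tolerance = 1e-10)
  # military d = 1: at s_i the planted ranking ties the inverted 2-class one
  thm <- resolution_thresholds(pa(0.001, q = 0), 1)
  pm <- pa(thm$values$s_i, q = 0)
  expect_equal(candidate_hierarchy(pm, 1, a - 1, inverted = TRUE),
               as.numeric(planted_hierarchy(pm, 1)), tolerance = 1e-10)
  # at s_3_i the inverted 2- and 3-class rankings tie
  p3 <- pa(thm$values$s_3_i, q = 0)
  expect_equal(candidate_hierarchy(p3, 1, a - 1, inverted = TRUE),
               candidate_hierarchy(p3, 1, a - log2(3), inverted = TRUE),
               tolerance = 1e-10)
  # the interior optimum formula maximises the d = 1 closed form
  pm2 <- pa(0.01, q = 0)
  bst <- resolution_thresholds(pm2, 1)$values$b_i_star
  opt <- optimize(function(b) candidate_hierarchy(pm2, 1, b, inverted = TRUE),
                  c(0, a - 1), maximum = TRUE, tol = 1e-9)
  expect_equal(bst, opt$maximum, tolerance = 1e-5)
})

test_that("d = 2 thresholds tie and order as stated", {
  a <- 5
  pa <- function(s, q) suppressWarnings(rsbm(0.5, q, s, 32, 128))
  th <- resolution_thresholds(pa(0.001, 0.5), 2, regime = "twitter")
  # s_2m: planted ties the R-1 class merge under the quadratic penalty
  pt <- pa(th$values$s_2m, 0.5)
  expect_equal(candidate_hierarchy(pt, 2, a - log2(31)),
               as.numeric(planted_hierarchy(pt, 2)), tolerance = 1e-10)
  # s_21: the 2-class merge crosses zero (trivial ranking takes over)
  expect_equal(candidate_hierarchy(pa(th$values$s_21, 0.5), 2, a - 1), 0,
               tolerance = 1e-10)
  # quadratic penalty resolves less: s_2m < s_m
  th1 <- resolution_thresholds(pa(0.001, 0.5), 1)
  expect_lt(th$values$s_2m, th1$values$s_m)
  thm <- resolution_thresholds(pa(0.001, 0), 2, regime = "military")
  # s_21_0 is the planted zero for d = 2
  expect_equal(thm$values$s_21_0, s_planted_zero(pa(0.001, 0), 2),
               tolerance = 1e-12)
  # s_23_i = 3 s_22_i exactly, and the ordering s_21_0 < s_22_i holds
  expect_identical(thm$values$s_23_i, 3 * thm$values$s_22_i)
  expect_lt(thm$values$s_21_0, thm$values$s_22_i)
  # s_22_i: the inverted 2-class estimate crosses zero
  expect_equal(candidate_hierarchy(pa(thm$values$s_22_i, 0), 2, a - 1,
                                   inverted = TRUE), 0, tolerance = 1e-10)
})

test_that("thresholds scale as the large-R asymptotics prescribe", {
  sm_scaled <- sapply(6:9, function(a) {
    pa <- rsbm(0.4, 0.2, 1e-6, 2^a, 2)
    resolution_thresholds(pa, 1, regime = "twitter")$values$s_m * 4^a
  })
  expect_equal(sm_scaled[length(sm_scaled)], 6 * 0.4 - 3 * 0.2,
               tolerance = 0.02)
  expect_true(all(diff(abs(sm_scaled - (6 * 0.4 - 3 * 0.2))) < 0))
  si_scaled <- sapply(6:9, function(a) {
    pa <- rsbm(0.4, 0, 1e-6, 2^a, 2)
    resolution_thresholds(pa, 1)$values$s_i * 4^a
  })
  expect_equal(si_scaled[length(si_scaled)], 6 * 0.4, tolerance = 0.02)
  s210_scaled <- sapply(6:9, function(a) {
    pa <- rsbm(0.4, 0, 1e-6, 2^a, 2)
    resolution_thresholds(pa, 2)$values$s_21_0 * 8^a
  })
  expect_equal(s210_scaled[length(s210_scaled)], 12 * 0.4, tolerance = 0.05)
})

test_that("d = 0 optimum is the fully split ranking with estimate >= 1/2", {
  for (pa in params_grid()) {
    if (!pa$valid) next
    oc <- optimal_candidate(pa, 0)
    expect_equal(oc$R_tilde, pa$N)
    expect_false(oc$inverted)
    expect_gte(oc$estimate, 0.5)
  }
})

test_that("optimal candidate tracks the piecewise phase selection", {
  # twitter, s below s_m: planted wins
  pa <- rsbm(0.5, 0.5, 0.001, 32, 128)
  oc <- optimal_candidate(pa, 1)
  expect_equal(oc$b, 0)
  expect_false(oc$inverted)
  # twitter, s above the integer flip: a merged ranking wins
  pa2 <- suppressWarnings(rsbm(0.5, 0.5, 0.008, 32, 128))
  oc2 <- optimal_candidate(pa2, 1)
  expect_gt(oc2$b, 0)
  expect_false(oc2$inverted)
  # military, s just above s_i: the inverted 2-class ranking wins
  pa3 <- suppressWarnings(rsbm(0.5, 0, 0.004, 32, 128))
  oc3 <- optimal_candidate(pa3, 1)
  expect_true(oc3$inverted)
  expect_equal(oc3$R_tilde, 2)
})

test_that("optimal class count is non-increasing in s (twitter, d = 1)", {
  s_max_val <- s_max(rsbm(0.5, 0.5, 0, 16, 16))
  s_grid <- seq(1e-4, s_max_val, length.out = 12)
  rt <- sapply(s_grid, function(s) {
    pa <- suppressWarnings(rsbm(0.5, 0.5, s, 16, 16))
    optimal_candidate(pa, 1, max_split = 0)$R_tilde
  })
  expect_true(all(diff(rt) <= 0))
  expect_equal(rt[1], 16)
  expect_lt(rt[length(rt)], 16)
})

test_that("regime detection validates the parameter patterns", {
  expect_error(resolution_thresholds(rsbm(0.3, 0.6, 0.01, 8, 4), 1,
                                     regime = "twitter"), "p >= q > s")
  expect_error(resolution_thresholds(rsbm(0.5, 0.2, 0.01, 8, 4), 1,
                                     regime = "military"), "q = 0")
  th <- resolution_thresholds(rsbm(0.5, 0, 0.01, 8, 4), 1)
  expect_equal(th$regime, "military")
})
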