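#' First-order expected hierarchy of the planted ranking
#'
#' The first-order (large-N) estimate of the expected hierarchy of an RSBM
#' under its planted ranking,
#' \deqn{\bar h_d = 1 - \frac{s \sum_{k=0}^{R-1} (k+1)^d b_k}
#'                          {p b_1 + q \sum_{k \ge 2} b_k + s \sum_k b_k},}
#' with pair counts \eqn{b_k = \sum_i n_i n_{i+k}} (ensemble convention,
#' \eqn{b_0 = \sum_i n_i^2}). Valid for any penalty exponent and any class
#' sizes. At `s = 0` the estimate is exactly 1.
#'
#' @param params an [rsbm()] parameter object.
#' @param d penalty exponent.
#' @return the estimate, with attributes `expected_agony` and `expected_m`
#'   (per-\eqn{n^2} ensemble masses).
#' @examples
#' planted_hierarchy(rsbm(0.5, 0.5, 0.001, R = 32, n = 128), d = 1)
#' @export
planted_hierarchy <- function(params, d = 1) {
  stopifnot(inherits(params, "rsbm"))
  check_d(d)
  b <- b_counts(params$class_sizes)
  R <- params$R
  k <- 0:(R - 1L)
  fwd <- params$p * (if (R >= 2L) b[2L] else 0) +
    (if (R >= 3L) params$q * sum(b[3:R]) else 0)
  EA <- params$s * sum((k + 1)^d * b)
  Em <- fwd + params$s * sum(b)
  if (Em == 0) stop("expected edge count is zero; estimate undefined")
  structure(1 - EA / Em, expected_agony = EA, expected_m = Em)
}

#' Root in s of the planted first-order estimate
#'
#' The backward-link probability at which the planted ranking's expected
#' hierarchy crosses zero (i.e. the trivial one-class ranking overtakes it):
#' solving `planted_hierarchy = 0` in `s` gives
#' `s = (p b_1 + q sum_{k>=2} b_k) / (sum_k ((k+1)^d - 1) b_k)`.
#' For `d = 1`, `q = 0` and uniform sizes this is `6 p / (R (R + 1))`.
#'
#' @inheritParams planted_hierarchy
#' @return the root (a probability).
#' @examples
#' s_planted_zero(rsbm(0.5, 0, 0.001, R = 32, n = 128), d = 1) # 0.00284
#' @export
s_planted_zero <- function(params, d = 1) {
  stopifnot(inherits(params, "rsbm"))
  check_d(d)
  b <- b_counts(params$class_sizes)
  R <- params$R
  k <- 0:(R - 1L)
  fwd <- params$p * (if (R >= 2L) b[2L] else 0) +
    (if (R >= 3L) params$q * sum(b[3:R]) else 0)
  denom <- sum(((k + 1)^d - 1) * b)
  if (denom <= 0)
    stop("the planted estimate has no root in s for d = ", d)
  fwd / denom
}

#' Expected hierarchy of a candidate ranking (expectation oracle)
#'
#' Computes the first-order expected hierarchy of a merged (`b > 0`),
#' planted (`b = 0`) or split (`b < 0`) candidate ranking, optionally
#' inverted, by direct summation of `E[m_ij] * f_d(rank drop)` over all
#' block pairs. This is the normative reference every closed form in
#' [candidate_hierarchy()] is validated against; it works for any `d`.
#'
#' Merging groups `2^b` adjacent planted classes (requires `2^b` to divide
#' `R`); splitting divides each class into `2^{-b}` equal parts with edge
#' mass assigned pro rata (requires `2^{-b}` to divide the class size).
#'
#' @param params an [rsbm()] parameter object with uniform class sizes.
#' @param d penalty exponent.
#' @param b merge exponent: integer, positive to merge, negative to split.
#' @param inverted reverse the candidate class order.
#' @param convention `"ensemble"` uses the ensemble-style pair count
#'   \eqn{n^2} on the diagonal (matches the closed-form theory);
#'   `"exact"` uses the ordered distinct-pair count \eqn{n (n - 1)}
#'   (matches the sampler's moments).
#' @return the estimate, with attributes `expected_agony`, `expected_m` and
#'   `R_tilde` (the candidate class count).
#' @examples
#' pars <- rsbm(0.5, 0.5, 0.01, R = 32, n = 128)
#' expected_hierarchy(pars, d = 1, b = 2)
#' @export
expected_hierarchy <- function(params, d = 1, b = 0, inverted = FALSE,
                               convention = c("ensemble", "exact")) {
  stopifnot(inherits(params, "rsbm"))
  check_d(d)
  convention <- match.arg(convention)
  if (!params$uniform)
    stop("the expectation oracle requires uniform class sizes")
  if (length(b) != 1L || is.na(b) || b != round(b))
    stop("'b' must be a single integer (merge > 0, split < 0)")
  b <- as.integer(b)
  R <- params$R
  n <- params$class_sizes[1L]
  if (b > 0 && R %% 2L^b != 0L)
    stop("2^b = ", 2^b, " does not divide R = ", R)
  split <- if (b < 0) 2L^(-b) else 1L
  if (n %% split != 0L)
    stop("2^-b = ", split, " does not divide the class size n = ", n)
  Rf <- R * split
  nf <- n / split
  parent <- rep(seq_len(R), each = split)
  cand <- if (b >= 0) ceiling(parent / 2^b) else seq_len(Rf)
  Rt <- max(cand)
  if (inverted) cand <- Rt + 1L - cand
  C <- affinity_matrix(params)
  Cf <- C[parent, parent, drop = FALSE]
  mass <- matrix(as.numeric(nf)^2, Rf, Rf)
  if (convention == "exact") diag(mass) <- as.numeric(nf) * (nf - 1)
  drop <- outer(cand, cand, `-`)
  pen <- (drop + 1)^d
  pen[drop < 0] <- 0
  EA <- sum(mass * Cf * pen)
  Em <- sum(mass * Cf)
  if (Em == 0) stop("expected edge count is zero; estimate undefined")
  structure(1 - EA / Em, expected_agony = EA, expected_m = Em, R_tilde = Rt)
}

denom_e <- function(p, q, s, A) {
  A * (2 * p - 3 * q + s) + A^2 * (q + s) - 2 * p + 2 * q
}

#' Closed-form expected hierarchy of merged and inverted rankings
#'
#' First-order estimates of the expected hierarchy of the candidate family
#' built from the planted ranking of a uniform RSBM with `R = 2^a` classes:
#' direct or inverted rankings with `2^(a-b)` uniform classes. Closed forms
#' exist for `d = 1` and `d = 2` and for merges (`b >= 0`, real-valued `b`
#' allowed, matching the continuous-class-number family). Each form is
#' validated against the expectation oracle ([expected_hierarchy()]) to
#' machine precision in the test suite. Integer splits (`b < 0`) are
#' delegated to the oracle, whose summation is exact there.
#'
#' @param params an [rsbm()] parameter object with uniform sizes and `R` a
#'   power of two.
#' @param d penalty exponent: 1 or 2 (other values: use
#'   [expected_hierarchy()]).
#' @param b merge exponent, real `>= 0`, or a negative integer for splits.
#' @param inverted reverse the candidate class order.
#' @return the estimate (plain numeric).
#' @examples
#' pars <- rsbm(0.5, 0.5, 0.01, R = 32, n = 128)
#' candidate_hierarchy(pars, d = 1, b = 0) # equals planted_hierarchy()
#' @export
candidate_hierarchy <- function(params, d = 1, b = 0, inverted = FALSE) {
  stopifnot(inherits(params, "rsbm"))
  if (!d %in% c(1, 2))
    stop("closed forms exist only for d = 1 or 2; ",
         "use expected_hierarchy() for other exponents")
  if (!params$uniform || is.na(params$a))
    stop("closed forms require uniform class sizes and R a power of two")
  if (length(b) != 1L || is.na(b)) stop("'b' must be a single number")
  if (b < 0) {
    if (b != round(b))
      stop("splits require integer b; closed forms cover merges b >= 0")
    return(as.numeric(expected_hierarchy(params, d = d, b = b,
                                         inverted = inverted)))
  }
  a <- params$a
  if (b > a) stop("'b' cannot exceed a = log2(R) = ", a)
  p <- params$p; q <- params$q; s <- params$s
  A <- 2^a; B <- 2^b
  den <- 3 * denom_e(p, q, s, A)
  if (den == 0) stop("degenerate parameters: zero expected edge mass")
  if (d == 1) {
    if (!inverted)
      (A - B) / B * (6 * p + 3 * (A * B - 2) * q - A * (A + B) * s) / den
    else
      (B - A) / B * (A * B * (q - 3 * s) + (A^2 - 6) * q + 6 * p) / den
  } else {
    if (!inverted)
      -(A - B) / (2 * B^2) *
        (2 * A * B^2 * (2 * s - 3 * q) + 5 * s * A^2 * B + A^3 * s -
           12 * B * (p - q)) / den
    else
      (B - A) / (2 * B^2) *
        (2 * A * B^2 * (2 * q - 3 * s) + (5 * A^2 - 36) * B * q +
           A^3 * q + 36 * B * p) / den
  }
}

detect_regime <- function(params, regime) {
  p <- params$p; q <- params$q; s <- params$s
  military <- q == 0 && p > 0
  twitter <- p >= q && q > s
  if (regime == "auto") {
    if (military) return("military")
    if (twitter) return("twitter")
    stop("parameters fit neither regime: twitter needs p >= q > s, ",
         "military needs q = 0 and p > 0")
  }
  if (regime == "twitter" && !twitter)
    stop("twitter regime requires p >= q > s")
  if (regime == "military" && !military)
    stop("military regime requires q = 0 and p > 0")
  regime
}

#' Resolution thresholds of agony minimisation on the RSBM
#'
#' Closed-form critical values of the backward-link probability `s` at
#' which candidate rankings from the uniform continuous-class-number family
#' overtake the planted one, for `d` in 0, 1, 2, in the two parameter
#' regimes: twitter-like (`p >= q > s`, forward links to any upper class)
#' and military-like (`q = 0`, forward links only to the next class up).
#'
#' For `d = 1`, twitter: `s_m` (planted stops being optimal; the flip
#' against the merged ranking with `R - 1` classes), `s_2` (the merged
#' family collapses to two classes) and the interior merge optimum
#' `b_star` at the current `s`. Military: `s_i` (the inverted two-class
#' ranking overtakes the planted), `s_1` (the planted estimate crosses
#' zero), `s_3_i` (inverted three classes overtake inverted two) and the
#' interior inverted optimum `b_i_star`. For `d = 2` the analogous set
#' (`s_2m`, `s_21`; `s_21_0`, `s_22_i`, `s_23_i = 3 s_22_i`, `b_2i_star`);
#' the interior `b_2star` solves a cubic and is computed numerically from
#' the closed form. For `d = 0` the optimum is the fully split ranking with
#' one node per class, whose estimate is bounded below by 1/2 for every
#' valid parameter set.
#'
#' @param params an [rsbm()] parameter object (uniform sizes, `R = 2^a`).
#' @param d penalty exponent: 0, 1 or 2.
#' @param regime `"auto"`, `"twitter"` or `"military"`.
#' @return an object of class `"threshold_set"`: list with `d`, `regime`
#'   and `values` (named list of thresholds).
#' @examples
#' resolution_thresholds(rsbm(0.5, 0.5, 0.001, 32, 128), d = 1)$values$s_m
#' @export
resolution_thresholds <- function(params, d = 1,
                                  regime = c("auto", "twitter", "military")) {
  stopifnot(inherits(params, "rsbm"))
  regime <- match.arg(regime)
  if (!d %in% c(0, 1, 2))
    stop("thresholds are available for d = 0, 1, 2")
  if (!params$uniform || is.na(params$a))
    stop("thresholds require uniform class sizes and R a power of two")
  regime <- detect_regime(params, regime)
  p <- params$p; q <- params$q; s <- params$s
  a <- params$a; A <- 2^a
  n <- params$class_sizes[1L]
  vals <- if (d == 0) {
    full_split_ok <- isTRUE(all.equal(log2(n), round(log2(n))))
    list(R_opt = params$N,
         h0_opt = if (full_split_ok)
           as.numeric(expected_hierarchy(params, 0, b = -as.integer(round(log2(n)))))
         else NA_real_,
         lower_bound = 0.5)
  } else if (d == 1 && regime == "twitter") {
    barg <- (2 * A^2 * s + 6 * (q - p)) / (3 * q - s)
    list(s_m = (6 * (A - 1) * p - 3 * (A - 2) * q) / (A - A^2 + A^3),
         s_2 = 3 * ((A^2 - 12) * q + 12 * p) / (7 * A^2),
         b_star = if (is.finite(barg) && barg > 0) log2(barg) / 2
         else NA_real_)
  } else if (d == 1 && regime == "military") {
    list(s_i = 12 * p / (3 * A + 2 * A^2 - 2),
         s_1 = s_planted_zero(params, 1),
         s_3_i = 12 * p / A^2,
         b_i_star = if (s > 0) log2(2 * p / s) / 2 else NA_real_)
  } else if (d == 2 && regime == "twitter") {
    b2 <- if (s > 0) {
      opt <- optimize(function(bb) candidate_hierarchy(params, 2, bb),
                      interval = c(0, a), maximum = TRUE, tol = 1e-10)
      opt$maximum
    } else NA_real_
    list(s_2m = 6 * (2 * (q - p) / A + 2 * p - q) /
           (2 * A^3 + A^2 - 3 * A + 4),
         s_21 = (A^2 * q + 4 * p - 4 * q) / (3 * A^2),
         b_2star = b2)
  } else {
    list(s_21_0 = 12 * p / (A * (A^2 + 5 * A + 4)),
         s_22_i = 12 * p / A^2,
         s_23_i = 36 * p / A^2,
         b_2i_star = if (s > 0) log2(6 * p / s) / 2 else NA_real_)
  }
  structure(list(d = d, regime = regime, values = vals,
                 s_max = params$s_max),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("Resolution thresholds (d = ", x$d, ", ", x$regime,
      " regime)\n", sep = "")
  for (nm in names(x$values))
    cat("  ", format(nm, width = 10), " = ",
        format(signif(x$values[[nm]], 6)), "\n", sep = "")
  cat("  ", format("s_max", width = 10), " = ",
      format(signif(x$s_max, 6)), "\n", sep = "")
  invisible(x)
}

#' Best candidate ranking by expected hierarchy
#'
#' Scans the candidate family (direct and inverted rankings with
#' `2^(a-b)` uniform classes, integer `b` from full merge down to the
#' deepest admissible split) with the expectation oracle and returns the
#' candidate maximising the first-order expected hierarchy. Ties prefer
#' the direct, less-modified candidate, so the planted ranking wins below
#' threshold.
#'
#' @param params an [rsbm()] parameter object (uniform sizes, `R = 2^a`).
#' @param d penalty exponent.
#' @param max_split deepest split exponent to scan (default: full split
#'   when the class size is a power of two, else no splits).
#' @return a list with `b`, `inverted`, `R_tilde`, `estimate` and `scan`
#'   (a data frame of every candidate evaluated).
#' @examples
#' optimal_candidate(rsbm(0.5, 0.5, 0.0005, 16, 16), d = 1)$R_tilde # 16
#' @export
optimal_candidate <- function(params, d = 1, max_split = NULL) {
  stopifnot(inherits(params, "rsbm"))
  check_d(d)
  if (!params$uniform || is.na(params$a))
    stop("the candidate scan requires uniform sizes and R a power of two")
  a <- params$a
  n <- params$class_sizes[1L]
  if (is.null(max_split)) {
    l2n <- log2(n)
    max_split <- if (isTRUE(all.equal(l2n, round(l2n))))
      as.integer(round(l2n)) else 0L
  }
  bs <- seq.int(a, -max_split)
  rows <- list()
  for (b in bs) {
    for (inv in c(FALSE, TRUE)) {
      if (b == a && inv) next # trivial ranking has no distinct inversion
      est <- expected_hierarchy(params, d = d, b = b, inverted = inv)
      rows[[length(rows) + 1L]] <-
        data.frame(b = b, inverted = inv,
                   R_tilde = attr(est, "R_tilde"),
                   estimate = as.numeric(est))
    }
  }
  scan <- do.call(rbind, rows)
  ord <- order(-scan$estimate, scan$inverted, abs(scan$b))
  best <- scan[ord[1L], ]
  list(b = best$b, inverted = best$inverted, R_tilde = best$R_tilde,
       estimate = best$estimate, scan = scan)
}
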