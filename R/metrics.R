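#' Adjusted Rand index between two rankings
#'
#' Hubert-Arabie adjusted Rand index (permutation-model expectation)
#' between the partitions induced by two rankings of the same node set.
#' Class order is ignored, so a ranking and its inversion have index 1;
#' use [rank_alignment()] to detect inversions.
#'
#' @param r1,r2 rankings (named integer vectors) over the same node set.
#' @return the adjusted Rand index (1 for identical partitions, about 0
#'   for independent ones; can be negative).
#' @examples
#' adjusted_rand_index(c(a = 1, b = 1, c = 2), c(a = 2, b = 2, c = 1))
#' @export
adjusted_rand_index <- function(r1, r2) {
  al <- align_rankings(r1, r2)
  tab <- table(al$r1, al$r2)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n2 <- choose(n, 2)
  expected <- sum_a * sum_b / n2
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1) # both partitions degenerate-identical
  (sum_ij - expected) / (maximum - expected)
}

align_rankings <- function(r1, r2) {
  r1 <- as_ranking(r1)
  r2 <- as_ranking(r2)
  if (length(r1) != length(r2) || !setequal(names(r1), names(r2)))
    stop("rankings must cover the same node set")
  list(r1 = unname(r1), r2 = unname(r2[names(r1)]))
}

#' Rank alignment (inversion detector)
#'
#' Kendall rank correlation between the class labels two rankings assign
#' to the same nodes. Values near 1 indicate the same class order, values
#' near -1 an inverted hierarchy — which the adjusted Rand index cannot
#' see. When either ranking is constant (a single class) the correlation
#' is undefined; 0 is returned with attribute `degenerate = TRUE`.
#'
#' @inheritParams adjusted_rand_index
#' @return correlation in `[-1, 1]`.
#' @examples
#' rank_alignment(c(a = 1, b = 2, c = 3), c(a = 3, b = 2, c = 1)) # -1
#' @export
rank_alignment <- function(r1, r2) {
  al <- align_rankings(r1, r2)
  if (length(unique(al$r1)) < 2L || length(unique(al$r2)) < 2L) {
    warning("constant ranking: alignment undefined, returning 0")
    return(structure(0, degenerate = TRUE))
  }
  cor(al$r1, al$r2, method = "kendall")
}

#' Planted-vs-inferred contingency counts
#'
#' The heat-map matrix of the numerical experiments: entry (i, j) is the
#' number of nodes in planted class i placed in inferred class j. Row sums
#' are the planted class sizes, column sums the inferred ones, and the
#' grand total is N.
#'
#' @param planted,inferred rankings over the same node set.
#' @return an integer matrix with planted classes as rows.
#' @export
contingency_counts <- function(planted, inferred) {
  al <- align_rankings(planted, inferred)
  m <- as.matrix(table(planted = al$r1, inferred = al$r2))
  storage.mode(m) <- "integer"
  m
}

#' Write a contingency heat map as CSV
#'
#' @param counts a matrix from [contingency_counts()].
#' @param path output CSV path (planted classes as rows).
#' @return `path`, invisibly.
#' @export
write_heatmap_csv <- function(counts, path) {
  write.table(counts, path, sep = ",", quote = FALSE,
              row.names = TRUE, col.names = NA)
  invisible(path)
}
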