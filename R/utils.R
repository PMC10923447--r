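# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad <- function(...) stop(..., call. = FALSE)

assert_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_bad(what, " must lie in [0, 1]")
  invisible(x)
}

assert_counts <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x != round(x)))
    stop_bad(what, " must be non-negative integers")
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples;
#' 1 for identical partitions (up to relabeling), ~0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return A number in (-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_bad("label vectors differ in length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

# biased (1/n) column variances, the form used by the clustering distance
biased_var <- function(x) {
  n <- nrow(x)
  colMeans(x^2) - colMeans(x)^2
}

# sample skewness g1 = m3 / m2^(3/2)
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m3 / m2^1.5
}

# deterministic 32-bit child seed for cohort-level RNG streams
child_seed <- function(root, index) {
  as.integer((as.numeric(root) * 10007 + 7919 * index) %% 2147483647L)
}
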