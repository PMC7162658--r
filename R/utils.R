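#' @useDynLib fingermatch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor cutree hclust mad median pt qt quantile rnorm runif
#'   runmed sd var
#' @importFrom utils head read.csv tail write.csv
NULL

stop_invalid <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_count <- function(x, field, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop_invalid(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

check_nonneg <- function(x, field) {
  if (length(x) != 1L || !is.finite(x) || x < 0)
    stop_invalid(field, "must be a single non-negative number")
  as.numeric(x)
}

check_pos <- function(x, field) {
  if (length(x) != 1L || !is.finite(x) || x <= 0)
    stop_invalid(field, "must be a single positive number")
  as.numeric(x)
}

#' Adjusted Rand index between two labellings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions (up to relabelling), about 0 for independent
#' ones. Used to score recovery of planted cluster structure.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A single number in (-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("labellings must have equal length")
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

# Derive a stream-specific 32-bit seed from a base seed; keeps independent
# stages decoupled while remaining reproducible from one integer.
derive_seed <- function(seed, stream) {
  # double arithmetic: chained derivations overflow 32-bit integers
  as.integer((as.numeric(seed) * 1009 + as.numeric(stream) * 9973) %%
               2147483647)
}
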