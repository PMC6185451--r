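# Small shared helpers.

#' Area under the ROC curve for a score against binary truth
#'
#' Rank-based (Mann-Whitney) AUROC; ties get midranks. Higher scores are
#' expected for positives.
#'
#' @param score numeric vector of scores.
#' @param truth logical vector (or 0/1) of the same length.
#' @return AUROC in \[0, 1\], or `NA` if either class is empty.
#' @export
auroc <- function(score, truth) {
  truth <- as.logical(truth)
  ok <- !is.na(score) & !is.na(truth)
  score <- score[ok]; truth <- truth[ok]
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b factors or vectors interpretable as cluster labels.
#' @return the adjusted Rand index (1 = identical partitions, ~0 = random).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (maximum - expected)
}

# Derive a stream of child seeds from one master seed, staying below 2^31.
derive_seeds <- function(seed, n) {
  (as.integer(seed) + 1000003L * seq_len(n)) %% 2147483629L
}

ildqc_msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message("[ildqc] ", ...)
}
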