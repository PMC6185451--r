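# Composite genotypic linkage disequilibrium for a pair of unphased
# biallelic loci, from the 3x3 table of joint genotype counts.
#
# With minor-allele copy counts gA, gB in {0,1,2}, the table is
#
#            B/B  B/b  b/b        (gB = 2, 1, 0)
#   A/A  n1   n2   n3             (gA = 2)
#   A/a  n4   n5   n6             (gA = 1)
#   a/a  n7   n8   n9             (gA = 0)
#
# and the ML-weighted count of AB gametes is sigma_AB = 2 n1 + n2 + n4 + n5/2,
# equivalently sum_i gA_i * gB_i / 2 over complete samples. The composite
# disequilibrium is D_AB = sigma_AB / n - 2 pA pB.

#' Cross-tabulate joint genotypes of two loci
#'
#' Samples missing at either locus are dropped (pairwise deletion).
#'
#' @param genotypes_a,genotypes_b equal-length vectors of minor-allele copy
#'   counts (0/1/2, `NA` missing) from one population.
#' @return a 3x3 integer matrix of counts; rows are genotypes A/A, A/a, a/a
#'   (2, 1, 0 copies), columns B/B, B/b, b/b.
#' @export
cross_tab <- function(genotypes_a, genotypes_b) {
  stopifnot(length(genotypes_a) == length(genotypes_b))
  ok <- !is.na(genotypes_a) & !is.na(genotypes_b)
  a <- factor(genotypes_a[ok], levels = c(2, 1, 0))
  b <- factor(genotypes_b[ok], levels = c(2, 1, 0))
  tab <- table(a, b)
  dimnames(tab) <- list(A = c("A/A", "A/a", "a/a"), B = c("B/B", "B/b", "b/b"))
  m <- matrix(as.integer(tab), 3L, 3L, dimnames = dimnames(tab))
  m
}

#' Maximum-likelihood AB-gamete count from a 3x3 genotype table
#'
#' `sigma_AB = 2 n1 + n2 + n4 + n5/2`: double homozygotes for the minor
#' alleles contribute two AB gametes, single-het cells one, and the double
#' heterozygote (phase unknown) one half.
#'
#' @param tab 3x3 table from [cross_tab()].
#' @return the (possibly half-integer) AB-gamete count.
#' @export
sigma_ab <- function(tab) {
  2 * tab[1L, 1L] + tab[1L, 2L] + tab[2L, 1L] + tab[2L, 2L] / 2
}

#' Composite disequilibrium and allele frequencies for one table
#'
#' @param tab 3x3 table from [cross_tab()].
#' @return list with `sigma_ab`, `n`, `p_a`, `p_b`, `d_ab`
#'   (`= sigma_ab/n - 2 p_a p_b`), and the within-locus Hardy-Weinberg
#'   disequilibrium coefficients `d_a`, `d_b` (homozygote excess).
#' @export
pair_stats <- function(tab) {
  n <- sum(tab)
  if (n == 0L) stop("empty table: all samples missing at one locus")
  s <- sigma_ab(tab)
  p_a <- (2 * sum(tab[1L, ]) + sum(tab[2L, ])) / (2 * n)
  p_b <- (2 * sum(tab[, 1L]) + sum(tab[, 2L])) / (2 * n)
  d_a <- sum(tab[1L, ]) / n - p_a^2
  d_b <- sum(tab[, 1L]) / n - p_b^2
  list(sigma_ab = s, n = n, p_a = p_a, p_b = p_b,
       d_ab = s / n - 2 * p_a * p_b, d_a = d_a, d_b = d_b)
}

#' Chi-square (T2) approximate p-value for composite LD
#'
#' `T2 = n D_AB^2 / ((pA(1-pA) + D_A)(pB(1-pB) + D_B))` referred to a
#' chi-square with 1 df; `D_A`, `D_B` correct the variance for within-locus
#' departure from Hardy-Weinberg. The denominator is floored at 1e-12; a
#' degenerate (monomorphic) table returns p = 1 with a warning.
#'
#' @param tab 3x3 table from [cross_tab()].
#' @return two-sided approximate p-value.
#' @export
t2_pvalue <- function(tab) {
  st <- pair_stats(tab)
  va <- st$p_a * (1 - st$p_a) + st$d_a
  vb <- st$p_b * (1 - st$p_b) + st$d_b
  denom <- va * vb
  if (denom <= 1e-12) {
    warning("degenerate table in T2 (monomorphic locus); p = 1")
    return(1)
  }
  t2 <- st$n * st$d_ab^2 / denom
  stats::pchisq(t2, df = 1L, lower.tail = FALSE)
}

#' One-tailed exact p-value for positive association of minor alleles
#'
#' The 3x3 genotype table is collapsed to carrier status (at least one minor
#' allele at each locus) and the enrichment of double carriers is tested
#' against the hypergeometric null with fixed margins; smaller p means more
#' double carriers than expected. Degenerate margins give p = 1.
#'
#' @param tab 3x3 table from [cross_tab()].
#' @return one-tailed exact p-value in (0, 1\].
#' @export
exact_pvalue_positive <- function(tab) {
  n <- sum(tab)
  carriers_a <- n - sum(tab[3L, ])
  carriers_b <- n - sum(tab[, 3L])
  x <- sum(tab[1:2, 1:2])
  carrier_test_p(x, carriers_a, carriers_b, n)
}

# Upper-tail hypergeometric p for x double carriers given margins.
# Vectorized; degenerate margins -> 1.
carrier_test_p <- function(x, m_a, m_b, n) {
  p <- stats::phyper(x - 1, m_a, n - m_a, m_b, lower.tail = FALSE)
  degen <- m_a <= 0L | m_b <= 0L | m_a >= n | m_b >= n
  p[degen] <- 1
  pmin(p, 1)
}

#' Combine per-population p-values with Fisher's method
#'
#' `-2 sum(log p)` referred to chi-square with `2k` df; p-values are floored
#' at machine epsilon before taking logs.
#'
#' @param p_list numeric vector of p-values in (0, 1\], one per population
#'   where the pair is testable.
#' @return the combined p-value.
#' @export
combine_pvalues <- function(p_list) {
  p_list <- p_list[!is.na(p_list)]
  if (length(p_list) == 0L) stop("no p-values to combine: pair untestable")
  p_list <- pmax(p_list, .Machine$double.eps)
  stat <- -2 * sum(log(p_list))
  stats::pchisq(stat, df = 2L * length(p_list), lower.tail = FALSE)
}
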