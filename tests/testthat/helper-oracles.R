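# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: brute-force enumeration, direct summation, or
# Monte-Carlo at small n.

# Eq-weight oracle for the AB-gamete count: per-sample gamete reasoning.
# (2,2): both gametes are AB -> 2. (2,1)/(1,2): exactly one AB -> 1.
# (1,1): phase unresolved, AB/ab and Ab/aB equally likely -> 1/2.
# Any genotype with a zero: no AB gamete can be certain -> 0.
oracle_sigma_ab <- function(ga, gb) {
  w <- function(a, b) {
    if (a == 2L && b == 2L) return(2)
    if ((a == 2L && b == 1L) || (a == 1L && b == 2L)) return(1)
    if (a == 1L && b == 1L) return(0.5)
    0
  }
  ok <- !is.na(ga) & !is.na(gb)
  sum(mapply(w, ga[ok], gb[ok]))
}

# Full hypergeometric enumeration for the one-tailed carrier test:
# P(X >= x) with margins m_a, m_b out of n, summed cell by cell from
# log-factorials (no phyper).
oracle_carrier_p <- function(x, m_a, m_b, n) {
  if (m_a <= 0 || m_b <= 0 || m_a >= n || m_b >= n) return(1)
  ks <- max(0, m_a + m_b - n):min(m_a, m_b)
  logp <- lchoose(m_a, ks) + lchoose(n - m_a, m_b - ks) - lchoose(n, m_b)
  sum(exp(logp[ks >= x]))
}

# Chi-square upper tail by numerical integration of the density.
oracle_chisq_upper <- function(stat, df) {
  stats::integrate(function(x) stats::dchisq(x, df), lower = stat,
                   upper = Inf, rel.tol = 1e-10)$value
}

# Step-up BH by the textbook recipe (sort, m*p/i, cummin from the top).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- rev(cummin(rev(m * p[o] / seq_len(m))))
  pmin(q, 1)[order(o)]
}

# Monte-Carlo heterozygote-count distribution under random gamete pairing.
oracle_hwe_excess_mc <- function(n_aa, n_ab, n_bb, reps = 20000L, seed = 42L) {
  n <- n_aa + n_ab + n_bb
  alleles <- rep(0:1, c(2L * n_aa + n_ab, 2L * n_bb + n_ab))
  het_ge <- ildqc:::with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      s <- sample(alleles)
      sum(s[seq(1, 2 * n, 2)] != s[seq(2, 2 * n, 2)]) >= n_ab
    }, logical(1L))
  })
  mean(het_ge)
}

# Random 3x3 genotype table with n samples and given MAFs, with an optional
# shared binary batch driving positive association.
random_geno_pair <- function(n, p_a, p_b, batch_frac = 0, seed = 1L) {
  ildqc:::with_seed(seed, {
    ga <- stats::rbinom(n, 2L, p_a)
    gb <- stats::rbinom(n, 2L, p_b)
    if (batch_frac > 0) {
      hit <- seq_len(ceiling(batch_frac * n))
      ga[hit] <- pmax(ga[hit], 1L)
      gb[hit] <- pmax(gb[hit], 1L)
    }
    list(ga = ga, gb = gb)
  })
}
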