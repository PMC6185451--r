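# Per-individual contribution to the linkage signal. For a linked pair with
# positive composite D, a sample contributes the Eq.-weight of its joint
# genotype: 2 for (A/A, B/B), 1 for (A/A, B/b) or (A/a, B/B), 1/2 for the
# double heterozygote, 0 otherwise -- identically gA * gB / 2 for
# minor-allele copy counts. Summing contributions over samples recovers
# sigma_AB of each pair exactly.

#' Per-sample contribution (nAB) to the linkage signal
#'
#' @param gm a [genotype_matrix()].
#' @param links a [link_set()] or any data.frame with variant-index columns
#'   `i` and `j`.
#' @return an object of class `nab_profile`: data.frame with `sample_id`,
#'   `population`, `nab`, and globally z-transformed `z_nab`; the pair set
#'   used is kept as attribute `pairs`.
#' @export
compute_nab <- function(gm, links) {
  g <- gm$genotypes
  n <- nrow(g)
  nab <- numeric(n)
  if (is.null(links) || nrow(links) == 0L) {
    warning("empty link set: nAB profile is all zeros")
  } else {
    ga <- g[, links$i, drop = FALSE]
    gb <- g[, links$j, drop = FALSE]
    w <- ga * gb / 2
    w[is.na(w)] <- 0
    nab <- rowSums(w)
  }
  z <- if (stats::sd(nab) > 0) as.numeric(scale(nab)) else rep(0, n)
  structure(
    data.frame(sample_id = gm$samples$sample_id,
               population = gm$samples$population,
               nab = nab, z_nab = z, stringsAsFactors = FALSE),
    class = c("nab_profile", "data.frame"),
    pairs = if (is.null(links)) NULL else links[, c("i", "j")])
}

# nAB profiles on permuted matrices, using the same pair set.
permuted_nab <- function(gm, links, n_perm = 3L, seed = 1L) {
  seeds <- derive_seeds(seed + 7L, n_perm)
  lapply(seq_len(n_perm), function(r)
    suppressWarnings(compute_nab(permute_chromosomes(gm, seeds[r]), links)))
}

#' Test for excess variance of nAB against permuted profiles
#'
#' Per population, the ratio of the observed nAB variance to the mean
#' variance across permutation replicates, with a one-tailed one-sample
#' t-test of the replicate variances against the observed value
#' (alternative: permuted < observed). Population results are combined with
#' Fisher's method.
#'
#' @param profile an observed `nab_profile`.
#' @param permuted list of permuted `nab_profile`s (>= 3 for the t-test).
#' @return list with `by_population` (data.frame: population, ratio, p) and
#'   the Fisher-combined `p`.
#' @export
nab_variance_test <- function(profile, permuted) {
  stopifnot(length(permuted) >= 2L)
  pops <- sort(unique(profile$population))
  res <- lapply(pops, function(pp) {
    obs <- profile$nab[profile$population == pp]
    v_obs <- stats::var(obs)
    v_perm <- vapply(permuted, function(q) stats::var(q$nab[q$population == pp]),
                     numeric(1L))
    if (!is.finite(v_obs) || v_obs == 0 || all(v_perm == 0)) {
      warning(sprintf("population %s: degenerate nAB variance; test skipped", pp))
      return(data.frame(population = pp, ratio = NA_real_, p = NA_real_))
    }
    ratio <- v_obs / mean(v_perm)
    p <- if (stats::sd(v_perm) == 0) {
      # all permuted variances identical: rank-based fallback
      if (v_obs > v_perm[1L]) 1 / (length(v_perm) + 1) else 1
    } else {
      stats::t.test(v_perm, mu = v_obs, alternative = "less")$p.value
    }
    data.frame(population = pp, ratio = ratio, p = p)
  })
  by_pop <- do.call(rbind, res)
  p_comb <- if (all(is.na(by_pop$p))) NA_real_ else
    combine_pvalues(by_pop$p[!is.na(by_pop$p)])
  list(by_population = by_pop, p = p_comb)
}
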