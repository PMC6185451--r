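# Empirical null for the pair scan: within each population, the per-sample
# diploid genotype vectors of each chromosome are independently permuted
# across the population's samples. Within-chromosome structure (frequencies,
# heterozygosity, local LD) is preserved exactly; cross-chromosome
# association is destroyed.

#' Permute chromosomes across individuals within populations
#'
#' @param gm a [genotype_matrix()].
#' @param seed integer seed; identical seeds give identical permutations.
#' @return a `genotype_matrix` with permuted genotypes.
#' @export
permute_chromosomes <- function(gm, seed = 1L) {
  g <- gm$genotypes
  chroms <- unique(gm$variants$chrom)
  pops <- sort(unique(gm$samples$population))
  with_seed(seed, {
    for (p in pops) {
      rows <- which(gm$samples$population == p)
      if (length(rows) < 2L) next
      for (ch in chroms) {
        cols <- which(gm$variants$chrom == ch)
        perm <- sample.int(length(rows))
        g[rows, cols] <- g[rows[perm], cols, drop = FALSE]
      }
    }
  })
  out <- gm
  out$genotypes <- g
  out
}

#' Empirical FDR from permutation replicates
#'
#' For each observed p-value t, `FDR(t)` is the mean over replicates of the
#' number of permuted p-values at or below t, divided by the number of
#' observed p-values at or below t, clipped to \[0, 1\] and made monotone
#' non-increasing as t decreases (each pair is assigned the best rate
#' achievable at or above its own p).
#'
#' @param observed_p numeric vector of observed p-values (the full scan).
#' @param permuted_p_replicates list of numeric vectors, one per permutation
#'   replicate.
#' @param eval_p p-values at which to evaluate the FDR (default: each
#'   observed p).
#' @return numeric vector of FDR values aligned with `eval_p`.
#' @export
empirical_fdr <- function(observed_p, permuted_p_replicates, eval_p = observed_p) {
  stopifnot(length(permuted_p_replicates) >= 1L)
  obs_sorted <- sort(observed_p)
  perm_sorted <- lapply(permuted_p_replicates, sort)
  ord <- order(eval_p)
  t_sorted <- eval_p[ord]
  n_obs <- findInterval(t_sorted, obs_sorted)  # count <= t (ties included)
  counts <- vapply(perm_sorted, function(s) findInterval(t_sorted, s),
                   numeric(length(t_sorted)))
  n_perm <- rowMeans(matrix(counts, nrow = length(t_sorted)))
  raw <- ifelse(n_obs == 0L, 1, pmin(n_perm / pmax(n_obs, 1L), 1))
  # monotone: FDR at t is the minimum raw rate over thresholds >= t
  mono <- rev(cummin(rev(raw)))
  out <- numeric(length(eval_p))
  out[ord] <- mono
  out
}

#' Run the pair scan with its permutation null and attach empirical FDR
#'
#' Runs [scan_pairs()] on the data and on `n_perm` chromosome-permuted
#' replicates (same scan settings), then computes the per-pair empirical FDR
#' for the reported pairs.
#'
#' @param gm a [genotype_matrix()].
#' @param n_perm number of permutation replicates (default 3; a handful is
#'   sufficient because every replicate contributes millions of null pairs).
#' @param seed master seed for the permutations.
#' @param ... further arguments passed to [scan_pairs()].
#' @return the observed `pair_scan` with an `fdr` column added to `$pairs`
#'   and the permutation settings recorded.
#' @export
scan_with_null <- function(gm, n_perm = 3L, seed = 1L, ...) {
  scan <- scan_pairs(gm, ...)
  seeds <- derive_seeds(seed, n_perm)
  perm_p <- vector("list", n_perm)
  for (r in seq_len(n_perm)) {
    perm <- permute_chromosomes(gm, seed = seeds[r])
    perm_p[[r]] <- scan_pairs(perm, ...)$p_sorted
  }
  scan$pairs$fdr <- if (nrow(scan$pairs))
    empirical_fdr(scan$p_sorted, perm_p, eval_p = scan$pairs$p_final)
  else numeric(0)
  scan$n_perm <- n_perm
  scan$perm_seed <- seed
  scan
}

#' Define the significant link set
#'
#' Pairs with empirical FDR at or below the cutoff and positive composite
#' disequilibrium.
#'
#' @param scan a `pair_scan` with an `fdr` column (see [scan_with_null()]).
#' @param fdr_cutoff FDR cutoff (default 0.05; 0.20 is the low-power
#'   setting).
#' @return an object of class `link_set`: data.frame of linked pairs plus
#'   attributes `fdr_cutoff` and `p_threshold` (largest linked p).
#' @export
link_set <- function(scan, fdr_cutoff = 0.05) {
  stopifnot(inherits(scan, "pair_scan"), !is.null(scan$pairs$fdr))
  # a cutoff of 0 disables linking (empirical FDR can be exactly 0)
  keep <- fdr_cutoff > 0 & scan$pairs$fdr <= fdr_cutoff & scan$pairs$d_sum > 0
  links <- scan$pairs[keep, , drop = FALSE]
  structure(links,
            class = c("link_set", "data.frame"),
            fdr_cutoff = fdr_cutoff,
            p_threshold = if (nrow(links)) max(links$p_final) else NA_real_)
}
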