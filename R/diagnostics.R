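# Genotype- and depth-based characterization of flagged candidates against
# frequency-matched background variants. Recurrent false heterozygotes leave
# two signatures: heterozygote excess relative to Hardy-Weinberg, and allele
# imbalance of read support at heterozygous calls.

#' Exact one-tailed test for heterozygote excess under Hardy-Weinberg
#'
#' Conditional on the observed allele counts, the number of heterozygotes
#' follows the Levene-Haldane distribution; the one-tailed p-value sums the
#' probabilities of heterozygote counts at or above the observed one (same
#' parity). Monomorphic sites give p = 1.
#'
#' @param n_aa,n_ab,n_bb genotype counts (major hom, het, minor hom).
#' @return one-tailed p-value for heterozygote excess.
#' @export
hwe_excess_het_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  stopifnot(n > 0)
  n_minor <- 2L * n_bb + n_ab
  n_major <- 2L * n_aa + n_ab
  if (n_minor == 0L || n_major == 0L) return(1)
  rare <- min(n_minor, n_major)
  # het counts share the parity of the rare-allele count
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  logp <- lgamma(n + 1) - lgamma((n_minor - hets) / 2 + 1) -
    lgamma(hets + 1) - lgamma((n_major - hets) / 2 + 1) +
    hets * log(2) +
    lgamma(n_minor + 1) + lgamma(n_major + 1) - lgamma(2 * n + 1)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  min(sum(pr[hets >= n_ab]), 1)
}

#' Two-sided exact binomial test for allele imbalance
#'
#' Read support for the two alleles at a putatively heterozygous genotype is
#' tested against the 50/50 expectation.
#'
#' @param ref_depth,alt_depth read counts supporting each allele.
#' @return two-sided binomial p-value, or `NA` when total depth is 0.
#' @export
allele_imbalance_test <- function(ref_depth, alt_depth) {
  n <- ref_depth + alt_depth
  if (is.na(n) || n < 1) return(NA_real_)
  stats::binom.test(alt_depth, n, p = 0.5)$p.value
}

#' Transition/transversion summary of a variant set
#'
#' @param ref,alt character vectors of single-base alleles.
#' @return list with `transitions`, `transversions`, `ratio`, and the
#'   per-variant `is_transition` flags (`NA` for non-SNV rows, which are
#'   skipped).
#' @export
tstv_summary <- function(ref, alt) {
  purine <- c("A", "G")
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
  is_ts <- rep(NA, length(ref))
  is_ts[ok] <- (ref[ok] %in% purine) == (alt[ok] %in% purine)
  ts <- sum(is_ts, na.rm = TRUE)
  tv <- sum(!is_ts, na.rm = TRUE)
  list(transitions = ts, transversions = tv,
       ratio = if (tv > 0) ts / tv else NA_real_,
       is_transition = is_ts)
}

# Frequency-matched background: sample (without replacement, seeded) from
# non-candidate variants within 1%-wide MAF bins of the candidate set.
match_background <- function(maf, candidate_idx, ratio = 1L, seed = 1L,
                             bin_width = 0.01) {
  pool <- setdiff(seq_along(maf), candidate_idx)
  bins <- floor(maf / bin_width)
  picked <- integer(0)
  with_seed(seed, {
    for (b in unique(bins[candidate_idx])) {
      want <- ratio * sum(bins[candidate_idx] == b)
      avail <- pool[bins[pool] == b]
      if (length(avail))
        picked <- c(picked, avail[sample.int(length(avail),
                                             min(want, length(avail)))])
    }
  })
  sort(picked)
}

#' Characterize candidate variants against frequency-matched background
#'
#' For flagged candidates and a MAF-matched background set, computes the
#' exact heterozygote-excess p per variant, the transition/transversion
#' composition, and (when allelic depths are attached to the matrix) the
#' per-heterozygote allele-imbalance p-values.
#'
#' @param gm a [genotype_matrix()], optionally carrying `ad_ref`/`ad_alt`.
#' @param candidates a `candidate_table` from [candidate_scan()].
#' @param seed seed for background sampling.
#' @param background_ratio background variants per candidate (default 1).
#' @return a `diagnostic_report` list: `per_variant` data.frame (set,
#'   variant index, MAF, hwe_p, is_transition, median imbalance p) and a
#'   `summary` data.frame per set.
#' @export
diagnostic_report <- function(gm, candidates, seed = 1L,
                              background_ratio = 1L) {
  flagged_idx <- candidates$variant[candidates$flagged]
  if (!length(flagged_idx)) {
    message("no flagged candidates: diagnostic report empty")
    return(structure(list(per_variant = NULL, summary = NULL),
                     class = "diagnostic_report"))
  }
  maf <- gm$variants$maf
  bg_idx <- match_background(maf, flagged_idx, background_ratio, seed)
  have_ad <- !is.null(gm$ad_ref) && !is.null(gm$ad_alt)
  one_set <- function(idx, label) {
    hwe <- vapply(idx, function(v) {
      g <- gm$genotypes[, v]
      hwe_excess_het_test(sum(g == 0L, na.rm = TRUE),
                          sum(g == 1L, na.rm = TRUE),
                          sum(g == 2L, na.rm = TRUE))
    }, numeric(1L))
    imb <- rep(NA_real_, length(idx))
    if (have_ad) {
      imb <- vapply(idx, function(v) {
        het <- which(!is.na(gm$genotypes[, v]) & gm$genotypes[, v] == 1L &
                       !is.na(gm$ad_ref[, v]) & !is.na(gm$ad_alt[, v]) &
                       gm$ad_ref[, v] >= 1 & gm$ad_alt[, v] >= 1)
        if (!length(het)) return(NA_real_)
        stats::median(vapply(het, function(s)
          allele_imbalance_test(gm$ad_ref[s, v], gm$ad_alt[s, v]),
          numeric(1L)))
      }, numeric(1L))
    }
    ts <- tstv_summary(gm$variants$ref[idx], gm$variants$alt[idx])
    data.frame(set = label, variant = idx, maf = maf[idx], hwe_p = hwe,
               is_transition = ts$is_transition, imbalance_p = imb,
               stringsAsFactors = FALSE)
  }
  pv <- rbind(one_set(flagged_idx, "candidate"), one_set(bg_idx, "background"))
  summarize <- function(d) data.frame(
    set = d$set[1L], n = nrow(d),
    median_hwe_p = stats::median(d$hwe_p, na.rm = TRUE),
    frac_hwe_p_lt_05 = mean(d$hwe_p < 0.05, na.rm = TRUE),
    tstv_ratio = tstv_summary(gm$variants$ref[d$variant],
                              gm$variants$alt[d$variant])$ratio,
    median_imbalance_p = stats::median(d$imbalance_p, na.rm = TRUE))
  summ <- rbind(summarize(pv[pv$set == "candidate", ]),
                summarize(pv[pv$set == "background", ]))
  structure(list(per_variant = pv, summary = summ),
            class = "diagnostic_report")
}
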