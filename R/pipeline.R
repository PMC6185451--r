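# Full iterative method: one LD scan with its permutation null, then
# repeated step-2/step-3 rounds. Each round recomputes nAB on the link set
# purged of pairs containing previously flagged variants, tests whether the
# burden still differs between individuals (variance + clustering support
# against permuted profiles), and if so calls a new round of candidates.
# Flagged variants stay in the matrix (diagnostics can inspect them); only
# the link set used for nAB is cleansed.

#' Pipeline configuration
#'
#' @param fdr_cutoff empirical FDR cutoff for the link set (0.05 default;
#'   0.20 for low-power data).
#' @param n_perm_fdr permutation replicates for the pair-scan FDR
#'   (default 3).
#' @param n_perm_profile permutation replicates for the step-2 variance and
#'   clustering nulls (default 20; up to 100 as in large panels).
#' @param prescreen_alpha combined-p gate for the full mixed model (0.01).
#' @param q_cutoff BH q cutoff for flagging (0.05).
#' @param stop_alpha significance level of the step-2 tests governing
#'   iteration (0.05).
#' @param max_iterations maximum step-2/step-3 rounds (>= 1).
#' @param k_max maximum mixture components (9).
#' @param prescreen_mult,subsample passed to [scan_pairs()].
#' @param seed master seed for every stochastic step.
#' @param verbose print progress messages.
#' @return a list of settings for [run_pipeline()].
#' @export
pipeline_config <- function(fdr_cutoff = 0.05, n_perm_fdr = 3L,
                            n_perm_profile = 20L, prescreen_alpha = 0.01,
                            q_cutoff = 0.05, stop_alpha = 0.05,
                            max_iterations = 5L, k_max = 9L,
                            prescreen_mult = 100, subsample = 1,
                            seed = 1L, verbose = TRUE) {
  stopifnot(fdr_cutoff > 0, fdr_cutoff <= 1, max_iterations >= 1L,
            prescreen_alpha > 0, prescreen_alpha <= 1,
            q_cutoff > 0, q_cutoff <= 1, stop_alpha > 0, stop_alpha <= 1)
  as.list(environment())
}

#' Run the full iterative error-detection pipeline
#'
#' Step 1 (once): cross-chromosome composite-LD scan, permutation null,
#' empirical FDR, link set. Then iterate: compute nAB over the link set
#' (excluding pairs containing flagged variants), test variance excess and
#' clustering support against permuted profiles, and -- when both tests are
#' significant at `stop_alpha` -- scan all variants for association with
#' z(nAB) and flag candidates. Stops when the burden tests are no longer
#' significant, when an iteration flags nothing new, or at
#' `max_iterations`.
#'
#' @param gm a [genotype_matrix()].
#' @param config a [pipeline_config()].
#' @param scan optional precomputed result of [scan_with_null()] on `gm`
#'   (with matching settings); step 1 is skipped when supplied.
#' @return object of class `ildqc_result`: list with `scan`, `links`,
#'   `candidates` (all iterations pooled), `profiles`, `step2` (per-iteration
#'   test results), `mixtures`, `iterations`, `homogeneous` (TRUE when no
#'   links were found or burden tests were never significant), `config`.
#' @export
run_pipeline <- function(gm, config = pipeline_config(), scan = NULL) {
  v <- config$verbose
  if (is.null(scan))
    scan <- scan_with_null(gm, n_perm = config$n_perm_fdr, seed = config$seed,
                           prescreen_mult = config$prescreen_mult,
                           subsample = config$subsample)
  stopifnot(inherits(scan, "pair_scan"))
  links <- link_set(scan, fdr_cutoff = config$fdr_cutoff)
  ildqc_msg(sprintf("step 1: %d linked pair(s) at FDR <= %g",
                    nrow(links), config$fdr_cutoff), verbose = v)
  result <- list(scan = scan, links = links, candidates = NULL,
                 profiles = list(), step2 = list(), mixtures = list(),
                 iterations = 0L, homogeneous = TRUE, config = config)
  class(result) <- "ildqc_result"
  if (nrow(links) == 0L) {
    ildqc_msg("no significant links: dataset looks homogeneous", verbose = v)
    return(result)
  }
  flagged_vars <- integer(0)
  all_cand <- NULL
  for (it in seq_len(config$max_iterations)) {
    active <- links[!(links$i %in% flagged_vars) &
                      !(links$j %in% flagged_vars), , drop = FALSE]
    if (nrow(active) == 0L) {
      ildqc_msg("link set exhausted by flagged variants", verbose = v)
      break
    }
    profile <- compute_nab(gm, active)
    perm_profiles <- permuted_nab(gm, active,
                                  n_perm = max(3L, config$n_perm_fdr),
                                  seed = config$seed + it)
    vt <- nab_variance_test(profile, perm_profiles)
    pops <- sort(unique(profile$population))
    cluster_perm <- permuted_nab(gm, active, n_perm = config$n_perm_profile,
                                 seed = config$seed + 100L + it)
    fit_pop <- function(pr, pop_i, seed_off) {
      x <- pr$nab[pr$population == pop_i]
      tryCatch(fit_mixture(x, k_max = config$k_max,
                           seed = config$seed + seed_off),
               error = function(e) NULL)
    }
    obs_fits <- lapply(seq_along(pops), function(k)
      fit_pop(profile, pops[k], 200L + k))
    obs_stat <- vapply(obs_fits, function(f)
      if (is.null(f)) NA_real_ else clustering_stat(f), numeric(1L))
    perm_stat <- vapply(seq_along(cluster_perm), function(r)
      vapply(seq_along(pops), function(k) {
        f <- fit_pop(cluster_perm[[r]], pops[k], 300L + 17L * r + k)
        if (is.null(f)) NA_real_ else clustering_stat(f)
      }, numeric(1L)), numeric(length(pops)))
    perm_stat <- matrix(perm_stat, nrow = length(pops))
    ct <- clustering_support_test(obs_stat, perm_stat)
    result$profiles[[it]] <- profile
    result$mixtures[[it]] <- obs_fits
    result$step2[[it]] <- list(variance = vt, clustering = ct)
    ildqc_msg(sprintf(
      "iteration %d: variance ratio %s (p=%.3g), clustering p=%.3g",
      it, paste(signif(vt$by_population$ratio, 3), collapse = "/"),
      vt$p, ct$p), verbose = v)
    # proceed while at least one burden test is significant; stop when
    # neither is (NA counts as not significant)
    significant <- (!is.na(vt$p) && vt$p < config$stop_alpha) ||
      (!is.na(ct$p) && ct$p < config$stop_alpha)
    if (!significant) {
      ildqc_msg("neither burden test significant: stopping", verbose = v)
      break
    }
    result$homogeneous <- FALSE
    result$iterations <- it
    cand <- candidate_scan(gm, profile,
                           prescreen_alpha = config$prescreen_alpha,
                           q_cutoff = config$q_cutoff, iteration = it,
                           verbose = v)
    # variants flagged in earlier iterations are settled; drop their rows
    cand <- cand[!(cand$variant %in% flagged_vars), , drop = FALSE]
    new_flagged <- cand$variant[cand$flagged]
    # iteration 1 keeps the full genome-wide table; later rounds add only
    # their new discoveries (flag sets stay disjoint across iterations)
    all_cand <- rbind(all_cand,
                      if (it == 1L) cand else cand[cand$flagged, , drop = FALSE])
    ildqc_msg(sprintf("iteration %d: %d new flagged variant(s)", it,
                      length(new_flagged)), verbose = v)
    flagged_vars <- union(flagged_vars, new_flagged)
    if (length(new_flagged) == 0L) break
  }
  result$candidates <- all_cand
  result$flagged_variants <- flagged_vars
  result
}

#' @export
print.ildqc_result <- function(x, ...) {
  cat(sprintf("ildqc_result: %d linked pair(s), %d iteration(s), %d flagged variant(s)\n",
              nrow(x$links), x$iterations,
              length(x$flagged_variants %||% integer(0))))
  if (x$homogeneous) cat("  dataset homogeneous (no significant error burden)\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
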