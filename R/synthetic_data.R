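# Generators with known truth: clean unlinked HWE genotypes across
# chromosomes, and batch-structured recurrent false-heterozygote errors
# (the dominant error mode of mixed sequencing batches).

#' Draw a minor-allele frequency spectrum
#'
#' `"uniform"`: MAF ~ U(\[lo, hi\]) (common-variant regime, default
#' \[0.05, 0.5\]). `"sfs"`: density proportional to 1/x on \[lo, hi\]
#' (default \[0.01, 0.5\]), the neutral site-frequency spectrum -- a
#' parametric stand-in for resampling real panel genotypes, dominated by
#' rare variants as real data are.
#'
#' @param n number of variants.
#' @param spectrum `"uniform"` or `"sfs"`.
#' @param lo,hi frequency range; defaults depend on the spectrum.
#' @return numeric vector of MAFs in \[lo, hi\].
#' @export
draw_maf <- function(n, spectrum = c("uniform", "sfs"), lo = NULL, hi = 0.5) {
  spectrum <- match.arg(spectrum)
  if (is.null(lo)) lo <- if (spectrum == "uniform") 0.05 else 0.01
  stopifnot(lo > 0, hi <= 0.5, lo < hi)
  u <- stats::runif(n)
  switch(spectrum,
         uniform = lo + u * (hi - lo),
         sfs = lo * (hi / lo)^u)  # inverse CDF of density ~ 1/x
}

#' Simulate clean unlinked genotypes
#'
#' Per variant a MAF is drawn from the configured spectrum; diploid
#' genotypes are drawn under Hardy-Weinberg equilibrium independently per
#' sample and per chromosome, so there is no cross-chromosome association by
#' construction. Ref/alt alleles are assigned with a 2:1
#' transition:transversion ratio (human-like). One or more populations share
#' the same per-variant MAF.
#'
#' @param n_individuals samples per population (scalar, or named vector of
#'   population sizes).
#' @param n_variants total variant count, split evenly across chromosomes.
#' @param n_chrom number of chromosomes (default 10).
#' @param spectrum,lo,hi passed to [draw_maf()].
#' @param seed RNG seed; identical seeds give identical matrices.
#' @return a [genotype_matrix()] with the drawn MAF stored in
#'   `variants$sim_maf`.
#' @export
simulate_genotypes <- function(n_individuals = 100L, n_variants = 2000L,
                               n_chrom = 10L,
                               spectrum = c("uniform", "sfs"),
                               lo = NULL, hi = 0.5, seed = 1L) {
  spectrum <- match.arg(spectrum)
  if (is.null(names(n_individuals)))
    n_individuals <- stats::setNames(n_individuals,
      paste0("pop", seq_along(n_individuals)))
  n_total <- sum(n_individuals)
  with_seed(seed, {
    maf <- draw_maf(n_variants, spectrum, lo, hi)
    g <- matrix(stats::rbinom(n_total * n_variants, 2L,
                              rep(maf, each = n_total)),
                nrow = n_total, ncol = n_variants)
    # coded allele = realized minor allele (drawn MAFs near 0.5 can realize
    # a sample frequency above 0.5)
    flip <- colMeans(g) / 2 > 0.5
    g[, flip] <- 2L - g[, flip]
    is_transition <- stats::runif(n_variants) < 2 / 3
    ref <- sample(c("A", "C", "G", "T"), n_variants, replace = TRUE)
    transition_of <- c(A = "G", G = "A", C = "T", T = "C")
    transversions <- list(A = c("C", "T"), G = c("C", "T"),
                          C = c("A", "G"), T = c("A", "G"))
    alt <- ifelse(is_transition, transition_of[ref],
                  vapply(transversions[ref], sample, character(1L), size = 1L))
  })
  ci <- sort(rep_len(seq_len(n_chrom), n_variants))
  chrom <- sprintf("chr%02d", ci)  # zero-padded: lexicographic == numeric order
  pos <- stats::ave(ci, ci, FUN = seq_along)
  variants <- data.frame(chrom = chrom, pos = pos * 100L,
                         ref = ref, alt = unname(alt), sim_maf = maf,
                         stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n_total)),
    population = rep(names(n_individuals), n_individuals),
    stringsAsFactors = FALSE)
  genotype_matrix(g, variants, samples)
}

#' Inject batch-structured false-heterozygote errors
#'
#' A batch of individuals is selected; within it, a subset of affected
#' individuals receives recurrent errors: at each selected error site,
#' affected individuals with genotype 0 become heterozygous (genotype 1).
#' Genotypes already carrying the minor allele are left unchanged. The
#' injection is deterministic given the selected site and sample sets
#' (recurrent-error model of batch effects).
#'
#' @param gm a clean [genotype_matrix()].
#' @param batch_fraction fraction of individuals in the error batch
#'   (default 0.2).
#' @param affected_fraction fraction of the batch receiving errors
#'   (default 0.5).
#' @param error_site_fraction fraction of sites carrying the recurrent
#'   error (default 0.001).
#' @param seed RNG seed for the site/sample selection.
#' @return list with `gm` (modified matrix), `error_sites` (variant
#'   indices), `affected` and `batch` (sample ids), `n_changed`, and
#'   `error_rate` (realized per-site-per-individual rate).
#' @export
inject_errors <- function(gm, batch_fraction = 0.2, affected_fraction = 0.5,
                          error_site_fraction = 0.001, seed = 1L) {
  stopifnot(batch_fraction > 0, batch_fraction <= 1,
            affected_fraction > 0, affected_fraction <= 1,
            error_site_fraction > 0, error_site_fraction <= 1)
  n <- nrow(gm$genotypes); m <- ncol(gm$genotypes)
  with_seed(seed, {
    batch <- sort(sample.int(n, max(1L, round(batch_fraction * n))))
    affected <- sort(sample(batch, max(1L, round(affected_fraction *
                                                   length(batch)))))
    sites <- sort(sample.int(m, max(1L, round(error_site_fraction * m))))
  })
  g <- gm$genotypes
  block <- g[affected, sites, drop = FALSE]
  changeable <- !is.na(block) & block == 0L
  n_skipped <- sum(!is.na(block) & block > 0L)
  if (n_skipped > 0)
    message(sprintf("%d genotype(s) at error sites already carried the minor allele; left unchanged",
                    n_skipped))
  block[changeable] <- 1L
  g[affected, sites] <- block
  out <- genotype_matrix(g, gm$variants[, setdiff(names(gm$variants),
                                                  c("maf", "freq_class")),
                                        drop = FALSE],
                         gm$samples)
  out$samples$batch_truth <- gm$samples$sample_id %in%
    gm$samples$sample_id[batch]
  out$samples$affected_truth <- gm$samples$sample_id %in%
    gm$samples$sample_id[affected]
  list(gm = out, error_sites = sites,
       affected = gm$samples$sample_id[affected],
       batch = gm$samples$sample_id[batch],
       n_changed = sum(changeable),
       error_rate = sum(changeable) / (as.double(n) * m))
}
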