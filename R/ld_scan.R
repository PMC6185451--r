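# Vectorized cross-chromosome scan. For each population the per-pair
# composite-LD statistics are obtained from a handful of cross-products of
# the genotype matrix: sigma_AB over complete pairs is (G'G)/2 with missing
# genotypes zeroed, and the pairwise-complete allele frequencies and
# Hardy-Weinberg disequilibria come from analogous indicator cross-products.

# Linear indices (into an m x m matrix) of unordered cross-chromosome pairs.
cross_pair_index <- function(chrom) {
  m <- length(chrom)
  if (length(unique(chrom)) < 2L)
    stop("interchromosomal scan needs variants on >= 2 chromosomes")
  diffc <- outer(chrom, chrom, "!=")
  lin <- which(upper.tri(diffc) & diffc)
  i <- as.integer((lin - 1L) %% m + 1L)
  j <- as.integer((lin - 1L) %/% m + 1L)
  list(lin = lin, i = i, j = j, m = m)
}

# One-tailed (positive-association) approximate p-values for one population.
# Returns per-pair vectors aligned with idx; untestable pairs are NA.
pop_approx_scan <- function(G, idx, alternative = "positive") {
  n_samp <- nrow(G)
  G <- matrix(as.double(G), nrow(G), ncol(G))
  if (anyNA(G)) {
    not_na <- !is.na(G); storage.mode(not_na) <- "double"
    G0 <- G; G0[is.na(G0)] <- 0
    H <- (G == 2); H[is.na(H)] <- FALSE; storage.mode(H) <- "double"
    n_pair <- crossprod(not_na)[idx$lin]
    s_ab <- crossprod(G0)[idx$lin] / 2
    sum_a <- crossprod(G0, not_na)  # [a, b]: sum of gA over pairs complete at both
    sum_hom <- crossprod(H, not_na)
    p_a <- sum_a[idx$lin] / (2 * n_pair)
    p_b <- t(sum_a)[idx$lin] / (2 * n_pair)
    d_a <- sum_hom[idx$lin] / n_pair - p_a^2
    d_b <- t(sum_hom)[idx$lin] / n_pair - p_b^2
  } else {
    n_pair <- rep(n_samp, length(idx$lin))
    s_ab <- crossprod(G)[idx$lin] / 2
    pa <- colMeans(G) / 2
    hom <- colMeans(G == 2)
    da <- hom - pa^2
    p_a <- pa[idx$i]; p_b <- pa[idx$j]
    d_a <- da[idx$i]; d_b <- da[idx$j]
  }
  v_a <- p_a * (1 - p_a) + d_a
  v_b <- p_b * (1 - p_b) + d_b
  d_ab <- s_ab / n_pair - 2 * p_a * p_b
  t2 <- n_pair * d_ab^2 / pmax(v_a * v_b, 1e-12)
  z <- sign(d_ab) * sqrt(t2)
  if (alternative == "negative") z <- -z
  p1 <- stats::pnorm(z, lower.tail = FALSE)
  untestable <- n_pair == 0 | p_a <= 0 | p_a >= 1 | p_b <= 0 | p_b >= 1 |
    v_a <= 1e-12 | v_b <= 1e-12
  p1[untestable] <- NA_real_
  p1 <- pmax(p1, .Machine$double.xmin)
  list(p = p1, d_ab = d_ab, n = n_pair)
}

# Fisher-combine a pairs x populations matrix of p-values (NA = untestable).
fisher_combine_rows <- function(pmat) {
  pm <- pmax(pmat, .Machine$double.eps)
  lp <- log(pm)
  lp[is.na(lp)] <- 0
  k <- rowSums(!is.na(pmat))
  stat <- -2 * rowSums(lp)
  out <- stats::pchisq(stat, df = 2 * k, lower.tail = FALSE)
  out[k == 0L] <- NA_real_
  out
}

#' Scan all cross-chromosome variant pairs for composite LD
#'
#' Per population, a one-tailed approximate p-value for positive association
#' of minor alleles is computed for every cross-chromosome pair via the
#' chi-square T2 statistic (signed square root referred to the normal upper
#' tail); p-values are combined across populations with Fisher's method. For
#' pairs whose combined approximate p falls below `prescreen_mult / nSNP^2`
#' (default 100/nSNP^2), the one-tailed exact carrier test replaces the
#' approximation, again combined across populations.
#'
#' @param gm a [genotype_matrix()].
#' @param alternative `"positive"` (default) or `"negative"` minor-allele
#'   association.
#' @param prescreen_mult numerator of the exact-test prescreen threshold
#'   `prescreen_mult / nSNP^2`.
#' @param subsample optional fraction in (0, 1\] of cross-chromosome pairs to
#'   scan (seeded), for genome-scale inputs.
#' @param seed seed used when `subsample < 1`; recorded in the result.
#' @param p_report pairs with final p at or below this (or among the
#'   `top_min` smallest) are returned in the pair table; all final p-values
#'   are kept (sorted) for FDR computation.
#' @param top_min minimum number of top pairs to report.
#' @return an object of class `pair_scan`: a list with `pairs` (data.frame
#'   of reported pairs: indices, coordinates, per-pair `p_approx`,
#'   `p_exact`, `p_final`, sample-size-weighted composite-D sum `d_sum`),
#'   `p_sorted` (all final p-values, ascending, NAs dropped), `n_pairs`,
#'   `n_snp`, `prescreen_p`, `populations`, `seed`.
#' @export
scan_pairs <- function(gm, alternative = c("positive", "negative"),
                       prescreen_mult = 100, subsample = 1, seed = 1L,
                       p_report = 1e-3, top_min = 2000L) {
  alternative <- match.arg(alternative)
  chrom <- gm$variants$chrom
  idx <- cross_pair_index(chrom)
  if (subsample < 1) {
    keep <- with_seed(seed, sort(sample.int(length(idx$lin),
      size = max(1L, round(subsample * length(idx$lin))))))
    idx <- list(lin = idx$lin[keep], i = idx$i[keep], j = idx$j[keep],
                m = idx$m)
  }
  pops <- sort(unique(gm$samples$population))
  n_pair_total <- length(idx$lin)
  pmat <- matrix(NA_real_, n_pair_total, length(pops))
  d_sum <- numeric(n_pair_total)
  pop_rows <- lapply(pops, function(p) which(gm$samples$population == p))
  names(pop_rows) <- pops
  for (k in seq_along(pops)) {
    G <- gm$genotypes[pop_rows[[k]], , drop = FALSE]
    sc <- pop_approx_scan(G, idx, alternative)
    pmat[, k] <- sc$p
    d_sum <- d_sum + ifelse(is.na(sc$p), 0, sc$d_ab * sc$n)
  }
  p_comb <- fisher_combine_rows(pmat)

  n_snp <- ncol(gm$genotypes)
  thr <- prescreen_mult / n_snp^2
  sel <- which(!is.na(p_comb) & p_comb < thr)
  p_exact <- rep(NA_real_, n_pair_total)
  if (length(sel)) {
    for (s in sel) {
      a <- idx$i[s]; b <- idx$j[s]
      pe <- rep(NA_real_, length(pops))
      for (k in seq_along(pops)) {
        if (is.na(pmat[s, k])) next  # untestable in this population
        ga <- gm$genotypes[pop_rows[[k]], a]
        gb <- gm$genotypes[pop_rows[[k]], b]
        ok <- !is.na(ga) & !is.na(gb)
        n <- sum(ok)
        if (n == 0L) next
        ca <- ga[ok] > 0L; cb <- gb[ok] > 0L
        if (alternative == "negative") cb <- !cb
        pe[k] <- carrier_test_p(sum(ca & cb), sum(ca), sum(cb), n)
      }
      if (any(!is.na(pe))) p_exact[s] <- combine_pvalues(pe[!is.na(pe)])
    }
  }
  p_final <- ifelse(is.na(p_exact), p_comb, p_exact)

  ok <- which(!is.na(p_final))
  p_sorted <- sort(p_final[ok], method = "quick")
  cutoff <- max(p_report,
                if (length(p_sorted) > top_min) p_sorted[top_min] else 1)
  top <- ok[p_final[ok] <= cutoff]
  top <- top[order(p_final[top], idx$i[top], idx$j[top])]
  pairs <- data.frame(
    i = idx$i[top], j = idx$j[top],
    chrom_a = chrom[idx$i[top]], pos_a = gm$variants$pos[idx$i[top]],
    chrom_b = chrom[idx$j[top]], pos_b = gm$variants$pos[idx$j[top]],
    p_approx = p_comb[top], p_exact = p_exact[top], p_final = p_final[top],
    d_sum = d_sum[top],
    stringsAsFactors = FALSE)
  structure(list(pairs = pairs, p_sorted = p_sorted,
                 n_pairs = n_pair_total, n_snp = n_snp, prescreen_p = thr,
                 populations = pops, alternative = alternative,
                 seed = if (subsample < 1) seed else NA_integer_),
            class = "pair_scan")
}

#' @export
print.pair_scan <- function(x, ...) {
  cat(sprintf("pair_scan: %d cross-chromosome pairs over %d variants (%s tail)\n",
              x$n_pairs, x$n_snp, x$alternative))
  cat(sprintf("  exact-test prescreen threshold: %.3g; reported pairs: %d\n",
              x$prescreen_p, nrow(x$pairs)))
  invisible(x)
}

# Run `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
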