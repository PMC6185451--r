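# The central container: a samples x variants matrix of minor-allele counts
# (0/1/2, NA = missing) plus variant and sample metadata.

#' Construct a genotype matrix object
#'
#' The genotype matrix is the package's central container: an integer matrix
#' of minor-allele copy counts (0, 1, 2, or `NA` for missing) with samples in
#' rows and biallelic SNVs in columns, together with per-variant records
#' (chromosome, position, ref/alt alleles) and per-sample records (sample id,
#' population). Per-population minor-allele frequencies are computed over
#' non-missing genotypes and folded to \[0, 0.5\].
#'
#' @param genotypes integer matrix, samples x variants, values in
#'   `c(0, 1, 2, NA)` counting minor-allele copies.
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (one row per genotype column). Additional columns are preserved.
#' @param samples data.frame with columns `sample_id`, `population`
#'   (one row per genotype row).
#' @return An object of class `genotype_matrix` with per-population folded
#'   minor-allele frequencies in `x$pop_maf` (variants x populations) and a
#'   `maf` column (pooled minor-allele frequency) added to `x$variants`.
#' @export
genotype_matrix <- function(genotypes, variants, samples) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  stopifnot(nrow(genotypes) == nrow(samples),
            ncol(genotypes) == nrow(variants))
  vals <- genotypes[!is.na(genotypes)]
  if (length(vals) && (min(vals) < 0L || max(vals) > 2L))
    stop("genotypes must be 0, 1, 2 or NA (minor-allele copy counts)")
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos") %in% names(variants)),
            all(c("sample_id", "population") %in% names(samples)))
  rownames(genotypes) <- samples$sample_id
  obj <- structure(
    list(genotypes = genotypes, variants = variants, samples = samples),
    class = "genotype_matrix")
  obj$variants$maf <- fold_freq(pooled_freq(obj))
  obj$pop_maf <- pop_maf(obj)
  obj
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d samples x %d variants, %d chromosome(s), %d population(s)\n",
    nrow(x$genotypes), ncol(x$genotypes),
    length(unique(x$variants$chrom)), length(unique(x$samples$population))))
  nmiss <- sum(is.na(x$genotypes))
  if (nmiss > 0)
    cat(sprintf("  missing genotypes: %d (%.2f%%)\n", nmiss,
                100 * nmiss / length(x$genotypes)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$genotypes)

# Frequency of the coded (minor) allele over all non-missing genotypes.
pooled_freq <- function(gm) {
  colMeans(gm$genotypes, na.rm = TRUE) / 2
}

fold_freq <- function(f) pmin(f, 1 - f)

# Per-population frequency of the coded allele (unfolded), variants x pops.
pop_freq <- function(gm) {
  pops <- sort(unique(gm$samples$population))
  out <- vapply(pops, function(p) {
    colMeans(gm$genotypes[gm$samples$population == p, , drop = FALSE],
             na.rm = TRUE) / 2
  }, numeric(ncol(gm$genotypes)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L, dimnames = list(NULL, pops))
  colnames(out) <- pops
  out
}

# Folded per-population minor-allele frequency, in [0, 0.5].
pop_maf <- function(gm) {
  f <- pop_freq(gm)
  f[] <- fold_freq(f)
  f
}

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param samples,variants integer or logical indices (default: keep all).
#' @return a new `genotype_matrix` with frequencies recomputed.
#' @export
subset_genotypes <- function(x, samples = NULL, variants = NULL) {
  si <- if (is.null(samples)) seq_len(nrow(x$genotypes)) else samples
  vi <- if (is.null(variants)) seq_len(ncol(x$genotypes)) else variants
  genotype_matrix(x$genotypes[si, vi, drop = FALSE],
                  x$variants[vi, setdiff(names(x$variants), c("maf", "freq_class")),
                             drop = FALSE],
                  x$samples[si, , drop = FALSE])
}

#' Classify variants by population-specific minor-allele frequency
#'
#' A variant is `common` when its folded minor-allele frequency exceeds
#' `common_threshold` in at least one population; `rare` when it exceeds
#' `rare_threshold` in at least one population but is at or below
#' `common_threshold` in all; otherwise `below_threshold`.
#'
#' @param gm a `genotype_matrix`.
#' @param common_threshold,rare_threshold frequency cutoffs (defaults 0.05
#'   and 0.01).
#' @return `gm` with a `freq_class` factor column added to `gm$variants`.
#' @export
classify_maf <- function(gm, common_threshold = 0.05, rare_threshold = 0.01) {
  maf <- gm$pop_maf
  is_common <- apply(maf > common_threshold, 1L, any, na.rm = TRUE)
  is_rare <- !is_common & apply(maf > rare_threshold, 1L, any, na.rm = TRUE)
  cls <- rep("below_threshold", nrow(maf))
  cls[is_rare] <- "rare"
  cls[is_common] <- "common"
  gm$variants$freq_class <- factor(cls,
    levels = c("common", "rare", "below_threshold"))
  gm
}
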