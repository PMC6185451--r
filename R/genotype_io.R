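# VCF / TSV input-output. Parsing is delegated to VariantAnnotation; this
# layer restricts records to biallelic autosomal-style SNVs, fixes the minor
# allele from the pooled samples, and attaches population metadata.

GT_CODE <- c("0/0" = 0L, "0|0" = 0L,
             "0/1" = 1L, "1/0" = 1L, "0|1" = 1L, "1|0" = 1L,
             "1/1" = 2L, "1|1" = 2L,
             "./." = NA_integer_, ".|." = NA_integer_, "." = NA_integer_,
             "0" = 0L, "1" = 1L)

#' Read a population map
#'
#' Two-column TSV (`sample_id<TAB>population`, header optional). Populations
#' with fewer than `min_pop_size` samples are dropped.
#'
#' @param path TSV path.
#' @param min_pop_size minimum number of samples for a population to be
#'   analyzed (default 95, the size used for population-scale panels; set
#'   lower for small studies).
#' @return data.frame with columns `sample_id`, `population`.
#' @export
read_popmap <- function(path, min_pop_size = 95L) {
  pm <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = "character")
  if (ncol(pm) < 2L) stop("population map must have two columns")
  pm <- pm[, 1:2]
  names(pm) <- c("sample_id", "population")
  if (tolower(pm$sample_id[1L]) %in% c("sample", "sample_id", "id"))
    pm <- pm[-1L, ]  # header row
  if (anyDuplicated(pm$sample_id))
    stop("duplicate sample ids in population map")
  keep <- names(which(table(pm$population) >= min_pop_size))
  dropped <- setdiff(unique(pm$population), keep)
  if (length(dropped))
    message(sprintf("dropping %d population(s) with < %d samples: %s",
                    length(dropped), min_pop_size,
                    paste(dropped, collapse = ", ")))
  as.data.frame(pm[pm$population %in% keep, ])
}

#' Read multi-sample genotypes from a VCF
#'
#' Restricts to biallelic SNVs (single-base REF and ALT), recodes genotypes
#' as minor-allele copy counts with the minor allele determined once from
#' the pooled non-missing genotypes of the analyzed samples, and attaches
#' the population map. Samples absent from the map are dropped with a
#' warning; non-SNV or multiallelic records are skipped and counted.
#'
#' @param vcf_path path to a VCF 4.x file (plain or bgzipped).
#' @param popmap a data.frame as returned by [read_popmap()], or a path to
#'   the population-map TSV.
#' @param region_bed optional BED path (0-based half-open) restricting the
#'   variants analyzed.
#' @param min_pop_size passed to [read_popmap()] when `popmap` is a path.
#' @param keep_ad keep per-sample allelic depths (AD) for diagnostics when
#'   present in the VCF.
#' @return a [genotype_matrix()]; when `keep_ad = TRUE` and AD is present,
#'   elements `ad_ref` and `ad_alt` hold samples x variants depth matrices
#'   oriented so that `ad_alt` counts reads supporting the minor allele.
#' @export
read_genotypes <- function(vcf_path, popmap, region_bed = NULL,
                           min_pop_size = 95L, keep_ad = FALSE) {
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path)
  if (is.character(popmap)) popmap <- read_popmap(popmap, min_pop_size)
  vcf <- VariantAnnotation::readVcf(vcf_path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(altl)
  alt <- rep(NA_character_, length(ref))
  alt[n_alt == 1L] <- as.character(unlist(altl[n_alt == 1L]))
  snv <- n_alt == 1L & nchar(ref) == 1L & !is.na(alt) & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snv)
  if (n_skipped > 0)
    message(sprintf("skipping %d non-biallelic-SNV record(s)", n_skipped))
  if (!any(snv)) stop("no biallelic SNVs in VCF")
  vcf <- vcf[snv, ]
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  vcf_samples <- colnames(gt)
  common_samples <- intersect(vcf_samples, popmap$sample_id)
  if (length(common_samples) == 0L)
    stop("no overlap between VCF samples and population map")
  if (length(common_samples) < length(vcf_samples))
    warning(sprintf("dropping %d VCF sample(s) absent from the population map",
                    length(vcf_samples) - length(common_samples)))
  gt <- gt[, common_samples, drop = FALSE]

  g <- matrix(GT_CODE[gt], nrow = nrow(gt), dimnames = dimnames(gt))
  unknown <- !is.na(gt) & !(gt %in% names(GT_CODE))
  if (any(unknown)) {
    warning(sprintf("%d unrecognized GT value(s) set to missing", sum(unknown)))
    g[unknown] <- NA_integer_
  }
  g <- t(g)  # samples x variants

  variants <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr))[snv],
    pos = GenomicRanges::start(rr)[snv],
    ref = ref[snv], alt = alt[snv],
    stringsAsFactors = FALSE)

  if (!is.null(region_bed)) {
    keep <- bed_overlap(variants, region_bed)
    message(sprintf("BED restriction: keeping %d of %d variants",
                    sum(keep), length(keep)))
    g <- g[, keep, drop = FALSE]
    variants <- variants[keep, , drop = FALSE]
    if (!ncol(g)) stop("no variants left after BED restriction")
  }

  # Minor allele fixed once from the pooled analyzed samples.
  alt_freq <- colMeans(g, na.rm = TRUE) / 2
  flip <- !is.na(alt_freq) & alt_freq > 0.5
  g[, flip] <- 2L - g[, flip]
  variants$minor_is_alt <- !flip

  sm <- popmap[match(rownames(g), popmap$sample_id), , drop = FALSE]
  gm <- genotype_matrix(g, variants, sm)

  if (keep_ad) {
    ad <- VariantAnnotation::geno(vcf)$AD
    if (!is.null(ad)) {
      get_ad <- function(k) {
        if (is.array(ad) && length(dim(ad)) == 3L) {
          m <- ad[, , k, drop = TRUE]
        } else {
          m <- vapply(ad, function(x)
            if (length(x) >= k) as.numeric(x[[k]]) else NA_real_,
            numeric(1L))
          dim(m) <- dim(ad)[1:2]
        }
        # samples x variants, restricted to the analyzed samples
        t(m)[match(rownames(g), vcf_samples), , drop = FALSE]
      }
      ad1 <- get_ad(1L); ad2 <- get_ad(2L)
      gm$ad_ref <- ifelse(matrix(flip, nrow(g), ncol(g), byrow = TRUE), ad2, ad1)
      gm$ad_alt <- ifelse(matrix(flip, nrow(g), ncol(g), byrow = TRUE), ad1, ad2)
    }
  }
  gm
}

# BED is 0-based half-open; VCF positions are 1-based.
bed_overlap <- function(variants, bed_path) {
  bed <- data.table::fread(bed_path, header = FALSE)
  if (ncol(bed) < 3L) stop("BED needs at least 3 columns")
  names(bed)[1:3] <- c("chrom", "start", "end")
  keep <- rep(FALSE, nrow(variants))
  for (ch in unique(bed$chrom)) {
    b <- bed[bed$chrom == ch, ]
    idx <- which(variants$chrom == ch)
    if (!length(idx)) next
    pos0 <- variants$pos[idx] - 1L
    hit <- vapply(pos0, function(p) any(p >= b$start & p < b$end), logical(1L))
    keep[idx[hit]] <- TRUE
  }
  keep
}

#' Write a candidate table to TSV
#'
#' Columns `chrom, pos, ref, alt, prescreen_p, lrt_p, bh_q, flagged,
#' iteration`, ordered by (chrom, pos); byte-identical across reruns on the
#' same input.
#'
#' @param candidates a data.frame as produced by [candidate_scan()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  cols <- c("chrom", "pos", "ref", "alt", "prescreen_p", "lrt_p", "bh_q",
            "flagged", "iteration")
  missing_cols <- setdiff(cols, names(candidates))
  for (cc in missing_cols) candidates[[cc]] <- logical(0)
  out <- as.data.frame(candidates)[, cols, drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  out$flagged <- ifelse(out$flagged, "true", "false")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Write a genotype matrix as a minimal VCF
#'
#' The coded minor allele is written as ALT (using the `ref`/`alt` columns of
#' the variant table when `minor_is_alt` is absent or true). GT-only,
#' unphased; missing genotypes become `./.`.
#'
#' @param gm a `genotype_matrix`.
#' @param path output path (plain text).
#' @return the path, invisibly.
#' @export
write_vcf <- function(gm, path) {
  v <- gm$variants
  g <- gm$genotypes
  gt_str <- c("0/0", "0/1", "1/1")
  ord <- order(v$chrom, v$pos)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=ildqc",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(unique(sprintf("##contig=<ID=%s>", v$chrom[ord])), collapse = "\n"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples$sample_id), collapse = "\t")), con)
  for (j in ord) {
    gj <- g[, j]
    cells <- ifelse(is.na(gj), "./.", gt_str[gj + 1L])
    writeLines(paste(c(v$chrom[j], v$pos[j], ".", v$ref[j], v$alt[j], ".",
                       "PASS", ".", "GT", cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a population map TSV
#'
#' @param gm a `genotype_matrix`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_popmap <- function(gm, path) {
  data.table::fwrite(gm$samples[, c("sample_id", "population")], path,
                     sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}
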