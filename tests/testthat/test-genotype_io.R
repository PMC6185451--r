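# VCF / popmap / candidate-table round trips and the frequency classifier.

make_tmp_popmap <- function(gm) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  write_popmap(gm, path)
  path
}

test_that("a hand-written VCF is read with direct coding and minor-allele folding", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "##contig=<ID=chr1>", "##contig=<ID=chr2>",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t1/1\t1/1\t0/1",   # alt freq 0.83 -> folded
    "chr2\t300\t.\tG\tC\t.\tPASS\t.\tGT\t0/1\t./.\t0/0",
    "chr2\t400\t.\tG\tGA\t.\tPASS\t.\tGT\t0/0\t0/0\t0/1",  # indel: skipped
    "chr2\t500\t.\tT\tA,C\t.\tPASS\t.\tGT\t0/0\t0/1\t0/2"  # triallelic: skipped
  ), vcf)
  pop <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\tpopA", "s2\tpopA", "s3\tpopA"), pop)
  expect_message(gm <- read_genotypes(vcf, pop, min_pop_size = 2),
                 "skipping 2 non-biallelic-SNV")
  expect_equal(dim(gm), c(3L, 3L))
  expect_equal(unname(gm$genotypes[, 1]), c(0L, 1L, 2L))     # alt minor
  expect_equal(unname(gm$genotypes[, 2]), c(0L, 0L, 1L))     # folded to ref
  expect_false(gm$variants$minor_is_alt[2])
  expect_equal(unname(gm$genotypes[, 3]), c(1L, NA, 0L))     # missing kept
  expect_equal(gm$variants$maf[1], 0.5)
  expect_equal(gm$variants$maf[2], 1 / 6)
})

test_that("samples missing from the popmap are dropped; zero overlap errors", {
  gm0 <- simulate_genotypes(n_individuals = 6, n_variants = 10, n_chrom = 2,
                            seed = 1)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm0, vcf)
  pop <- withr::local_tempfile(fileext = ".tsv")
  writeLines(sprintf("%s\tpopA", gm0$samples$sample_id[1:4]), pop)
  expect_warning(gm <- read_genotypes(vcf, pop, min_pop_size = 2),
                 "absent from the population map")
  expect_equal(nrow(gm$genotypes), 4L)
  pop_bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sX\tpopA\nsY\tpopA", pop_bad)
  expect_error(suppressWarnings(read_genotypes(vcf, pop_bad, min_pop_size = 1)),
               "no overlap")
})

test_that("simulate -> write_vcf -> read_genotypes round-trips exactly", {
  gm0 <- simulate_genotypes(n_individuals = 25, n_variants = 60, n_chrom = 3,
                            seed = 9)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm0, vcf)
  gm <- read_genotypes(vcf, data.frame(sample_id = gm0$samples$sample_id,
                                       population = gm0$samples$population),
                       min_pop_size = 1)
  expect_identical(unname(gm$genotypes), unname(gm0$genotypes))
  expect_equal(gm$variants$chrom, gm0$variants$chrom)
  expect_equal(gm$variants$pos, gm0$variants$pos)
  expect_equal(gm$variants$ref, gm0$variants$ref)
  expect_equal(gm$variants$alt, gm0$variants$alt)
})

test_that("BED restriction keeps only overlapped variants (half-open 0-based)", {
  gm0 <- simulate_genotypes(n_individuals = 10, n_variants = 20, n_chrom = 2,
                            seed = 2)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm0, vcf)
  bed <- withr::local_tempfile(fileext = ".bed")
  # positions are 100, 200, ...; BED [99, 300) covers 1-based pos 100..300
  writeLines("chr01\t99\t300", bed)
  pm <- data.frame(sample_id = gm0$samples$sample_id,
                   population = gm0$samples$population)
  gm <- suppressMessages(read_genotypes(vcf, pm, region_bed = bed,
                                        min_pop_size = 1))
  expect_true(all(gm$variants$chrom == "chr01"))
  expect_setequal(gm$variants$pos, c(100L, 200L, 300L))
})

test_that("classify_maf follows the common/rare/below-threshold rule", {
  g <- rbind(matrix(0L, 88, 3), matrix(1L, 12, 3))  # placeholder genotypes
  gm <- genotype_matrix(
    g, data.frame(chrom = "chr1", pos = 1:3, ref = "A", alt = "C"),
    data.frame(sample_id = sprintf("s%03d", 1:100),
               population = rep(c("p1", "p2"), each = 50)))
  # inject controlled per-population frequencies
  gm$pop_maf <- rbind(c(0.06, 0.01), c(0.03, 0.04), c(0.005, 0.009))
  gm <- classify_maf(gm)
  expect_equal(as.character(gm$variants$freq_class),
               c("common", "rare", "below_threshold"))
})

test_that("classification is invariant to sample and population order", {
  gm <- simulate_genotypes(n_individuals = c(a = 30, b = 30), n_variants = 40,
                           n_chrom = 2, spectrum = "sfs", seed = 12)
  gm <- classify_maf(gm)
  perm <- sample(nrow(gm$genotypes))
  gm2 <- classify_maf(subset_genotypes(gm, samples = perm))
  expect_equal(as.character(gm2$variants$freq_class),
               as.character(gm$variants$freq_class))
})

test_that("write_candidates is deterministic and handles empty tables", {
  gm <- simulate_genotypes(n_individuals = 8, n_variants = 6, n_chrom = 2,
                           seed = 3)
  cand <- data.frame(variant = 1:2, chrom = gm$variants$chrom[1:2],
                     pos = gm$variants$pos[1:2], ref = "A", alt = "C",
                     prescreen_p = c(0.001, 0.5), lrt_p = c(0.002, NA),
                     bh_q = c(0.012, 1), flagged = c(TRUE, FALSE),
                     iteration = 1L)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_candidates(cand, f1); write_candidates(cand, f2)
  expect_identical(readLines(f1), readLines(f2))
  lines <- readLines(f1)
  expect_length(lines, 3L)
  expect_match(lines[2], "true")
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_candidates(cand[0, ], f3)
  expect_length(readLines(f3), 1L)  # header only
})

test_that("popmap reader enforces the minimum population size", {
  pop <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(sprintf("a%d\tbig", 1:5), "b1\tsmall"), pop)
  expect_message(pm <- read_popmap(pop, min_pop_size = 3), "dropping 1")
  expect_setequal(unique(pm$population), "big")
  expect_equal(nrow(pm), 5L)
})
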