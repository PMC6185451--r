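# Composite genotypic LD: table construction, Eq. weights, T2, exact test,
# Fisher combination, and the vectorized scan against the scalar route.

test_that("cross_tab counts joint genotypes with pairwise deletion", {
  expect_equal(cross_tab(c(2, 2), c(2, 2))[1, 1], 2L)
  expect_equal(sum(cross_tab(c(2, 2), c(2, 2))), 2L)
  expect_equal(cross_tab(1, 1)[2, 2], 1L)
  tab <- cross_tab(c(2, NA), c(2, 2))
  expect_equal(tab[1, 1], 1L)
  expect_equal(sum(tab), 1L)
})

test_that("sigma_ab reproduces the Eq. weights", {
  tab <- matrix(0L, 3, 3)
  tab[1, 1] <- 1L; tab[1, 2] <- 2L; tab[2, 2] <- 4L
  expect_identical(sigma_ab(tab), 6)
  tab5 <- matrix(0L, 3, 3); tab5[2, 2] <- 10L
  expect_identical(sigma_ab(tab5), 5)
  tab3 <- matrix(0L, 3, 3); tab3[1, 3] <- 4L
  expect_identical(sigma_ab(tab3), 0)
})

test_that("sigma_ab and D match the brute-force gamete oracle on random tables", {
  set.seed(11)
  for (rep in 1:200) {
    n <- sample(3:40, 1)
    ga <- sample(0:2, n, replace = TRUE)
    gb <- sample(0:2, n, replace = TRUE)
    tab <- cross_tab(ga, gb)
    expect_identical(sigma_ab(tab), oracle_sigma_ab(ga, gb))
    st <- pair_stats(tab)
    expect_equal(st$d_ab, oracle_sigma_ab(ga, gb) / n -
                   2 * (mean(ga) / 2) * (mean(gb) / 2))
  }
})

test_that("closed-form D examples: independence, coupling, repulsion", {
  # 10 samples all double heterozygous: sigma = 5, p = 0.5 -> D = 0
  tab <- matrix(0L, 3, 3); tab[2, 2] <- 10L
  st <- pair_stats(tab)
  expect_equal(st$sigma_ab, 5)
  expect_equal(st$d_ab, 0)
  # 5 (A/A,B/B) + 5 (a/a,b/b): D = +0.5
  tab <- matrix(0L, 3, 3); tab[1, 1] <- 5L; tab[3, 3] <- 5L
  expect_equal(pair_stats(tab)$d_ab, 0.5)
  # 5 (A/A,b/b) + 5 (a/a,B/B): D = -0.5
  tab <- matrix(0L, 3, 3); tab[1, 3] <- 5L; tab[3, 1] <- 5L
  expect_equal(pair_stats(tab)$d_ab, -0.5)
})

test_that("D is antisymmetric under swapping allele labels at one locus", {
  set.seed(7)
  for (rep in 1:50) {
    ga <- sample(0:2, 30, replace = TRUE)
    gb <- sample(0:2, 30, replace = TRUE)
    d1 <- pair_stats(cross_tab(ga, gb))$d_ab
    d2 <- pair_stats(cross_tab(2L - ga, gb))$d_ab
    expect_equal(d1, -d2)
  }
})

test_that("T2 matches the chi-square integration oracle and scales with n", {
  # maximal coupling: D = 0.5, D_A = D_B = 0.25 -> T2 = 10
  tab <- matrix(0L, 3, 3); tab[1, 1] <- 5L; tab[3, 3] <- 5L
  p <- t2_pvalue(tab)
  expect_equal(p, oracle_chisq_upper(10, 1), tolerance = 1e-8)
  # doubling all counts doubles T2 (same frequencies)
  st <- function(tb) {
    s <- pair_stats(tb)
    s$n * s$d_ab^2 /
      ((s$p_a * (1 - s$p_a) + s$d_a) * (s$p_b * (1 - s$p_b) + s$d_b))
  }
  set.seed(5)
  for (rep in 1:20) {
    ga <- sample(0:2, 20, replace = TRUE)
    gb <- sample(0:2, 20, replace = TRUE)
    tab <- cross_tab(ga, gb)
    if (stats::sd(ga) == 0 || stats::sd(gb) == 0) next
    expect_equal(st(tab + tab), 2 * st(tab), tolerance = 1e-12)
  }
  # independent table: D = 0 -> p = 1
  tab0 <- matrix(0L, 3, 3); tab0[2, 2] <- 10L
  expect_equal(t2_pvalue(tab0), 1)
  # degenerate (monomorphic) table warns and returns 1
  tabm <- matrix(0L, 3, 3); tabm[1, 2] <- 3L; tabm[1, 3] <- 3L
  expect_warning(pm <- t2_pvalue(tabm), "degenerate")
  expect_equal(pm, 1)
})

test_that("exact positive-tail p matches the enumeration oracle", {
  # diagonal table: 5 double carriers, 5 double non-carriers
  tab <- matrix(0L, 3, 3); tab[1, 1] <- 5L; tab[3, 3] <- 5L
  expect_equal(exact_pvalue_positive(tab), 1 / choose(10, 5), tolerance = 1e-12)
  # no double carrier: positive tail is everything
  tabz <- matrix(0L, 3, 3); tabz[1, 3] <- 5L; tabz[3, 1] <- 5L
  expect_equal(exact_pvalue_positive(tabz), 1)
  # independent margins with expected cell counts -> p >= 0.5
  tabi <- matrix(c(1L, 1L, 2L, 1L, 1L, 2L, 2L, 2L, 4L), 3, 3)
  expect_gte(exact_pvalue_positive(tabi), 0.5)
  set.seed(19)
  for (rep in 1:150) {
    n <- sample(4:30, 1)
    ga <- sample(0:2, n, replace = TRUE)
    gb <- sample(0:2, n, replace = TRUE)
    tab <- cross_tab(ga, gb)
    x <- sum(tab[1:2, 1:2])
    m_a <- n - sum(tab[3, ]); m_b <- n - sum(tab[, 3])
    expect_equal(exact_pvalue_positive(tab), oracle_carrier_p(x, m_a, m_b, n),
                 tolerance = 1e-12)
  }
})

test_that("Fisher combination matches hand values and the k=1 identity", {
  expect_equal(combine_pvalues(c(1, 1)), 1)
  expect_equal(combine_pvalues(c(0.5, 0.5)),
               oracle_chisq_upper(-2 * sum(log(c(0.5, 0.5))), 4),
               tolerance = 1e-8)
  expect_equal(combine_pvalues(c(0.5, 0.5)), 0.5966, tolerance = 1e-4)
  for (p in c(1e-6, 0.037, 0.42, 1)) expect_equal(combine_pvalues(p), p)
  expect_error(combine_pvalues(numeric(0)), "untestable")
})

test_that("scan_pairs counts pairs, applies the prescreen rule, errors on one chromosome", {
  gm <- simulate_genotypes(n_individuals = 40, n_variants = 20, n_chrom = 2,
                           seed = 21)
  sc <- scan_pairs(gm)
  expect_equal(sc$n_pairs, 100L)  # 10 x 10 cross-chromosome pairs
  expect_equal(sc$prescreen_p, 100 / 20^2)
  # exact p only below the prescreen threshold
  expect_true(all(is.na(sc$pairs$p_exact[sc$pairs$p_approx >= sc$prescreen_p])))
  gm1 <- simulate_genotypes(n_individuals = 20, n_variants = 10, n_chrom = 1,
                            seed = 22)
  expect_error(scan_pairs(gm1), "2 chromosomes")
})

test_that("vectorized scan agrees with the scalar per-table route, with missing data", {
  set.seed(33)
  n <- 50; m <- 12
  g <- matrix(rbinom(n * m, 2, runif(m, 0.1, 0.5)[rep(1:m, each = n)]), n, m)
  g[sample(length(g), 60)] <- NA
  gm <- genotype_matrix(
    g,
    data.frame(chrom = rep(c("chr1", "chr2"), each = m / 2), pos = 1:m,
               ref = "A", alt = "C"),
    data.frame(sample_id = sprintf("s%02d", 1:n), population = "pop1"))
  idx <- ildqc:::cross_pair_index(gm$variants$chrom)
  sc <- ildqc:::pop_approx_scan(gm$genotypes, idx)
  for (k in seq_along(idx$i)) {
    ga <- g[, idx$i[k]]; gb <- g[, idx$j[k]]
    tab <- cross_tab(ga, gb)
    st <- pair_stats(tab)
    va <- st$p_a * (1 - st$p_a) + st$d_a
    vb <- st$p_b * (1 - st$p_b) + st$d_b
    if (st$p_a %in% c(0, 1) || st$p_b %in% c(0, 1) || va <= 1e-12 || vb <= 1e-12) {
      expect_true(is.na(sc$p[k]))
      next
    }
    t2 <- st$n * st$d_ab^2 / max(va * vb, 1e-12)
    p1 <- pnorm(sign(st$d_ab) * sqrt(t2), lower.tail = FALSE)
    expect_equal(sc$p[k], p1, tolerance = 1e-12)
    expect_equal(sc$d_ab[k], st$d_ab, tolerance = 1e-12)
  }
})

test_that("T2 and exact p rank-agree on associated large-n tables", {
  set.seed(55)
  p_t2 <- p_ex <- numeric(0)
  for (rep in 1:600) {
    gp <- random_geno_pair(n = 300, p_a = runif(1, 0.05, 0.4),
                           p_b = runif(1, 0.05, 0.4),
                           batch_frac = runif(1, 0, 0.3), seed = rep)
    tab <- cross_tab(gp$ga, gp$gb)
    if (stats::sd(gp$ga) == 0 || stats::sd(gp$gb) == 0) next
    p_t2 <- c(p_t2, suppressWarnings(t2_pvalue(tab)))
    p_ex <- c(p_ex, exact_pvalue_positive(tab))
  }
  expect_gt(suppressWarnings(cor(p_t2, p_ex, method = "spearman")), 0.9)
})
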