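# nAB contributions, conservation, variance test, and the mixture machinery.

test_that("per-sample contributions follow the genotype-configuration weights", {
  # one pair; samples: (A/A,B/B) -> 2, (A/A,b/b) -> 0, (A/a,B/b) -> 0.5
  g <- rbind(c(2L, 2L), c(2L, 0L), c(1L, 1L), c(0L, 2L))
  gm <- genotype_matrix(
    g, data.frame(chrom = c("chr1", "chr2"), pos = c(1L, 1L),
                  ref = "A", alt = "C"),
    data.frame(sample_id = paste0("s", 1:4), population = "p"))
  prof <- compute_nab(gm, data.frame(i = 1L, j = 2L))
  expect_equal(prof$nab, c(2, 0, 0.5, 0))
})

test_that("contributions sum exactly to sigma_AB for every pair (conservation)", {
  gm <- simulate_genotypes(n_individuals = 40, n_variants = 30, n_chrom = 3,
                           spectrum = "sfs", seed = 17)
  set.seed(71)
  pairs <- data.frame(i = sample(1:10, 20, TRUE), j = sample(11:30, 20, TRUE))
  prof <- compute_nab(gm, pairs)
  total <- sum(vapply(seq_len(nrow(pairs)), function(k)
    sigma_ab(cross_tab(gm$genotypes[, pairs$i[k]], gm$genotypes[, pairs$j[k]])),
    numeric(1)))
  expect_equal(sum(prof$nab), total)
  # and per single pair
  for (k in c(1, 7, 20)) {
    p1 <- compute_nab(gm, pairs[k, ])
    expect_equal(sum(p1$nab),
                 sigma_ab(cross_tab(gm$genotypes[, pairs$i[k]],
                                    gm$genotypes[, pairs$j[k]])))
  }
})

test_that("nAB is invariant to pair order and empty link sets warn", {
  gm <- simulate_genotypes(n_individuals = 20, n_variants = 20, n_chrom = 2,
                           seed = 23)
  pairs <- data.frame(i = c(1L, 3L, 5L), j = c(12L, 15L, 18L))
  p1 <- compute_nab(gm, pairs)
  p2 <- compute_nab(gm, pairs[c(3, 1, 2), ])
  expect_equal(p1$nab, p2$nab)
  expect_warning(p0 <- compute_nab(gm, NULL), "empty link set")
  expect_true(all(p0$nab == 0))
})

test_that("variance test: self-comparison is calibrated, degenerate profiles warn", {
  gm <- simulate_genotypes(n_individuals = 60, n_variants = 40, n_chrom = 4,
                           seed = 29)
  pairs <- data.frame(i = rep(1:10, each = 3), j = sample(11:40, 30, TRUE))
  prof <- compute_nab(gm, pairs)
  perm <- ildqc:::permuted_nab(gm, pairs, n_perm = 4, seed = 3)
  vt <- nab_variance_test(prof, perm)
  expect_true(vt$by_population$ratio > 0.3 && vt$by_population$ratio < 3)
  # observed drawn from the same process as permuted: p should not be tiny
  expect_gt(vt$p, 0.001)
  # constant profile -> warning, NA result
  prof0 <- prof; prof0$nab[] <- 0
  perm0 <- lapply(perm, function(q) { q$nab[] <- 0; q })
  expect_warning(vt0 <- nab_variance_test(prof0, perm0), "degenerate")
  expect_true(is.na(vt0$p))
})

test_that("variance test detects injected batch structure", {
  inj <- suppressMessages(inject_errors(
    simulate_genotypes(100, 400, 4, spectrum = "sfs", seed = 41),
    batch_fraction = 0.5, affected_fraction = 0.5,
    error_site_fraction = 0.01, seed = 42))
  gm <- inj$gm
  sites <- inj$error_sites
  combos <- expand.grid(i = sites, j = sites)
  combos <- combos[gm$variants$chrom[combos$i] != gm$variants$chrom[combos$j] &
                     combos$i < combos$j, ]
  prof <- compute_nab(gm, combos)
  perm <- ildqc:::permuted_nab(gm, combos, n_perm = 3, seed = 43)
  vt <- nab_variance_test(prof, perm)
  expect_gt(vt$by_population$ratio, 5)
  expect_lt(vt$p, 0.05)
})

test_that("fit_mixture recovers K on easy cases and applies the AICc domain rule", {
  # single Gaussian: best K = 1 in a clear majority of seeds
  hits <- vapply(1:10, function(s) {
    x <- ildqc:::with_seed(1000 + s, rnorm(100))
    fit_mixture(x, k_max = 4, seed = s)$best_k == 1L
  }, logical(1))
  expect_gte(mean(hits), 0.7)
  # two Gaussians 10 SDs apart: K = 2 and assignments match labels
  x <- ildqc:::with_seed(7, c(rnorm(60), rnorm(40, 10)))
  fit <- fit_mixture(x, k_max = 5, seed = 7)
  expect_equal(fit$best_k, 2L)
  truth <- rep(1:2, c(60, 40))
  expect_gt(adjusted_rand_index(fit$assignment, truth), 0.95)
  expect_equal(sum(fit$aicc_weight), 1)
  # n too small for larger K: those K are skipped (AICc undefined)
  small <- ildqc:::with_seed(8, rnorm(9))
  fit_s <- fit_mixture(small, k_max = 9, seed = 2)
  expect_true(all(as.integer(names(fit_s$aicc)) <= 3L))  # 3K-1 < n-1 needs K <= 3
})

test_that("clustering support test obeys rank bounds", {
  obs <- 5
  perm <- rep(10, 100)  # observed below all permuted
  expect_gte(clustering_support_test(obs, matrix(perm, 1))$p, 0.5)
  perm2 <- rep(1, 100)  # observed above all permuted
  expect_lte(clustering_support_test(obs, matrix(perm2, 1))$p, 1 / 101 + 1e-12)
  expect_warning(clustering_support_test(obs, matrix(1:2, 1)), "unreliable")
})

test_that("permuted profiles favor K = 1 more often than batch-structured ones", {
  k1_perm <- k1_obs <- logical(6)
  for (s in 1:6) {
    inj <- suppressMessages(inject_errors(
      simulate_genotypes(80, 200, 4, spectrum = "sfs", seed = 500 + s),
      batch_fraction = 0.5, affected_fraction = 0.5,
      error_site_fraction = 0.02, seed = 600 + s))
    gm <- inj$gm
    sites <- inj$error_sites
    combos <- expand.grid(i = sites, j = sites)
    combos <- combos[gm$variants$chrom[combos$i] != gm$variants$chrom[combos$j] &
                       combos$i < combos$j, ]
    prof <- compute_nab(gm, combos)
    perm <- ildqc:::permuted_nab(gm, combos, n_perm = 1, seed = 700 + s)[[1]]
    k1_obs[s] <- fit_mixture(prof$nab, k_max = 4, seed = s)$best_k == 1L
    k1_perm[s] <- fit_mixture(perm$nab, k_max = 4, seed = s)$best_k == 1L
  }
  expect_gte(sum(k1_perm), sum(k1_obs))
  expect_lte(mean(k1_obs), 0.5)
})
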