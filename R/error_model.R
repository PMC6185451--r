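# Step 3: variants whose minor-allele presence is predicted by the
# per-sample error burden z(nAB). A fast per-population logistic prescreen
# (allele presence per chromosome copy ~ z(nAB), Fisher-combined) gates a
# full logistic mixed model with population and sample random effects,
# compared to its null by a likelihood-ratio test and BH-corrected.

# Binomial log-likelihood ratio of slope-vs-intercept logistic models for
# aggregated copies: successes = minor-allele copies (0/1/2) out of 2.
# Returns list(p, separated).
logistic_lrt <- function(g, z) {
  ok <- !is.na(g)
  g <- g[ok]; z <- z[ok]
  if (length(g) < 3L || all(g == 0L) || all(g == 2L) || stats::sd(z) == 0)
    return(list(p = NA_real_, separated = FALSE))
  y <- g / 2
  X <- cbind(1, z)
  fit <- suppressWarnings(
    stats::glm.fit(X, y, weights = rep(2, length(y)),
                   family = stats::binomial()))
  separated <- !fit$converged || max(abs(fit$coefficients)) > 12
  if (separated) {
    # weak ridge on the slope stabilizes complete separation
    fit <- ridge_logistic(X, y, weights = rep(2, length(y)), lambda = 1e-2)
  }
  dev_null <- binom_null_deviance(y, rep(2, length(y)))
  p <- stats::pchisq(dev_null - fit$deviance, df = 1L, lower.tail = FALSE)
  list(p = min(max(p, .Machine$double.xmin), 1), separated = separated)
}

binom_null_deviance <- function(y, w) {
  mu <- sum(w * y) / sum(w)
  if (mu <= 0 || mu >= 1) return(0)
  -2 * sum(w * (y * log(mu) + (1 - y) * log(1 - mu))) +
    2 * sum(w * ifelse(y %in% c(0, 1), 0,
                       y * log(y) + (1 - y) * log(1 - y)))
}

# Minimal IRLS with an L2 penalty on the slope coefficient(s).
ridge_logistic <- function(X, y, weights, lambda = 1e-2, max_iter = 50L) {
  beta <- rep(0, ncol(X))
  pen <- diag(c(0, rep(lambda, ncol(X) - 1L)), ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- weights * mu * (1 - mu)
    H <- crossprod(X, X * W) + pen
    score <- crossprod(X, weights * (y - mu)) - pen %*% beta
    step <- tryCatch(solve(H, score), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  eta <- drop(X %*% beta)
  mu <- pmin(pmax(1 / (1 + exp(-eta)), 1e-12), 1 - 1e-12)
  dev <- -2 * sum(weights * (y * log(mu) + (1 - y) * log(1 - mu))) +
    2 * sum(weights * ifelse(y %in% c(0, 1), 0,
                             y * log(y) + (1 - y) * log(1 - y)))
  list(coefficients = beta, deviance = dev, converged = TRUE)
}

#' Logistic prescreen of one variant against the nAB profile
#'
#' Per population, minor-allele presence per chromosome copy is regressed on
#' z(nAB) by maximum likelihood (the two copies of a sample share its
#' covariate, so the per-copy Bernoulli model aggregates to a binomial) and
#' the slope is tested by LRT against the intercept-only model; populations
#' are combined with Fisher's method. Monomorphic populations are omitted.
#'
#' @param genotypes integer vector of minor-allele copy counts for one
#'   variant, aligned with `profile`.
#' @param profile an `nab_profile` (provides `z_nab` and `population`).
#' @return list with combined `p` (NA if untestable everywhere) and
#'   `separated` (TRUE if any population needed the penalized fit).
#' @export
prescreen <- function(genotypes, profile) {
  pops <- unique(profile$population)
  ps <- rep(NA_real_, length(pops)); sep <- FALSE
  for (k in seq_along(pops)) {
    rows <- profile$population == pops[k]
    r <- logistic_lrt(genotypes[rows], profile$z_nab[rows])
    ps[k] <- r$p; sep <- sep || r$separated
  }
  if (all(is.na(ps))) return(list(p = NA_real_, separated = sep))
  list(p = combine_pvalues(ps[!is.na(ps)]), separated = sep)
}

#' Mixed-model likelihood-ratio test for one variant
#'
#' Response: minor-allele presence per chromosome copy (two rows per sample;
#' for heterozygotes the carrying copy is arbitrary but fixed, absorbed by
#' the sample random intercept). Full model:
#' `presence ~ z_nab + (1|population) + (0 + z_nab|population) + (1|sample)`;
#' null model drops both nAB terms. With a single population the population
#' random terms collapse and the models reduce to `presence ~ z_nab +
#' (1|sample)` vs `presence ~ (1|sample)`. LRT df = 2 (fixed slope + random
#' slope variance) for multi-population data, 1 otherwise.
#'
#' @param genotypes integer vector of minor-allele copy counts for one
#'   variant, aligned with `profile`.
#' @param profile an `nab_profile`.
#' @return list with `p`, `logLik_full`, `logLik_null`, `df`, `converged`.
#' @export
mixed_lrt <- function(genotypes, profile) {
  ok <- !is.na(genotypes)
  g <- genotypes[ok]
  z <- profile$z_nab[ok]
  pop <- profile$population[ok]
  sample_id <- profile$sample_id[ok]
  if (length(g) < 3L || all(g == 0L) || all(g == 2L))
    return(list(p = NA_real_, converged = FALSE))
  if (stats::sd(z) == 0)  # full and null models coincide
    return(list(p = 1, logLik_full = NA_real_, logLik_null = NA_real_,
                df = 0L, converged = TRUE))
  dat <- data.frame(
    y = as.integer(c(g >= 1L, g >= 2L)),  # copy 1 carries the het allele
    z = rep(z, 2L), pop = rep(pop, 2L), sample = rep(sample_id, 2L),
    stringsAsFactors = FALSE)
  multi_pop <- length(unique(pop)) > 1L
  f_full <- if (multi_pop)
    y ~ z + (1 | pop) + (0 + z | pop) + (1 | sample)
  else y ~ z + (1 | sample)
  f_null <- if (multi_pop) y ~ (1 | pop) + (1 | sample) else y ~ (1 | sample)
  ctrl <- lme4::glmerControl(optimizer = "bobyqa", calc.derivs = FALSE,
                             check.conv.singular = "ignore")
  fit_one <- function(f) tryCatch(
    suppressMessages(suppressWarnings(
      lme4::glmer(f, data = dat, family = stats::binomial(), control = ctrl))),
    error = function(e) NULL)
  full <- fit_one(f_full)
  null <- fit_one(f_null)
  if (is.null(full) || is.null(null))
    return(list(p = NA_real_, converged = FALSE))
  ll_f <- as.numeric(stats::logLik(full))
  ll_n <- as.numeric(stats::logLik(null))
  df <- if (multi_pop) 2L else 1L
  stat <- max(2 * (ll_f - ll_n), 0)
  list(p = stats::pchisq(stat, df = df, lower.tail = FALSE),
       logLik_full = ll_f, logLik_null = ll_n, df = df, converged = TRUE)
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up BH adjustment.
#'
#' @param p_values numeric vector of p-values.
#' @return q-values of the same length.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  stats::p.adjust(p_values, method = "BH")
}

#' Scan all variants for association with the error burden
#'
#' Applies the logistic [prescreen()] to every variant in the matrix (the
#' error call is genome-wide, not restricted to the LD-scanned pairs), runs
#' [mixed_lrt()] on variants whose combined prescreen p falls below
#' `prescreen_alpha`, BH-corrects across all scanned variants (the
#' mixed-model p where available, the prescreen p otherwise; untestable
#' variants get q = 1), and flags mixed-model-tested candidates at
#' `q_cutoff`.
#'
#' @param gm a [genotype_matrix()].
#' @param profile an `nab_profile` for the current iteration.
#' @param prescreen_alpha combined-p threshold gating the full model
#'   (default 0.01).
#' @param q_cutoff BH q cutoff for flagging (default 0.05).
#' @param iteration iteration index recorded per row.
#' @param verbose print progress.
#' @return a `candidate_table` data.frame: one row per variant with
#'   `prescreen_p`, `lrt_p`, `bh_q`, `flagged`, `iteration` plus variant
#'   coordinates.
#' @export
candidate_scan <- function(gm, profile, prescreen_alpha = 0.01,
                           q_cutoff = 0.05, iteration = 1L, verbose = FALSE) {
  m <- ncol(gm$genotypes)
  pre_p <- rep(NA_real_, m)
  if (all(profile$nab == 0)) {
    ildqc_msg("empty nAB profile: no candidates scanned", verbose = verbose)
  } else {
    for (v in seq_len(m))
      pre_p[v] <- prescreen(gm$genotypes[, v], profile)$p
  }
  test_idx <- which(!is.na(pre_p) & pre_p < prescreen_alpha)
  ildqc_msg(sprintf("prescreen passed %d/%d variants", length(test_idx), m),
            verbose = verbose)
  lrt_p <- rep(NA_real_, m)
  approx_fallback <- logical(m)
  for (v in test_idx) {
    r <- mixed_lrt(gm$genotypes[, v], profile)
    if (isTRUE(r$converged) && !is.na(r$p)) {
      lrt_p[v] <- r$p
    } else {
      lrt_p[v] <- pre_p[v]  # fall back to the prescreen p, flagged approximate
      approx_fallback[v] <- TRUE
    }
  }
  # BH family = every variant entering the scan. The prescreen is only a
  # computational shortcut: variants failing it keep their (>= alpha)
  # prescreen p in the family, so the selected set is not corrected against
  # itself. Flagging still requires a mixed-model test.
  p_family <- ifelse(is.na(lrt_p), pre_p, lrt_p)
  in_family <- !is.na(p_family)
  q <- rep(1, m)
  q[in_family] <- bh_adjust(p_family[in_family])
  out <- data.frame(
    variant = seq_len(m),
    chrom = gm$variants$chrom, pos = gm$variants$pos,
    ref = gm$variants$ref, alt = gm$variants$alt,
    prescreen_p = pre_p, lrt_p = lrt_p, bh_q = q,
    flagged = seq_len(m) %in% test_idx & q <= q_cutoff,
    approximate = approx_fallback,
    iteration = iteration,
    stringsAsFactors = FALSE)
  class(out) <- c("candidate_table", "data.frame")
  out
}
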