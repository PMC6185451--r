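# One-dimensional Gaussian finite mixtures fitted by EM, model size selected
# by the small-sample-corrected AIC. A K-component mixture has m = 3K - 1
# free parameters (K means, K variances, K - 1 weights);
# AICc = -2 logLik + 2m + 2m(m+1)/(n-m-1), undefined when n <= m + 1.

# k-means++ style seeding of K initial centers.
kmeanspp_centers <- function(x, k) {
  centers <- numeric(k)
  centers[1L] <- x[sample.int(length(x), 1L)]
  if (k > 1L) for (i in 2:k) {
    d2 <- vapply(x, function(v) min((v - centers[1:(i - 1L)])^2), numeric(1L))
    centers[i] <- if (sum(d2) > 0)
      x[sample.int(length(x), 1L, prob = d2)] else x[sample.int(length(x), 1L)]
  }
  centers
}

em_gauss_1d <- function(x, k, centers, tol = 1e-8, max_iter = 500L) {
  n <- length(x)
  # floor component variances at (0.1 sd)^2 of the data: keeps genuine
  # point-mass clusters detectable while capping the likelihood gain a
  # spurious narrow component can extract from a few close points
  var_floor <- max(0.01 * stats::var(x), 1e-12)
  mu <- centers
  sigma2 <- rep(max(stats::var(x) / k, var_floor), k)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(c)
      w[c] * stats::dnorm(x, mu[c], sqrt(sigma2[c])), numeric(n))
    dim(dens) <- c(n, k)
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d == 0] <- .Machine$double.xmin
    ll <- sum(log(rowsum_d))
    resp <- dens / rowsum_d
    nk <- colSums(resp)
    if (any(nk < 1e-10)) nk <- pmax(nk, 1e-10)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sigma2 <- pmax(colSums(resp * (x - rep(mu, each = n))^2) / nk, var_floor)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  list(mu = mu, sigma2 = sigma2, w = w, loglik = ll, resp = resp)
}

#' Fit Gaussian mixtures with 1..k_max components, selected by AICc
#'
#' EM with k-means++ initialization and multiple seeded restarts; component
#' variances are floored to avoid degeneracy. The best K is the smallest K
#' whose AICc is within 2 units of the minimum (parsimony tie-break); AICc
#' weights are reported over all fitted K.
#'
#' @param x numeric vector (e.g. one population's nAB values).
#' @param k_max maximum number of components (default 9); lowered
#'   automatically when n is too small for the AICc to be defined.
#' @param seed RNG seed for initialization.
#' @param n_starts number of EM restarts per K (capped at 50).
#' @return object of class `mixture_fit`: list with per-K `fits` (mu,
#'   sigma2, w, loglik, aicc), `aicc` vector, `aicc_weight` vector,
#'   `best_k`, and `assignment` (max-responsibility component under the
#'   best K).
#' @export
fit_mixture <- function(x, k_max = 9L, seed = 1L, n_starts = 10L) {
  x <- x[!is.na(x)]
  n <- length(x)
  n_starts <- min(n_starts, 50L)
  if (n < 3L) stop("need at least 3 observations")
  fits <- list()
  aicc <- c()
  with_seed(seed, {
    for (k in seq_len(k_max)) {
      m <- 3L * k - 1L
      if (n <= m + 1L) break  # AICc undefined for this K
      if (stats::sd(x) == 0) {
        if (k > 1L) break
        fits[["1"]] <- list(mu = x[1L], sigma2 = 1e-12, w = 1,
                            loglik = Inf, aicc = -Inf)
        aicc["1"] <- -Inf
        next
      }
      best <- NULL
      for (s in seq_len(n_starts)) {
        fit <- tryCatch(em_gauss_1d(x, k, kmeanspp_centers(x, k)),
                        error = function(e) NULL)
        if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik))
          best <- fit
      }
      if (is.null(best)) next
      best$aicc <- -2 * best$loglik + 2 * m + 2 * m * (m + 1) / (n - m - 1)
      fits[[as.character(k)]] <- best
      aicc[as.character(k)] <- best$aicc
    }
  })
  if (!length(fits)) stop("no mixture model could be fitted")
  if (length(aicc) == 1L || !all(is.finite(aicc))) {
    delta <- ifelse(aicc == min(aicc), 0, Inf)
  } else {
    delta <- aicc - min(aicc)
  }
  weight <- exp(-0.5 * delta) / sum(exp(-0.5 * delta))
  ks <- as.integer(names(aicc))
  best_k <- min(ks[delta <= 2])  # smallest K within 2 AICc units of the optimum
  bf <- fits[[as.character(best_k)]]
  assignment <- if (best_k == 1L || is.null(bf$resp)) rep(1L, n)
    else max.col(bf$resp)
  structure(list(fits = fits, aicc = aicc, aicc_weight = weight,
                 best_k = best_k, assignment = assignment, n = n),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("mixture_fit: best K = %d (AICc weight %.3f) over K in {%s}\n",
              x$best_k, x$aicc_weight[as.character(x$best_k)],
              paste(names(x$aicc), collapse = ",")))
  invisible(x)
}

# AICc support for >1 cluster: AICc(K=1) - AICc(best K), floored at 0.
clustering_stat <- function(fit) {
  a1 <- fit$aicc["1"]
  if (is.na(a1)) return(NA_real_)
  max(a1 - min(fit$aicc), 0)
}

#' Compare clustering support against permuted-null fits
#'
#' The statistic is the AICc difference between the one-component model and
#' the best model. The one-tailed empirical p-value is the rank of the
#' observed statistic among the permuted ones; with several populations the
#' per-population statistics are compared with a one-sided Wilcoxon rank
#' test, as well.
#'
#' @param observed_stat numeric vector of observed per-population statistics
#'   (from [clustering_stat()] via [fit_mixture()]).
#' @param permuted_stats numeric vector (or matrix populations x replicates)
#'   of the same statistic on permuted data.
#' @return list with `p` (empirical, aggregated over populations by taking
#'   each population's rank and combining with Fisher), `p_wilcoxon`
#'   (only when > 1 population), and `n_perm`.
#' @export
clustering_support_test <- function(observed_stat, permuted_stats) {
  if (is.null(dim(permuted_stats)))
    permuted_stats <- matrix(permuted_stats, nrow = length(observed_stat))
  stopifnot(nrow(permuted_stats) == length(observed_stat))
  n_perm <- ncol(permuted_stats)
  if (n_perm < 3L)
    warning("fewer than 3 permuted fits: clustering-support p is unreliable")
  p_pop <- vapply(seq_along(observed_stat), function(i) {
    if (is.na(observed_stat[i])) return(NA_real_)
    (1 + sum(permuted_stats[i, ] >= observed_stat[i])) / (n_perm + 1)
  }, numeric(1L))
  p <- if (all(is.na(p_pop))) NA_real_ else
    combine_pvalues(p_pop[!is.na(p_pop)])
  p_wilcox <- if (length(observed_stat) > 1L)
    stats::wilcox.test(observed_stat, as.numeric(permuted_stats),
                       alternative = "greater", exact = FALSE)$p.value
  else NA_real_
  list(p = p, p_per_population = p_pop, p_wilcoxon = p_wilcox,
       n_perm = n_perm)
}
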