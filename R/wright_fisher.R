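# Two-locus Wright-Fisher dynamics under epistatic selection, tracking the
# four gamete counts (AB, Ab, aB, ab) in a constant-size gamete pool. Each
# generation first recombines (random pairing of gametes; a discordant
# double-heterozygous pairing {AB,ab} or {Ab,aB} switches phase with
# probability r), then resamples multinomially with fitness 1 + s_g
# (Wright-Fisher selection).

#' Simulate two-locus Wright-Fisher trajectories with epistatic selection
#'
#' @param n0 integer vector of initial gamete counts, named or ordered
#'   `c(AB, Ab, aB, ab)`; the total is the constant gamete population size.
#' @param s selection coefficients for the four gametes, same order
#'   (fitness `1 + s`). The two canonical scenarios are `s = c(s_AB, 0, 0, 0)`
#'   (advantageous minor-allele pair) and `s = c(0, -s, -s, 0)`
#'   (antagonistic mixed gametes).
#' @param r recombination probability per discordant pairing (0.5 =
#'   unlinked).
#' @param generations number of generations to simulate.
#' @param replicates number of independent trajectories.
#' @param seed RNG seed.
#' @return list with `freq`: array replicates x (generations+1) x 4 of
#'   gamete frequencies (generation 0 first), and `d`: replicates x
#'   (generations+1) matrix of the gametic disequilibrium
#'   `D = f_AB f_ab - f_Ab f_aB`.
#' @export
wf_two_locus <- function(n0 = c(AB = 250L, Ab = 250L, aB = 250L, ab = 250L),
                         s = c(0, 0, 0, 0), r = 0.5, generations = 20L,
                         replicates = 1L, seed = 1L) {
  stopifnot(length(n0) == 4L, all(n0 >= 0L), sum(n0) > 0L,
            length(s) == 4L, r >= 0, r <= 0.5)
  n_tot <- sum(n0)
  if (n_tot %% 2L != 0L) stop("gamete population size must be even (random pairing)")
  fitness <- 1 + s
  freq <- array(NA_real_, c(replicates, generations + 1L, 4L),
                dimnames = list(NULL, NULL, c("AB", "Ab", "aB", "ab")))
  with_seed(seed, {
    for (rep_i in seq_len(replicates)) {
      counts <- as.integer(n0)
      freq[rep_i, 1L, ] <- counts / n_tot
      for (t in seq_len(generations)) {
        counts <- wf_recombine(counts, r)
        counts <- wf_select(counts, fitness, n_tot)
        freq[rep_i, t + 1L, ] <- counts / n_tot
        if (sum(counts) == 0L) break
      }
    }
  })
  d <- freq[, , "AB", drop = FALSE] * freq[, , "ab", drop = FALSE] -
    freq[, , "Ab", drop = FALSE] * freq[, , "aB", drop = FALSE]
  list(freq = freq, d = matrix(d, replicates, generations + 1L))
}

# Random perfect pairing of the gamete pool; each {AB,ab} pairing recombines
# to {Ab,aB} with probability r, and vice versa.
wf_recombine <- function(counts, r) {
  if (r == 0) return(counts)
  n <- sum(counts)
  types <- rep.int(1:4, counts)
  perm <- sample.int(n)
  first <- types[perm[seq_len(n / 2)]]
  second <- types[perm[n / 2 + seq_len(n / 2)]]
  x_ab <- sum((first == 1L & second == 4L) | (first == 4L & second == 1L))
  x_rep <- sum((first == 2L & second == 3L) | (first == 3L & second == 2L))
  r1 <- stats::rbinom(1L, x_ab, r)   # {AB,ab} -> {Ab,aB}
  r2 <- stats::rbinom(1L, x_rep, r)  # {Ab,aB} -> {AB,ab}
  counts + c(r2 - r1, r1 - r2, r1 - r2, r2 - r1)
}

wf_select <- function(counts, fitness, n_tot) {
  w <- counts * fitness
  if (sum(w) <= 0) return(integer(4L))
  drop(stats::rmultinom(1L, n_tot, w / sum(w)))
}
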