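#' Hudson's Fst with a permutation test
#'
#' `Fst = 1 - Hw/Hb` with `Hw` the mean within-population diversity
#' `(pi1 + pi2)/2` and `Hb = dxy`, all on the jointly retained sites. When
#' `Hb = 0` the statistic is defined as 0, and small negative estimates
#' (within-population diversity exceeding between-population diversity) are
#' clamped to 0, so the reported value is always in `[0, 1]`. The p-value is
#' the proportion of population-label permutations with `Fst >= observed`.
#'
#' @param pair a [pop_pair()] with at least two sequences per population.
#' @param n_perm number of label permutations.
#' @param seed RNG seed for the permutations.
#' @return list with `fst`, `p`, `n_perm`.
#' @export
hudson_fst <- function(pair, n_perm = 1000, seed = 1) {
  stopifnot(inherits(pair, "pop_pair"))
  if (pair$n1 < 2 || pair$n2 < 2) {
    stop("insufficient data: Fst needs at least 2 sequences per population")
  }
  m <- clean_matrix(pooled_matrix(pair))
  n <- nrow(m)
  n1 <- pair$n1
  # per-site-summed pairwise difference matrix, reused across permutations
  L <- ncol(m)
  D <- matrix(0, n, n)
  if (L > 0) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        D[i, j] <- D[j, i] <- sum(m[i, ] != m[j, ])
      }
    }
    D <- D / L
  }
  fst_of <- function(idx1) {
    idx2 <- setdiff(seq_len(n), idx1)
    hw1 <- if (length(idx1) > 1) mean(D[idx1, idx1][upper.tri(diag(length(idx1)))]) else 0
    hw2 <- if (length(idx2) > 1) mean(D[idx2, idx2][upper.tri(diag(length(idx2)))]) else 0
    hb <- mean(D[idx1, idx2])
    if (hb <= 0) return(0)
    max(0, 1 - ((hw1 + hw2) / 2) / hb)
  }
  obs <- fst_of(seq_len(n1))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) fst_of(sample(n, n1)),
                 numeric(1))
  list(fst = obs, p = mean(perm >= obs), n_perm = as.integer(n_perm))
}
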