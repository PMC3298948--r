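# Fu's Fs, Ramos-Onsins & Rozas's R2, and their coalescent p-values.

# log |s(n, k)| (unsigned Stirling numbers of the first kind), rows 1..n
log_stirling1 <- function(n) {
  L <- matrix(-Inf, n, n)
  L[1, 1] <- 0
  if (n > 1) {
    for (m in 1:(n - 1)) {
      for (k in 1:m) {
        # |s(m+1, k+?)|: s(m+1, k) = s(m, k-1) + m * s(m, k)
        a <- if (k > 1) L[m, k - 1] else -Inf
        b <- L[m, k] + log(m)
        L[m + 1, k] <- if (is.infinite(a)) b else
          max(a, b) + log1p(exp(-abs(a - b)))
      }
      L[m + 1, m + 1] <- 0
    }
  }
  L
}

# P(K >= k | theta, n) under the Ewens sampling formula
ewens_p_ge <- function(k, theta, n, logS = NULL) {
  if (theta <= 0) return(NA_real_)
  if (is.null(logS)) logS <- log_stirling1(n)
  lrise <- sum(log(theta + 0:(n - 1)))
  lp <- logS[n, 1:n] + (1:n) * log(theta) - lrise
  p <- exp(lp)
  p <- p / sum(p) # renormalise against rounding
  sum(p[k:n])
}

#' Fu's Fs
#'
#' `Fs = ln(S'/(1-S'))` with `S' = P(K >= k_obs | theta = khat)`, the Ewens
#' sampling-formula probability of observing at least as many distinct
#' haplotypes as seen, given the pairwise-difference estimate of theta.
#' Strongly negative values indicate an excess of haplotypes, as after
#' population expansion.
#'
#' @inheritParams nucleotide_diversity
#' @return list with `fs` (NA when not applicable), `applicable`, `k_obs`,
#'   `khat`, `n`.
#' @export
fus_fs <- function(seqs) {
  m <- clean_matrix(seq_matrix(seqs))
  n <- nrow(m)
  na <- list(fs = NA_real_, applicable = FALSE, k_obs = NA_integer_,
             khat = NA_real_, n = n)
  if (n < 3) return(na)
  khat <- if (ncol(m) > 0) mean_pairwise(m) else 0
  k_obs <- length(unique(row_strings(m)))
  if (khat <= 0) { na$k_obs <- k_obs; na$khat <- khat; return(na) }
  sp <- ewens_p_ge(k_obs, khat, n)
  if (sp >= 1 || sp <= 0) {
    # boundary (e.g. a single haplotype): +/- infinity, flagged NA
    na$k_obs <- k_obs; na$khat <- khat
    return(na)
  }
  list(fs = log(sp / (1 - sp)), applicable = TRUE, k_obs = as.integer(k_obs),
       khat = khat, n = n)
}

# singletons carried by each sequence: at a site, a base present exactly once
singleton_counts <- function(m) {
  U <- numeric(nrow(m))
  cnt <- site_counts(m)
  base_codes <- c("A", "C", "G", "T")
  for (s in seq_len(ncol(m))) {
    ones <- which(cnt[, s] == 1)
    for (b in ones) U[m[, s] == base_codes[b]] <- U[m[, s] == base_codes[b]] + 1
  }
  U
}

#' Ramos-Onsins and Rozas's R2
#'
#' `R2 = sqrt(mean((U_i - khat/2)^2)) / S` with `U_i` the number of singleton
#' mutations carried by sequence `i`. Small values indicate population
#' expansion.
#'
#' @inheritParams nucleotide_diversity
#' @return list with `r2` (NA when `S = 0`), `s`, `u`, `khat`.
#' @export
r2_statistic <- function(seqs) {
  m <- clean_matrix(seq_matrix(seqs))
  check_min_seqs(m, 2, "R2")
  S <- count_segregating(m)
  khat <- if (ncol(m) > 0) mean_pairwise(m) else 0
  if (S == 0) return(list(r2 = NA_real_, s = 0L, u = numeric(nrow(m)),
                          khat = khat))
  U <- singleton_counts(m)
  list(r2 = sqrt(mean((U - khat / 2)^2)) / S, s = as.integer(S), u = U,
       khat = khat)
}

#' Monte-Carlo p-values for Fu's Fs and R2
#'
#' Null replicates are constant-size neutral coalescent samples conditioned
#' on the observed sample size and number of segregating sites (fixed-S);
#' alternatively (`condition = "theta"`) mutations are Poisson with
#' `theta = khat` per replicate genealogy, which removes the conditioning on
#' S. Both statistics are small under population expansion, so p-values are
#' one-tailed left: `p = P(stat_rep <= stat_obs)`.
#'
#' @inheritParams nucleotide_diversity
#' @param n_reps number of coalescent replicates (default 10000).
#' @param seed RNG seed; the result is reproducible bit-for-bit given the
#'   seed.
#' @param condition `"S"` (default, fixed-S) or `"theta"`.
#' @return list of class `neutrality_result`: `fs`, `r2`, `p_fs`, `p_r2`,
#'   `n_reps`, `seed` (NA statistics propagate NA p-values).
#' @export
neutrality_pvalues <- function(seqs, n_reps = 10000, seed = 1,
                               condition = c("S", "theta")) {
  condition <- match.arg(condition)
  m <- clean_matrix(seq_matrix(seqs))
  check_min_seqs(m, 2, "neutrality tests")
  n <- nrow(m)
  fs_obs <- fus_fs(m)
  r2_obs <- r2_statistic(m)
  S <- r2_obs$s
  out <- list(fs = fs_obs$fs, r2 = r2_obs$r2, p_fs = NA_real_,
              p_r2 = NA_real_, n_reps = as.integer(n_reps),
              seed = as.integer(seed))
  class(out) <- "neutrality_result"
  if (S == 0) return(out)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  if (condition == "S") {
    reps <- cpp_fixed_s_reps(n, S, n_reps)
  } else {
    # fixed-theta alternative: draw S per replicate from the khat-scaled null
    theta <- fs_obs$khat
    a1 <- sum(1 / seq_len(n - 1))
    Ss <- stats::rpois(n_reps, theta * a1) # approximate mixing over genealogy
    reps <- do.call(rbind, lapply(Ss, function(s) {
      if (s == 0) return(c(khat = 0, n_hap = 1, r2 = NA_real_))
      cpp_fixed_s_reps(n, s, 1)[1, ]
    }))
  }
  logS <- log_stirling1(n)
  if (!is.na(fs_obs$fs)) {
    fs_rep <- vapply(seq_len(nrow(reps)), function(i) {
      kh <- reps[i, 1]
      k <- reps[i, 2]
      if (kh <= 0) return(NA_real_)
      sp <- ewens_p_ge(k, kh, n, logS)
      if (sp >= 1 || sp <= 0) return(NA_real_)
      log(sp / (1 - sp))
    }, numeric(1))
    ok <- !is.na(fs_rep)
    out$p_fs <- mean(fs_rep[ok] <= fs_obs$fs)
  }
  if (!is.na(r2_obs$r2)) {
    r2_rep <- reps[, 3]
    ok <- !is.na(r2_rep)
    out$p_r2 <- mean(r2_rep[ok] <= r2_obs$r2)
  }
  out
}

#' @export
print.neutrality_result <- function(x, ...) {
  cat(sprintf("Fu's Fs = %s (p = %s)   R2 = %s (p = %s)   [%d replicates]\n",
              format(x$fs, digits = 4), format(x$p_fs, digits = 3),
              format(x$r2, digits = 4), format(x$p_r2, digits = 3),
              x$n_reps))
  invisible(x)
}

# save/restore .Random.seed so statistical helpers do not disturb the
# caller's RNG stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
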