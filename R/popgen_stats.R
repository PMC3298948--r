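# Per-sample and per-pair DNA polymorphism statistics.
#
# Sites with N or '-' in any sequence of the sample under analysis are
# excluded (complete deletion); per-site denominators use the retained-site
# count. Pair statistics (dxy, da, pooled pi/thetaW/D) are computed on sites
# retained jointly across both populations, which makes the identity
# da = dxy - (pi1 + pi2)/2 exact by construction.

# per-site allele counts: 4 x nsites matrix of A/C/G/T counts
site_counts <- function(m) {
  apply(m, 2, function(col) tabulate(match(col, c("A", "C", "G", "T")), 4))
}

# mean pairwise differences per sequence pair, total over sites (khat)
mean_pairwise <- function(m) {
  n <- nrow(m)
  if (n < 2) return(0)
  cnt <- site_counts(m)
  prs <- n * (n - 1) / 2
  sum(prs - colSums(cnt * (cnt - 1) / 2)) / prs
}

#' Nucleotide diversity (pi)
#'
#' Mean number of pairwise differences over all unordered sequence pairs,
#' divided by the number of analysed sites.
#'
#' @param seqs aligned sequences (see [seq_matrix()]).
#' @return per-site nucleotide diversity.
#' @examples
#' nucleotide_diversity(c("ACGT", "ACGA", "ACGA")) # 1/6
#' @export
nucleotide_diversity <- function(seqs) {
  m <- seq_matrix(seqs)
  check_min_seqs(m, 2, "nucleotide diversity")
  m <- clean_matrix(m)
  if (ncol(m) == 0) return(0)
  mean_pairwise(m) / ncol(m)
}

# number of segregating (polymorphic) sites among retained sites
count_segregating <- function(m) {
  if (ncol(m) == 0) return(0L)
  cnt <- site_counts(m)
  sum(colSums(cnt > 0) >= 2)
}

#' Watterson's theta
#'
#' `S / (a_n * L)` with `a_n = sum(1/i, i = 1..n-1)`, `S` the number of
#' segregating sites and `L` the number of analysed sites.
#'
#' @inheritParams nucleotide_diversity
#' @return per-site Watterson's theta.
#' @export
watterson_theta <- function(seqs) {
  m <- seq_matrix(seqs)
  check_min_seqs(m, 2, "Watterson's theta")
  m <- clean_matrix(m)
  if (ncol(m) == 0) return(0)
  a1 <- sum(1 / seq_len(nrow(m) - 1))
  count_segregating(m) / (a1 * ncol(m))
}

#' Between-population divergence and net divergence
#'
#' `dxy` is the mean per-site difference over all between-population sequence
#' pairs; `da = dxy - (pi1 + pi2)/2` is the net divergence. `da` may be
#' slightly negative; it is clamped to zero only inside the ABC summary
#' vector ([observed_vector()]), not here.
#'
#' @param pair a [pop_pair()].
#' @return list with `dxy`, `da`, `pi1`, `pi2`, all per site over the jointly
#'   retained sites.
#' @export
net_divergence <- function(pair) {
  stopifnot(inherits(pair, "pop_pair"))
  m <- clean_matrix(pooled_matrix(pair))
  L <- ncol(m)
  n1 <- pair$n1
  m1 <- m[seq_len(n1), , drop = FALSE]
  m2 <- m[-seq_len(n1), , drop = FALSE]
  if (L == 0) return(list(dxy = 0, da = 0, pi1 = 0, pi2 = 0))
  c1 <- site_counts(m1)
  c2 <- site_counts(m2)
  dxy <- sum(pair$n1 * pair$n2 - colSums(c1 * c2)) / (pair$n1 * pair$n2) / L
  pi1 <- if (pair$n1 > 1) mean_pairwise(m1) / L else 0
  pi2 <- if (pair$n2 > 1) mean_pairwise(m2) / L else 0
  list(dxy = dxy, da = dxy - (pi1 + pi2) / 2, pi1 = pi1, pi2 = pi2)
}

tajima_constants_r <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' Standard Tajima (1989) `D = (khat - S/a1) / sqrt(e1*S + e2*S*(S-1))` with
#' `khat` the mean pairwise difference count. With `S = 0` the statistic is
#' undefined and flagged rather than thrown.
#'
#' @inheritParams nucleotide_diversity
#' @return list with `d` (NA if undefined), `defined`, `s`, `khat`, `n`.
#' @export
tajimas_d <- function(seqs) {
  m <- seq_matrix(seqs)
  check_min_seqs(m, 2, "Tajima's D")
  m <- clean_matrix(m)
  n <- nrow(m)
  S <- count_segregating(m)
  khat <- if (ncol(m) > 0) mean_pairwise(m) else 0
  if (S == 0) {
    return(list(d = NA_real_, defined = FALSE, s = 0L, khat = khat, n = n))
  }
  tc <- tajima_constants_r(n)
  den <- sqrt(tc$e1 * S + tc$e2 * S * (S - 1))
  if (!is.finite(den) || den <= 0) {
    # n = 3 has e1 = e2 = 0: the variance estimate vanishes and D is undefined
    return(list(d = NA_real_, defined = FALSE, s = as.integer(S),
                khat = khat, n = n))
  }
  list(d = (khat - S / tc$a1) / den, defined = TRUE, s = as.integer(S),
       khat = khat, n = n)
}

#' Guarded inverse of Tajima's D
#'
#' `1/D`, with a bounded guard so that the quantity stays usable inside ABC
#' distance computations: if `D` is undefined (`S = 0`) the value is 0; if
#' `|D| < 0.001` it is `sign(D) * guard`.
#'
#' @param seqs aligned sequences, or the result of [tajimas_d()].
#' @param guard guard magnitude, default 1000.
#' @return guarded `1/D`.
#' @export
inv_tajima_d <- function(seqs, guard = 1000) {
  td <- if (is.list(seqs) && !is.null(seqs$defined)) seqs else tajimas_d(seqs)
  if (!td$defined) return(0)
  if (abs(td$d) < 0.001) return(sign(td$d) * guard)
  1 / td$d
}

#' Per-site Tajima's D denominator
#'
#' The sampling standard deviation of `pi - thetaW` evaluated with the
#' per-site segregating fraction `s = S/L` in place of the count `S`:
#' `sqrt(e1*s + e2*s*(s-1))`. This is the fourth default summary statistic of
#' the msBayes pipeline (often labelled "1/Tajima's D" in published tables).
#'
#' @inheritParams nucleotide_diversity
#' @return per-site Tajima denominator; 0 when `S = 0`.
#' @export
tajd_denom <- function(seqs) {
  m <- seq_matrix(seqs)
  check_min_seqs(m, 2, "Tajima denominator")
  m <- clean_matrix(m)
  S <- count_segregating(m)
  if (S == 0 || ncol(m) == 0) return(0)
  tc <- tajima_constants_r(nrow(m))
  s <- S / ncol(m)
  sqrt(tc$e1 * s + tc$e2 * s * (s - 1))
}

#' Haplotype count and diversity
#'
#' Distinct sequences counted on the retained sites;
#' `HD = n/(n-1) * (1 - sum(f_i^2))` with the Nei (1987) sampling variance.
#'
#' @inheritParams nucleotide_diversity
#' @return list with `hap_count`, `hap_diversity`, `sd`.
#' @export
haplotype_stats <- function(seqs) {
  m <- seq_matrix(seqs)
  check_min_seqs(m, 2, "haplotype statistics")
  m <- clean_matrix(m)
  n <- nrow(m)
  f <- as.vector(table(row_strings(m))) / n
  hd <- n / (n - 1) * (1 - sum(f^2))
  s2 <- sum(f^2)
  v <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum(f^3) - s2^2) + s2 - s2^2)
  list(hap_count = length(f), hap_diversity = hd, sd = sqrt(max(v, 0)))
}

#' Parsimony-informative site count
#'
#' A site is parsimony-informative when at least two distinct bases are each
#' carried by at least two sequences (complete deletion applied first).
#'
#' @inheritParams nucleotide_diversity
#' @return integer count.
#' @export
parsimony_informative <- function(seqs) {
  m <- clean_matrix(seq_matrix(seqs))
  if (ncol(m) == 0) return(0L)
  cnt <- site_counts(m)
  as.integer(sum(colSums(cnt >= 2) >= 2))
}

#' All per-pair polymorphism and divergence statistics
#'
#' One call computing the within-population, pooled and between-population
#' statistics for a population pair. Pooled and between-population values use
#' the jointly retained sites; within-population `pi_1`/`pi_2` reported here
#' also use the joint sites so that `da = dxy - (pi_1 + pi_2)/2` holds to
#' machine precision.
#'
#' @param pair a [pop_pair()].
#' @param guard guard for [inv_tajima_d()].
#' @return list of class `pair_stats` with fields `pi_1`, `pi_2`, `pi_total`,
#'   `dxy`, `da`, `theta_w_1`, `theta_w_2`, `theta_w_total`, `tajima_d`,
#'   `inv_tajima_d`, `tajd_denom`, `hap_count`, `hap_diversity`, `hap_sd`,
#'   `s`, `pars_inf`, `n1`, `n2`, `length` (retained sites).
#' @export
pair_stats <- function(pair, guard = 1000) {
  stopifnot(inherits(pair, "pop_pair"))
  m <- clean_matrix(pooled_matrix(pair))
  nd <- net_divergence(pair)
  n1 <- pair$n1
  m1 <- m[seq_len(n1), , drop = FALSE]
  m2 <- m[-seq_len(n1), , drop = FALSE]
  thw <- function(mm) {
    if (nrow(mm) < 2 || ncol(mm) == 0) return(0)
    count_segregating(mm) / (sum(1 / seq_len(nrow(mm) - 1)) * ncol(mm))
  }
  td <- tajimas_d(m)
  hp <- haplotype_stats(m)
  out <- list(
    pi_1 = nd$pi1, pi_2 = nd$pi2,
    pi_total = if (ncol(m) > 0) mean_pairwise(m) / ncol(m) else 0,
    dxy = nd$dxy, da = nd$da,
    theta_w_1 = thw(m1), theta_w_2 = thw(m2), theta_w_total = thw(m),
    tajima_d = td$d, inv_tajima_d = inv_tajima_d(td, guard = guard),
    tajd_denom = tajd_denom(m),
    hap_count = hp$hap_count, hap_diversity = hp$hap_diversity,
    hap_sd = hp$sd,
    s = td$s, pars_inf = parsimony_informative(m),
    n1 = pair$n1, n2 = pair$n2, length = ncol(m))
  class(out) <- "pair_stats"
  out
}

#' @export
print.pair_stats <- function(x, ...) {
  cat("pair_stats (", x$n1, "+", x$n2, " seqs, ", x$length,
      " analysed sites)\n", sep = "")
  cat(sprintf("  pi_total %.6f  da %.6f  thetaW %.6f  S %d  D %s\n",
              x$pi_total, x$da, x$theta_w_total, x$s,
              ifelse(is.na(x$tajima_d), "undef",
                     sprintf("%.3f", x$tajima_d))))
  invisible(x)
}
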