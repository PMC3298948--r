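#' Ordered ABC summary vector for a set of population pairs
#'
#' For each pair computes, on the pooled two-population sample, the four
#' default summary statistics of the hierarchical ABC stage: nucleotide
#' diversity `pi`, net divergence `net_pi` (clamped at 0), Watterson's
#' `theta_w`, and a fourth statistic that is either the per-site Tajima's D
#' denominator ([tajd_denom()], default — the statistic used by the msBayes
#' pipeline) or the guarded inverse of Tajima's D ([inv_tajima_d()]). Pairs
#' are ordered ascending by `net_pi`, ties broken by `pi` ascending; the same
#' ordering rule is applied to simulated vectors, which makes the vector
#' exchangeable over species identities.
#'
#' @param pairs list of [pop_pair()] objects (at least 2).
#' @param fourth_stat `"tajd_denom"` (default) or `"inv_tajima_d"`.
#' @param guard guard magnitude for [inv_tajima_d()].
#' @return data frame of class `summary_vector` with columns `species`,
#'   `pi`, `net_pi`, `theta_w` and the fourth statistic, one row per pair,
#'   sorted by the ordering rule.
#' @export
observed_vector <- function(pairs,
                            fourth_stat = c("tajd_denom", "inv_tajima_d"),
                            guard = 1000) {
  fourth_stat <- match.arg(fourth_stat)
  if (length(pairs) < 2) stop("need at least 2 population pairs")
  rows <- lapply(pairs, function(p) {
    st <- pair_stats(p, guard = guard)
    data.frame(species = p$species,
               pi = st$pi_total,
               net_pi = max(st$da, 0),
               theta_w = st$theta_w_total,
               stat4 = if (fourth_stat == "tajd_denom") st$tajd_denom
                       else st$inv_tajima_d,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  names(df)[names(df) == "stat4"] <- fourth_stat
  sort_summary_vector(df)
}

# ordering rule shared by observed and simulated vectors
sort_summary_vector <- function(df) {
  df <- df[order(df$net_pi, df$pi), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("summary_vector", "data.frame")
  df
}

#' Flatten a summary vector for ABC distance computation
#'
#' Concatenates the per-pair statistic blocks in the sorted order, matching
#' the column layout of [reference_table()].
#'
#' @param sv a `summary_vector` data frame (or any data frame with the four
#'   statistic columns after `species`).
#' @return numeric vector of length `4 * K`.
#' @export
flatten_summary <- function(sv) {
  stats_cols <- setdiff(names(sv), "species")
  as.vector(t(as.matrix(sv[, stats_cols])))
}
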