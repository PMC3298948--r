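# Conversion of mutation-scaled divergence estimates to years.
#
# The clock is an imported avian mtDNA divergence rate: 2.1% sequence
# divergence between a pair of lineages per million years, i.e. a
# per-lineage rate of 1.05e-8 substitutions per site per year. tau from the
# hierarchical ABC stage is in units of 4*N_ave generations with N_ave
# defined by theta_ave (half the theta-prior upper bound), so
# years = tau * theta_ave / rate_per_site_per_year — the unique reading of
# the tau clock that is simultaneously consistent with the per-generation
# mutation rate (mu_gen = rate_per_year * generation_time) and a
# generation-time multiplier.

#' Molecular-clock configuration
#'
#' @param divergence_rate divergence between two lineages, as a fraction per
#'   million years (default 0.021 = the general avian mtDNA rate of 2.1%/My).
#' @param generation_time generation time in years (default 2).
#' @param theta_ave reference per-site theta = half the theta-prior upper
#'   bound (default 0.0125).
#' @return list of class `clock_config` including the derived
#'   `rate_site_year` (= `divergence_rate / 2e6`, per lineage per site per
#'   year).
#' @export
clock_config <- function(divergence_rate = 0.021, generation_time = 2,
                         theta_ave = 0.0125) {
  stopifnot(divergence_rate > 0, generation_time > 0, theta_ave > 0)
  structure(list(divergence_rate = divergence_rate,
                 generation_time = generation_time,
                 theta_ave = theta_ave,
                 rate_site_year = divergence_rate / 2e6),
            class = "clock_config")
}

#' Convert a coalescent-scaled divergence time (tau) to years
#'
#' `years = tau * theta_ave / rate_site_year`. With the default clock this
#' is exactly `tau * 1190476.190...` years.
#'
#' @param tau divergence time in `4*N_ave`-generation units (vectorised).
#' @param clock a [clock_config()].
#' @return years.
#' @export
tau_to_years <- function(tau, clock = clock_config()) {
  stopifnot(all(tau >= 0 | is.na(tau)))
  tau * clock$theta_ave / clock$rate_site_year
}

#' Inverse of [tau_to_years()]
#'
#' @param years divergence time in years.
#' @param clock a [clock_config()].
#' @return tau.
#' @export
years_to_tau <- function(years, clock = clock_config()) {
  years * clock$rate_site_year / clock$theta_ave
}

#' Convert a per-locus mutation-scaled IM divergence time to years
#'
#' `years = t / (rate_site_year * geometric_mean(locus_lengths))`: the
#' per-locus per-year mutation rate is the per-site rate times the geometric
#' mean of the locus lengths.
#'
#' @param t mutation-scaled divergence time (expected substitutions per
#'   locus; vectorised).
#' @param locus_lengths locus lengths in bp (all > 0).
#' @param clock a [clock_config()].
#' @return years.
#' @export
imtime_to_years <- function(t, locus_lengths, clock = clock_config()) {
  stopifnot(all(t >= 0 | is.na(t)), length(locus_lengths) >= 1)
  if (any(locus_lengths <= 0)) stop("locus lengths must be positive")
  mu_locus_year <- clock$rate_site_year * geomean_length(locus_lengths)
  t / mu_locus_year
}

#' Convert net divergence (Da) values directly to years
#'
#' `years = mean(da) / divergence_rate * 1e6`: the average per-site net
#' divergence divided by the between-lineage divergence rate.
#'
#' @param da_values per-site net divergences (all >= 0).
#' @param clock a [clock_config()].
#' @return years.
#' @export
da_to_years <- function(da_values, clock = clock_config()) {
  if (length(da_values) == 0) stop("empty Da list")
  stopifnot(all(da_values >= 0))
  mean(da_values) / clock$divergence_rate * 1e6
}
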