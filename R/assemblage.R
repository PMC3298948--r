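# Species-assemblage isolation-with-migration fit: the IM model is fitted
# jointly to several species' population pairs, treating species as loci.
# Shared parameters (theta1, theta2, thetaA, m1, m2, t) describe the
# assemblage; per-species inheritance scalars h (reference species h = 1)
# scale all three effective sizes, letting species differ in effective
# population size while divergence time and migration are shared.
#
# The model is identical to the classical two-population IM model; the
# genealogy-sampling MCMC of the classical fit is replaced by
# simulation-based inference (ABC rejection + local-linear adjustment), so
# assemblage posteriors are validated by parameter-recovery properties, not
# by equality with any particular MCMC implementation.

#' Assemblage IM parameter set
#'
#' @param theta1,theta2,thetaA per-site mutation-scaled diversities of the
#'   two descendant assemblages and the ancestral assemblage (reference
#'   species scale; species `s` uses `theta * h[s]`).
#' @param t divergence time on the per-locus mutation scale (expected
#'   substitutions per locus, locus = geometric-mean length; the scale of
#'   [imtime_to_years()]).
#' @param m1,m2 directional scaled migration rates (per lineage per
#'   `4*N_ave` generations; `m1` = into population 1).
#' @param h per-species inheritance scalars; `h[1]` must be 1 (reference).
#' @return list of class `assemblage_params`.
#' @export
assemblage_params <- function(theta1, theta2, thetaA, t, m1 = 0, m2 = 0,
                              h = 1) {
  stopifnot(theta1 >= 0, theta2 >= 0, thetaA >= 0, t >= 0, m1 >= 0, m2 >= 0,
            all(h > 0), abs(h[1] - 1) < 1e-12)
  structure(list(theta1 = theta1, theta2 = theta2, thetaA = thetaA,
                 t = t, m1 = m1, m2 = m2, h = h),
            class = "assemblage_params")
}

# geometric mean of alignment lengths ("per-locus" reference length)
geomean_length <- function(lengths) exp(mean(log(lengths)))

#' Simulate a co-diverging species assemblage
#'
#' Each species' pair is simulated under the two-population IM coalescent
#' with the shared divergence time and migration rates and species-specific
#' effective sizes `theta * h[s]`, under HKY mutation.
#'
#' @param params an [assemblage_params()]; `h` must have one entry per
#'   species.
#' @param specs per-species [pair_spec()] list (or data frame with `n1`,
#'   `n2`, `length`).
#' @param theta_ave reference per-site theta for the clock (default 0.0125).
#' @return list of [pop_pair()] objects, one per species.
#' @export
simulate_assemblage <- function(params, specs, theta_ave = 0.0125) {
  stopifnot(inherits(params, "assemblage_params"))
  specs <- as_spec_list(specs)
  K <- length(specs)
  if (length(params$h) != K) stop("h must have one entry per species")
  L <- vapply(specs, `[[`, integer(1), "length")
  t_site <- params$t / geomean_length(L)
  tau <- if (theta_ave > 0) t_site / theta_ave else 0
  lapply(seq_len(K), function(s) {
    sp <- specs[[s]]
    h <- params$h[s]
    seqs <- cpp_sim_pair_seqs(sp$n1, sp$n2, sp$length,
                              params$theta1 * h, params$theta2 * h,
                              params$thetaA * h, tau, params$m1, params$m2,
                              theta_ave, sp$kappa, sp$base_freqs)
    pop_pair(seqs[seq_len(sp$n1)], seqs[-seq_len(sp$n1)],
             species = sprintf("species%02d", s))
  })
}

# per-species 6-statistic summary block: pi1, pi2, dxy, net_pi, S/L, D
assemblage_summary <- function(pairs) {
  unlist(lapply(pairs, function(p) {
    st <- pair_stats(p)
    c(st$pi_1, st$pi_2, st$dxy, st$da, st$s / max(st$length, 1),
      if (is.na(st$tajima_d)) 0 else st$tajima_d)
  }))
}

#' Prior bounds for the assemblage IM fit
#'
#' Uniform prior bounds; defaults span the ranges a shallow mtDNA divergence
#' plausibly occupies and are meant to be refined per analysis.
#'
#' @param theta_upper upper bound for `theta1` and `theta2` (per site).
#' @param thetaA_upper upper bound for `thetaA`.
#' @param t_upper upper bound for `t` (per-locus mutation scale).
#' @param m_upper upper bound for both migration rates (0 disables
#'   migration).
#' @param h_min lower bound of the inheritance-scalar prior `U(h_min, 1]`
#'   for non-reference species.
#' @return list of class `im_prior`.
#' @export
im_prior <- function(theta_upper = 0.025, thetaA_upper = 0.025,
                     t_upper = 40, m_upper = 0, h_min = 0.1) {
  stopifnot(theta_upper > 0, thetaA_upper > 0, t_upper > 0, m_upper >= 0,
            h_min > 0, h_min <= 1)
  structure(list(theta_upper = theta_upper, thetaA_upper = thetaA_upper,
                 t_upper = t_upper, m_upper = m_upper, h_min = h_min),
            class = "im_prior")
}

#' Fit the IM model to a species assemblage by ABC
#'
#' Simulates parameter draws from the uniform priors, summarises each
#' species pair by `(pi1, pi2, dxy, net_pi, S/L, D)` concatenated in fixed
#' species order, and applies ABC rejection with local-linear adjustment.
#' A single species is a valid degenerate assemblage (ordinary pairwise IM
#' fit, `h` fixed at 1).
#'
#' @param data list of [pop_pair()] objects (the assemblage), or a
#'   precomputed observed summary vector from [assemblage_summary_of()].
#' @param specs per-species designs; defaults to the designs implied by
#'   `data`.
#' @param prior an [im_prior()].
#' @param n_sims number of prior draws.
#' @param n_accept number of accepted draws.
#' @param seed integer seed.
#' @param theta_ave reference per-site theta.
#' @param chunk_size draws per chunk.
#' @return object of class `assemblage_posterior`: per-parameter list of
#'   adjusted posteriors (`theta1`, `theta2`, `thetaA`, `t`, `m1`, `m2`,
#'   and `h_2..h_K`), each with `mode` (peak posterior), `q025`, `q975`;
#'   plus run metadata.
#' @export
fit_assemblage <- function(data, specs = NULL, prior = im_prior(),
                           n_sims = 20000, n_accept = 200, seed = 1,
                           theta_ave = 0.0125, chunk_size = 10000) {
  if (is.list(data) && all(vapply(data, inherits, logical(1), "pop_pair"))) {
    if (is.null(specs)) {
      specs <- lapply(data, function(p) pair_spec(p$n1, p$n2, p$length))
    }
    obs <- assemblage_summary(data)
  } else {
    if (is.null(specs)) stop("specs required when 'data' is a summary vector")
    obs <- as.numeric(data)
  }
  specs <- as_spec_list(specs)
  K <- length(specs)
  if (length(obs) != 6 * K) stop("observed summary has wrong length")
  if (n_sims < n_accept) stop("fewer simulations than accepted draws requested")
  n1 <- vapply(specs, `[[`, integer(1), "n1")
  n2 <- vapply(specs, `[[`, integer(1), "n2")
  L <- vapply(specs, `[[`, integer(1), "length")
  gL <- geomean_length(L)
  t_site_upper <- prior$t_upper / gL
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  n_chunks <- ceiling(n_sims / chunk_size)
  tabs <- vector("list", n_chunks)
  for (ch in seq_len(n_chunks)) {
    nd <- min(chunk_size, n_sims - (ch - 1) * chunk_size)
    set.seed((seed + 104729 * ch) %% .Machine$integer.max)
    tabs[[ch]] <- cpp_assemblage_table(
      nd, n1, n2, L, prior$theta_upper, prior$thetaA_upper, t_site_upper,
      prior$m_upper, prior$h_min, theta_ave, specs[[1]]$kappa,
      specs[[1]]$base_freqs)
  }
  tab <- do.call(rbind, tabs)
  npar <- 6 + (K - 1)
  par_names <- c("theta1", "theta2", "thetaA", "t", "m1", "m2",
                 if (K > 1) paste0("h_", 2:K))
  stats <- tab[, (npar + 1):ncol(tab), drop = FALSE]
  acc <- abc_reject(stats, obs, n_accept)
  posts <- lapply(seq_len(npar), function(j) {
    x <- tab[acc$idx, j]
    if (j == 4) x <- x * gL # report t on the per-locus scale
    adjust_continuous(x, acc)
  })
  names(posts) <- par_names
  structure(list(posteriors = posts, n_sims = n_sims, n_accept = n_accept,
                 seed = seed, prior = prior, k_species = K,
                 geomean_length = gL, acc = acc),
            class = "assemblage_posterior")
}

#' Observed summary vector for an assemblage
#'
#' @param pairs list of [pop_pair()] in fixed species order.
#' @return numeric vector of length `6 * K`.
#' @export
assemblage_summary_of <- function(pairs) assemblage_summary(pairs)

#' @export
print.assemblage_posterior <- function(x, ...) {
  cat("Assemblage IM posterior (", x$k_species, " species, ", x$n_accept,
      "/", x$n_sims, " draws accepted)\n", sep = "")
  for (nm in names(x$posteriors)) {
    p <- x$posteriors[[nm]]
    cat(sprintf("  %-8s peak %.5g  (2.5%%-97.5%%: %.5g-%.5g)\n",
                nm, p$mode, p$q025, p$q975))
  }
  invisible(x)
}

#' Align HABC and assemblage-IM divergence-time estimates
#'
#' Converts each stage's mutation-scaled divergence-time summaries to years
#' with the shared clock and tabulates them side by side, including interval
#' widths (so "reduced credibility intervals" is an assertable comparison).
#'
#' @param im_fits named list of [fit_assemblage()] results, one per event.
#' @param habc_events `events` data frame from [constrained_habc()] (or any
#'   data frame with `tau_mode`, `tau_q025`, `tau_q975`), one row per event,
#'   aligned with `im_fits`; rows of all-NA flag a missing interval.
#' @param lengths list of per-event alignment-length vectors (for the
#'   per-locus mutation rate of the IM conversion).
#' @param clock a [clock_config()].
#' @return data frame with per-event years: HABC mode and interval, IM peak
#'   and interval, both interval widths, and a `flagged` column for rows
#'   with missing HABC intervals.
#' @export
compare_events <- function(im_fits, habc_events, lengths,
                           clock = clock_config()) {
  stopifnot(length(im_fits) >= 1,
            nrow(habc_events) == length(im_fits),
            length(lengths) == length(im_fits))
  rows <- lapply(seq_along(im_fits), function(i) {
    ev <- habc_events[i, ]
    tpost <- im_fits[[i]]$posteriors$t
    hb <- c(tau_to_years(ev$tau_mode, clock),
            tau_to_years(ev$tau_q025, clock),
            tau_to_years(ev$tau_q975, clock))
    im <- c(imtime_to_years(tpost$mode, lengths[[i]], clock),
            imtime_to_years(tpost$q025, lengths[[i]], clock),
            imtime_to_years(tpost$q975, lengths[[i]], clock))
    flagged <- anyNA(hb)
    data.frame(event = i,
               habc_mode_yr = hb[1], habc_lo_yr = hb[2], habc_hi_yr = hb[3],
               im_peak_yr = im[1], im_lo_yr = im[2], im_hi_yr = im[3],
               habc_width_yr = hb[3] - hb[2], im_width_yr = im[3] - im[2],
               flagged = flagged)
  })
  do.call(rbind, rows)
}
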