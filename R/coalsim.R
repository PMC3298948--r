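# Hierarchical co-divergence model: hyper-prior draws and finite-sites
# coalescent simulation of population pairs.
#
# Time unit: 4*N_ave generations, with N_ave the reference size defined by
# theta_ave = half the theta-prior upper bound (the same clock the
# year-conversion layer uses, so tau estimates convert directly via
# years = tau * theta_ave / mu_per_site_per_year).

#' Hyper-prior for the co-divergence model
#'
#' @param psi_max maximum number of co-divergence events (default 10, the
#'   number of pairs in the motivating design).
#' @param tau_upper upper bound of the uniform prior on event times, in units
#'   of `4*N_ave` generations (default 3.0).
#' @param theta_upper upper bound of the per-site theta prior (default 0.025).
#' @param ancestral_frac_upper upper bound on the ancestral population size
#'   as a fraction of the pair's theta (default 0.25).
#' @param migration_upper upper bound of the symmetric scaled migration-rate
#'   prior (default 0; an alternative analysis uses 0.5).
#' @param recomb_upper recombination-rate upper bound; only 0 is supported
#'   (non-recombining mtDNA).
#' @param founding_frac_lower lower bound of the founding-bottleneck prior:
#'   each descendant population is founded at a fraction `B ~ U(lower, 1)`
#'   of its present size, stays there from `tau` back to `0.75*tau`, and
#'   grows exponentially to its present size over the most recent
#'   `0.75*tau` (the msBayes sub-model). Set to 1 to disable the phase.
#' @return list of class `hyper_prior`. `theta_ave = theta_upper/2` is
#'   attached for the clock convention.
#' @export
hyper_prior <- function(psi_max = 10, tau_upper = 3.0, theta_upper = 0.025,
                        ancestral_frac_upper = 0.25, migration_upper = 0,
                        recomb_upper = 0, founding_frac_lower = 0.01) {
  stopifnot(psi_max >= 1, tau_upper >= 0, theta_upper >= 0,
            ancestral_frac_upper >= 0, migration_upper >= 0,
            founding_frac_lower > 0, founding_frac_lower <= 1)
  if (recomb_upper != 0) {
    stop("recombination is not modelled (mtDNA assumption); recomb_upper must be 0")
  }
  structure(list(psi_max = as.integer(psi_max), tau_upper = tau_upper,
                 theta_upper = theta_upper,
                 ancestral_frac_upper = ancestral_frac_upper,
                 migration_upper = migration_upper,
                 recomb_upper = 0,
                 founding_frac_lower = founding_frac_lower,
                 theta_ave = theta_upper / 2),
            class = "hyper_prior")
}

#' Per-pair simulation design
#'
#' @param n1,n2 sample sizes of the two populations (each >= 2).
#' @param length alignment length in bp.
#' @param base_freqs equilibrium base frequencies (A, C, G, T).
#' @param kappa HKY transition/transversion rate ratio (default 8, typical
#'   for avian mtDNA).
#' @return list of class `pair_spec`.
#' @export
pair_spec <- function(n1, n2, length, base_freqs = rep(0.25, 4), kappa = 8) {
  stopifnot(n1 >= 2, n2 >= 2, length > 0, length(base_freqs) == 4,
            abs(sum(base_freqs) - 1) < 1e-6, kappa > 0)
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2),
                 length = as.integer(length), base_freqs = base_freqs,
                 kappa = kappa),
            class = "pair_spec")
}

# specs argument normaliser: list of pair_spec or a data.frame(n1,n2,length)
as_spec_list <- function(specs) {
  if (is.data.frame(specs)) {
    specs <- lapply(seq_len(nrow(specs)), function(i)
      pair_spec(specs$n1[i], specs$n2[i], specs$length[i]))
  }
  stopifnot(all(vapply(specs, inherits, logical(1), "pair_spec")))
  specs
}

#' Draw from the hierarchical co-divergence hyper-prior
#'
#' `Psi ~ DU{1..psi_max}` (or fixed via `psi_fixed`); event times
#' `tau_j ~ U(0, tau_upper)` iid; the pair-to-event assignment is uniform
#' over surjections (every event receives at least one pair); per-pair
#' nuisance parameters: `theta_pair ~ U(0, theta_upper)`, a split fraction
#' `b ~ U(0,1)` giving descendant sizes `theta1 = 2*b*theta_pair`,
#' `theta2 = 2*(1-b)*theta_pair`, ancestral
#' `thetaA ~ U(0, ancestral_frac_upper) * theta_pair`, and symmetric
#' `migration ~ U(0, migration_upper)`.
#'
#' @param prior a [hyper_prior()].
#' @param k_pairs number of population pairs.
#' @param psi_fixed optionally constrain Psi to this value.
#' @return list of class `hyper_draw`: `psi`, `event_times`, `assignment`
#'   (pair -> event index), `tau_pair`, and per-pair `theta_pair`, `theta1`,
#'   `theta2`, `thetaA`, `migration`, `founding_frac1`, `founding_frac2`.
#' @export
draw_hyper <- function(prior, k_pairs, psi_fixed = NULL) {
  stopifnot(inherits(prior, "hyper_prior"), k_pairs >= 1)
  psi_max <- min(prior$psi_max, k_pairs)
  psi <- if (is.null(psi_fixed)) sample.int(psi_max, 1) else {
    stopifnot(psi_fixed >= 1, psi_fixed <= k_pairs)
    as.integer(psi_fixed)
  }
  event_times <- runif(psi, 0, prior$tau_upper)
  assignment <- as.integer(cpp_sample_surjection(k_pairs, psi))
  theta_pair <- runif(k_pairs, 0, prior$theta_upper)
  b <- runif(k_pairs)
  structure(list(
    psi = psi,
    event_times = event_times,
    assignment = assignment,
    tau_pair = event_times[assignment],
    theta_pair = theta_pair,
    theta1 = 2 * b * theta_pair,
    theta2 = 2 * (1 - b) * theta_pair,
    thetaA = runif(k_pairs, 0, prior$ancestral_frac_upper) * theta_pair,
    migration = if (prior$migration_upper > 0)
      runif(k_pairs, 0, prior$migration_upper) else numeric(k_pairs),
    founding_frac1 = if (prior$founding_frac_lower < 1)
      runif(k_pairs, prior$founding_frac_lower, 1) else rep(1, k_pairs),
    founding_frac2 = if (prior$founding_frac_lower < 1)
      runif(k_pairs, prior$founding_frac_lower, 1) else rep(1, k_pairs)),
    class = "hyper_draw")
}

#' Simulate one population pair under the isolation(-with-migration) model
#'
#' Two-population coalescent genealogy for `n1 + n2` tips with divergence at
#' `tau` (units of `4*N_ave` generations), deme sizes set by the per-site
#' thetas on the `theta_ave` reference scale, mutations as a Poisson process
#' on branches at rate `theta_ave` per site per unit time, and finite-sites
#' HKY substitution at each mutation event.
#'
#' @param theta1,theta2,thetaA per-site thetas of the two descendant demes
#'   and the ancestral deme.
#' @param tau divergence time in `4*N_ave`-generation units.
#' @param spec a [pair_spec()].
#' @param theta_ave reference per-site theta defining `N_ave` (default
#'   0.0125 = half the default theta-prior upper bound).
#' @param migration symmetric scaled migration rate (per lineage per unit
#'   time); or a length-2 vector of directional rates (pop1-in, pop2-in).
#' @param founding_frac founding-bottleneck fractions of the two descendant
#'   populations (length 1 or 2; 1 = no bottleneck).
#' @param species species label for the returned pair.
#' @return a [pop_pair()] with simulated aligned sequences.
#' @export
simulate_pair <- function(theta1, theta2, thetaA, tau, spec,
                          theta_ave = 0.0125, migration = 0,
                          founding_frac = 1, species = "sim") {
  stopifnot(inherits(spec, "pair_spec"), theta1 >= 0, theta2 >= 0,
            thetaA >= 0, tau >= 0, all(founding_frac > 0),
            all(founding_frac <= 1))
  mig <- rep(migration, length.out = 2)
  bfr <- rep(founding_frac, length.out = 2)
  seqs <- cpp_sim_pair_seqs(spec$n1, spec$n2, spec$length,
                            theta1, theta2, thetaA, tau, mig[1], mig[2],
                            theta_ave, spec$kappa, spec$base_freqs,
                            bfr[1], bfr[2])
  names(seqs) <- c(sprintf("%s_p1_%02d", species, seq_len(spec$n1)),
                   sprintf("%s_p2_%02d", species, seq_len(spec$n2)))
  pop_pair(seqs[seq_len(spec$n1)], seqs[-seq_len(spec$n1)],
           species = species)
}

#' Simulate a whole co-divergence dataset and summarise it
#'
#' Simulates every pair with its assigned event's tau and returns the
#' ordered summary vector, computed with the same statistics and ordering
#' rule as [observed_vector()].
#'
#' @param draw a [draw_hyper()] result.
#' @param specs list of [pair_spec()] (or data frame with `n1`, `n2`,
#'   `length`), one per pair.
#' @param theta_ave reference per-site theta.
#' @param fourth_stat passed to [observed_vector()].
#' @return `summary_vector` data frame.
#' @export
simulate_dataset <- function(draw, specs, theta_ave = 0.0125,
                             fourth_stat = c("tajd_denom", "inv_tajima_d")) {
  fourth_stat <- match.arg(fourth_stat)
  stopifnot(inherits(draw, "hyper_draw"))
  specs <- as_spec_list(specs)
  k <- length(draw$assignment)
  if (length(specs) != k) stop("specs length must equal the number of pairs")
  pairs <- lapply(seq_len(k), function(i)
    simulate_pair(draw$theta1[i], draw$theta2[i], draw$thetaA[i],
                  draw$tau_pair[i], specs[[i]], theta_ave = theta_ave,
                  migration = draw$migration[i],
                  founding_frac = c(draw$founding_frac1[i],
                                    draw$founding_frac2[i]),
                  species = sprintf("pair%02d", i)))
  observed_vector(pairs, fourth_stat = fourth_stat)
}

#' Simulate the ABC reference table
#'
#' Draws `n_sims` times from the hyper-prior, simulates every pair, and
#' records for each draw the hyper-parameters `Psi`, `E[tau]` (mean tau over
#' pairs), `Omega` (population variance of tau over pairs divided by the
#' mean; exactly 0 when all pairs share one event), per-pair tau and event
#' rank, and the per-pair 4-statistic blocks sorted by the
#' [observed_vector()] ordering rule. Work proceeds in chunks with
#' deterministic per-chunk seeds derived from `seed`, so a run is
#' reproducible and, when streaming to `file`, resumable: chunks already
#' present in the file are skipped.
#'
#' @param prior a [hyper_prior()].
#' @param specs list of [pair_spec()] or data frame with `n1`, `n2`,
#'   `length`.
#' @param n_sims number of prior draws.
#' @param seed integer seed governing the whole table.
#' @param psi_fixed optionally constrain Psi (used by [constrained_habc()]).
#' @param fourth_stat fourth summary statistic, as in [observed_vector()].
#' @param chunk_size draws per chunk (default 10000).
#' @param file optional CSV path to stream chunks to (appended; resumable).
#' @return data frame of class `reference_table` with columns `psi`,
#'   `e_tau`, `omega`, `tau_1..K`, `rank_1..K`, then `pi_i`, `net_pi_i`,
#'   `theta_w_i`, `stat4_i` for each sorted pair slot `i`.
#' @export
reference_table <- function(prior, specs, n_sims, seed = 1,
                            psi_fixed = NULL,
                            fourth_stat = c("tajd_denom", "inv_tajima_d"),
                            chunk_size = 10000, file = NULL) {
  fourth_stat <- match.arg(fourth_stat)
  stopifnot(inherits(prior, "hyper_prior"), n_sims >= 1)
  specs <- as_spec_list(specs)
  K <- length(specs)
  n1 <- vapply(specs, `[[`, integer(1), "n1")
  n2 <- vapply(specs, `[[`, integer(1), "n2")
  L <- vapply(specs, `[[`, integer(1), "length")
  kappa <- specs[[1]]$kappa
  freqs <- specs[[1]]$base_freqs
  psi_min <- if (is.null(psi_fixed)) 1L else as.integer(psi_fixed)
  psi_max <- if (is.null(psi_fixed)) min(prior$psi_max, K) else
    as.integer(psi_fixed)
  cols <- c("psi", "e_tau", "omega",
            paste0("tau_", seq_len(K)), paste0("rank_", seq_len(K)),
            as.vector(t(outer(seq_len(K), c("pi", "net_pi", "theta_w", "stat4"),
                              function(i, s) paste0(s, "_", i)))))
  n_chunks <- ceiling(n_sims / chunk_size)
  done_rows <- 0
  if (!is.null(file) && file.exists(file)) {
    done_rows <- max(0, length(readLines(file)) - 1)
    keep <- (done_rows %/% chunk_size) * chunk_size # drop a partial chunk
    if (keep < done_rows) {
      lines <- readLines(file)
      writeLines(lines[seq_len(keep + 1)], file)
      done_rows <- keep
    }
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  out <- vector("list", n_chunks)
  for (ch in seq_len(n_chunks)) {
    nd <- min(chunk_size, n_sims - (ch - 1) * chunk_size)
    first_row <- (ch - 1) * chunk_size
    set.seed((seed + 7919 * ch) %% .Machine$integer.max)
    if (!is.null(file) && first_row + nd <= done_rows) next # resumed chunk
    m <- cpp_reference_table(nd, psi_min, psi_max, prior$tau_upper,
                             prior$theta_upper, prior$ancestral_frac_upper,
                             prior$migration_upper, n1, n2, L,
                             prior$theta_ave, kappa, freqs,
                             if (fourth_stat == "tajd_denom") 0L else 1L,
                             1000.0, prior$founding_frac_lower)
    colnames(m) <- cols
    if (!is.null(file)) {
      df <- as.data.frame(m)
      write.table(df, file, sep = ",", row.names = FALSE,
                  col.names = !file.exists(file), append = file.exists(file))
    }
    out[[ch]] <- m
  }
  if (!is.null(file)) {
    tab <- read.table(file, header = TRUE, sep = ",")
  } else {
    tab <- as.data.frame(do.call(rbind, out))
  }
  attr(tab, "k_pairs") <- K
  attr(tab, "fourth_stat") <- fourth_stat
  attr(tab, "prior") <- prior
  class(tab) <- c("reference_table", "data.frame")
  tab
}

# statistic-block column names of a reference table
ref_stat_cols <- function(K) {
  as.vector(t(outer(seq_len(K), c("pi", "net_pi", "theta_w", "stat4"),
                    function(i, s) paste0(s, "_", i))))
}
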