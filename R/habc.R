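# Hierarchical ABC orchestration: joint (Psi, Omega, E[tau]) estimation,
# Bayes-factor model comparison, constrained-Psi timing/assignment, and the
# taxon-subset support procedure.

#' Hierarchical ABC fit of the co-divergence hyper-parameters
#'
#' Simulates a reference table under the hyper-prior, accepts the draws
#' nearest to the observed summary vector, and reports the posterior of
#' `Psi` (polychotomous regression with frequency fallback), the
#' regression-adjusted posteriors of `Omega` and `E[tau]`, and the standard
#' Bayes-factor comparisons (`Psi = 1` vs `Psi > 1`; `Psi <= mode` vs above;
#' `Psi < psi_max` vs the continuous-divergence extreme `Psi = psi_max`;
#' `Omega < eps` vs above).
#'
#' @param observed a `summary_vector` data frame ([observed_vector()] or
#'   [sort_observed()]); its fourth statistic must match `fourth_stat`.
#' @param specs per-pair simulation designs (list of [pair_spec()] or data
#'   frame with `n1`, `n2`, `length`), in any order (the summary vector is
#'   order-free by construction).
#' @param prior a [hyper_prior()].
#' @param n_sims reference-table size.
#' @param acc_frac acceptance fraction; `n_accept = round(acc_frac * n_sims)`
#'   unless `n_accept` is given directly. The default 3.6e-4 reproduces 1800
#'   accepted draws at 5e6 simulations.
#' @param n_accept number of accepted draws (overrides `acc_frac`).
#' @param seed integer seed.
#' @param omega_eps point-null tolerance for the `Omega = 0` Bayes factor
#'   (default 0.01).
#' @param fourth_stat fourth summary statistic, as in [observed_vector()].
#' @param ref optionally, a precomputed [reference_table()] to reuse.
#' @param chunk_size passed to [reference_table()].
#' @return object of class `habc_posterior`: `psi` (estimate_psi output),
#'   `omega`, `e_tau` (adjust_continuous outputs), `bayes_factors` (list),
#'   `n_accept`, `n_sims`, `seed`, `acc`, `ref_prior_psi`,
#'   `ref_prior_omega_lt_eps`.
#' @export
habc_fit <- function(observed, specs, prior = hyper_prior(),
                     n_sims = 200000, acc_frac = 3.6e-4, n_accept = NULL,
                     seed = 1, omega_eps = 0.01,
                     fourth_stat = c("tajd_denom", "inv_tajima_d"),
                     ref = NULL, chunk_size = 10000) {
  fourth_stat <- match.arg(fourth_stat)
  specs <- as_spec_list(specs)
  K <- length(specs)
  if (nrow(observed) != K) stop("observed vector and specs disagree on K")
  if (is.null(n_accept)) n_accept <- max(2, round(acc_frac * n_sims))
  if (is.null(ref)) {
    ref <- reference_table(prior, specs, n_sims, seed = seed,
                           fourth_stat = fourth_stat,
                           chunk_size = chunk_size)
  }
  n_sims <- nrow(ref)
  obs_vec <- flatten_summary(sort_summary_vector(observed))
  stat_cols <- ref_stat_cols(K)
  acc <- abc_reject(as.matrix(ref[, stat_cols]), obs_vec, n_accept)
  psi_max <- min(prior$psi_max, K)
  psi_acc <- as.integer(ref$psi[acc$idx])
  psi_est <- estimate_psi(psi_acc, acc, categories = seq_len(psi_max))
  omega_est <- adjust_continuous(ref$omega[acc$idx], acc)
  etau_est <- adjust_continuous(ref$e_tau[acc$idx], acc)

  prior_psi <- rep(1 / psi_max, psi_max) # discrete-uniform hyper-prior
  names(prior_psi) <- seq_len(psi_max)
  prior_omega_lt <- mean(ref$omega < omega_eps) # prior mass from the table
  post <- psi_est$posterior
  mode_psi <- psi_est$mode
  post_omega_lt <- sum(omega_est$weights[omega_est$adjusted < omega_eps]) /
    sum(omega_est$weights)
  bfs <- list(
    psi_1_vs_gt1 = bayes_factor(post["1"], prior_psi["1"],
                                "Psi = 1 vs Psi > 1"),
    psi_le_mode_vs_gt = if (mode_psi < psi_max)
      bayes_factor(sum(post[seq_len(mode_psi)]),
                   sum(prior_psi[seq_len(mode_psi)]),
                   sprintf("Psi <= %d vs Psi > %d", mode_psi, mode_psi))
      else NULL,
    psi_lt_max_vs_max = bayes_factor(
      sum(post[seq_len(psi_max - 1)]), sum(prior_psi[seq_len(psi_max - 1)]),
      sprintf("Psi < %d vs Psi = %d", psi_max, psi_max)),
    omega_zero_vs_pos = if (prior_omega_lt > 0 && prior_omega_lt < 1)
      bayes_factor(post_omega_lt, prior_omega_lt,
                   sprintf("Omega < %g vs Omega >= %g", omega_eps, omega_eps))
      else NULL)
  structure(list(psi = psi_est, omega = omega_est, e_tau = etau_est,
                 bayes_factors = bfs, n_accept = n_accept, n_sims = n_sims,
                 seed = seed, acc = acc, omega_eps = omega_eps,
                 ref_prior_psi = prior_psi,
                 ref_prior_omega_lt_eps = prior_omega_lt),
            class = "habc_posterior")
}

#' @export
print.habc_posterior <- function(x, ...) {
  cat("Hierarchical ABC posterior (", x$n_accept, "/", x$n_sims,
      " draws accepted)\n", sep = "")
  cat("  Psi posterior (", x$psi$method, "):\n", sep = "")
  print(round(x$psi$posterior, 4))
  cat(sprintf("  Psi mode = %d\n", x$psi$mode))
  cat(sprintf("  Omega  mode %.4f  (2.5%%-97.5%%: %.4f-%.4f)\n",
              x$omega$mode, x$omega$q025, x$omega$q975))
  cat(sprintf("  E[tau] mode %.4f  (2.5%%-97.5%%: %.4f-%.4f)\n",
              x$e_tau$mode, x$e_tau$q025, x$e_tau$q975))
  for (bf in x$bayes_factors) if (!is.null(bf)) print(bf)
  invisible(x)
}

#' Constrained-Psi timing and pair assignment
#'
#' Reruns the ABC with `Psi` fixed, pools per-event divergence times over
#' accepted draws (events ordered ascending by time within each draw), and
#' assigns each pair to the event rank it joins most frequently among
#' accepted draws. Pairs whose modal-event frequency falls below
#' `confidence` are flagged ambiguous rather than assigned.
#'
#' @inheritParams habc_fit
#' @param psi_fixed the constrained number of events.
#' @param confidence assignment-frequency threshold (default 0.67).
#' @return object of class `habc_constrained`: `events` (data frame with
#'   per-event tau mode and percentiles), `assignment` (data frame with
#'   per-pair modal event, frequency, `confident`), `n_confident`,
#'   `ambiguous` (species labels), plus acceptance metadata.
#' @export
constrained_habc <- function(observed, specs, psi_fixed,
                             prior = hyper_prior(), n_sims = 200000,
                             acc_frac = 3.6e-4, n_accept = NULL, seed = 1,
                             confidence = 0.67,
                             fourth_stat = c("tajd_denom", "inv_tajima_d"),
                             ref = NULL, chunk_size = 10000) {
  fourth_stat <- match.arg(fourth_stat)
  specs <- as_spec_list(specs)
  K <- length(specs)
  stopifnot(psi_fixed >= 1, psi_fixed <= K)
  if (is.null(n_accept)) n_accept <- max(2, round(acc_frac * n_sims))
  if (is.null(ref)) {
    ref <- reference_table(prior, specs, n_sims, seed = seed,
                           psi_fixed = psi_fixed, fourth_stat = fourth_stat,
                           chunk_size = chunk_size)
  } else if (any(ref$psi != psi_fixed)) {
    stop("reference table was not simulated with Psi = ", psi_fixed)
  }
  sv <- sort_summary_vector(observed)
  obs_vec <- flatten_summary(sv)
  acc <- abc_reject(as.matrix(ref[, ref_stat_cols(K)]), obs_vec, n_accept)
  tau_cols <- paste0("tau_", seq_len(K))
  rank_cols <- paste0("rank_", seq_len(K))
  taus <- as.matrix(ref[acc$idx, tau_cols])
  ranks <- as.matrix(ref[acc$idx, rank_cols])
  w <- acc$weights
  # per-event pooled tau (weighted by draw weight)
  events <- do.call(rbind, lapply(seq_len(psi_fixed), function(j) {
    sel <- ranks == j
    tj <- taus[sel]
    wj <- matrix(w, nrow(ranks), ncol(ranks))[sel]
    q <- weighted_quantile(tj, wj, c(0.025, 0.975))
    data.frame(event = j, tau_mode = kde_mode(tj, wj),
               tau_q025 = q[1], tau_q975 = q[2], n_draws = sum(sel))
  }))
  # per-pair modal event rank (pairs are in sorted summary-vector order)
  assignment <- do.call(rbind, lapply(seq_len(K), function(p) {
    f <- vapply(seq_len(psi_fixed),
                function(j) sum(w[ranks[, p] == j]), numeric(1))
    f <- f / sum(f)
    data.frame(species = sv$species[p], slot = p,
               event = which.max(f), freq = max(f),
               confident = max(f) >= confidence)
  }))
  counts <- vapply(seq_len(psi_fixed), function(j)
    sum(assignment$confident & assignment$event == j), integer(1))
  structure(list(events = events, assignment = assignment,
                 event_counts = counts,
                 n_confident = sum(assignment$confident),
                 ambiguous = assignment$species[!assignment$confident],
                 psi_fixed = psi_fixed, confidence = confidence,
                 n_accept = n_accept, n_sims = nrow(ref), seed = seed),
            class = "habc_constrained")
}

#' @export
print.habc_constrained <- function(x, ...) {
  cat("Constrained HABC (Psi = ", x$psi_fixed, ", ", x$n_accept, "/",
      x$n_sims, " accepted)\n", sep = "")
  print(x$events, row.names = FALSE)
  cat("confident assignments per event (ascending tau): ",
      paste(x$event_counts, collapse = "/"), "\n", sep = "")
  if (length(x$ambiguous) > 0) {
    cat("ambiguous: ", paste(x$ambiguous, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Support for a single co-divergence event in a taxon subset
#'
#' Full HABC rerun on a subset of pairs with `psi_max` equal to the subset
#' size. The subset supports a single shared divergence ("single event")
#' when the `Psi` posterior mode is 1 and the `Omega` estimate is at most
#' `omega_tol`; the `Psi = 1` vs `Psi > 1` Bayes factor is attached with its
#' Jeffreys label.
#'
#' @inheritParams habc_fit
#' @param omega_tol Omega threshold for the support label (default 0.05).
#' @return list of class `habc_subset`: `fit` (the [habc_fit()] result),
#'   `omega_mode`, `psi_mode`, `bf_single`, `single_event` (logical),
#'   `label`.
#' @export
subset_support <- function(observed, specs, prior = hyper_prior(),
                           n_sims = 50000, acc_frac = 3.6e-4,
                           n_accept = NULL, seed = 1, omega_tol = 0.05,
                           fourth_stat = c("tajd_denom", "inv_tajima_d"),
                           chunk_size = 10000) {
  fourth_stat <- match.arg(fourth_stat)
  specs <- as_spec_list(specs)
  if (length(specs) < 2) stop("subset must contain at least 2 pairs")
  prior_sub <- prior
  prior_sub$psi_max <- length(specs)
  fit <- habc_fit(observed, specs, prior = prior_sub, n_sims = n_sims,
                  acc_frac = acc_frac, n_accept = n_accept, seed = seed,
                  fourth_stat = fourth_stat, chunk_size = chunk_size)
  single <- fit$psi$mode == 1 && fit$omega$mode <= omega_tol
  structure(list(fit = fit, omega_mode = fit$omega$mode,
                 psi_mode = fit$psi$mode,
                 bf_single = fit$bayes_factors$psi_1_vs_gt1,
                 single_event = single,
                 label = if (single) "single event" else "multiple events"),
            class = "habc_subset")
}

#' @export
print.habc_subset <- function(x, ...) {
  cat("Subset support: ", x$label, " (Psi mode = ", x$psi_mode,
      ", Omega mode = ", signif(x$omega_mode, 3), ")\n", sep = "")
  print(x$bf_single)
  invisible(x)
}
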