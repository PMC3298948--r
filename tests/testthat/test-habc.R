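# Hierarchical ABC orchestration on small synthetic studies.

small_specs <- function(k = 6, n = 8, L = 400) {
  data.frame(n1 = rep(n, k), n2 = rep(n, k), length = rep(L, k))
}

sim_study_observed <- function(pr, specs, psi, taus, seed) {
  set.seed(seed)
  truth <- draw_hyper(pr, nrow(specs), psi_fixed = psi)
  truth$event_times <- taus
  truth$tau_pair <- taus[truth$assignment]
  list(obs = simulate_dataset(truth, specs), truth = truth)
}

test_that("habc_fit returns coherent posteriors and bookkeeping", {
  specs <- small_specs()
  pr <- hyper_prior(psi_max = 6)
  st <- sim_study_observed(pr, specs, 2, c(0.1, 1.8), seed = 1)
  fit <- habc_fit(st$obs, specs, prior = pr, n_sims = 5000, n_accept = 100,
                  seed = 2)
  expect_s3_class(fit, "habc_posterior")
  expect_equal(sum(fit$psi$posterior), 1, tolerance = 1e-9)
  expect_equal(sum(fit$psi$raw), 1, tolerance = 1e-9)
  expect_lte(fit$omega$q025, fit$omega$q975)
  expect_gte(fit$omega$mode, 0)
  expect_true(!is.null(fit$bayes_factors$psi_1_vs_gt1))
  # deterministic replay
  fit2 <- habc_fit(st$obs, specs, prior = pr, n_sims = 5000, n_accept = 100,
                   seed = 2)
  expect_identical(fit$psi$posterior, fit2$psi$posterior)
  expect_identical(fit$omega$mode, fit2$omega$mode)
})

test_that("a single shared event yields low Omega and Psi mode 1", {
  specs <- small_specs(5)
  pr <- hyper_prior(psi_max = 5)
  st <- sim_study_observed(pr, specs, 1, 0.8, seed = 3)
  fit <- habc_fit(st$obs, specs, prior = pr, n_sims = 6000, n_accept = 120,
                  seed = 4)
  expect_equal(fit$psi$mode, 1L)
  expect_lt(fit$omega$mode, 0.25)
})

test_that("constrained runs recover a planted 3-event structure", {
  specs <- small_specs(10, n = 10, L = 600)
  pr <- hyper_prior(psi_max = 10)
  set.seed(5)
  truth <- draw_hyper(pr, 10, psi_fixed = 3)
  truth$event_times <- c(0.05, 0.8, 2.0)
  truth$assignment <- rep(1:3, c(4, 3, 3))
  truth$tau_pair <- truth$event_times[truth$assignment]
  truth$theta_pair <- rep(0.008, 10)
  truth$theta1 <- rep(0.008, 10)
  truth$theta2 <- rep(0.008, 10)
  truth$thetaA <- rep(0.002, 10)
  obs <- simulate_dataset(truth, specs)
  cr <- constrained_habc(obs, specs, psi_fixed = 3, n_sims = 20000,
                         n_accept = 200, seed = 6)
  expect_equal(nrow(cr$events), 3)
  expect_true(all(diff(cr$events$tau_mode) > 0)) # events ordered by time
  expect_equal(sum(cr$assignment$event %in% 1:3), 10)
  # modal assignment recovers most pairs: compare recovered event sizes with
  # the planted 4/3/3 split
  sizes <- tabulate(cr$assignment$event, 3)
  expect_gte(sum(pmin(sizes, c(4, 3, 3))), 8)
  expect_error(constrained_habc(obs, specs, psi_fixed = 2, ref = cr_ref <-
    reference_table(pr, specs, 500, seed = 1, psi_fixed = 3)),
    "not simulated")
})

test_that("subset support separates shared from split histories", {
  specs3 <- small_specs(3, n = 8, L = 500)
  pr <- hyper_prior(psi_max = 3)
  shared <- sim_study_observed(pr, specs3, 1, 0.6, seed = 7)
  s1 <- suppressWarnings( # a pure Psi=1 acceptance set warns (point mass)
    subset_support(shared$obs, specs3, prior = pr, n_sims = 6000,
                   n_accept = 120, seed = 8))
  expect_s3_class(s1, "habc_subset")
  expect_equal(s1$psi_mode, 1L)
  specs2 <- small_specs(2, n = 8, L = 500)
  split <- sim_study_observed(hyper_prior(psi_max = 2), specs2, 2,
                              c(0.1, 2.5), seed = 9)
  s2 <- suppressWarnings(subset_support(split$obs, specs2, n_sims = 6000,
                                        n_accept = 120, seed = 10))
  expect_equal(s2$psi_mode, 2L)
  expect_false(s2$single_event)
  expect_error(subset_support(split$obs, specs2[1, , drop = FALSE]),
               "at least 2")
})
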