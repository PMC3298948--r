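# Assemblage isolation-with-migration model and its ABC fit.

test_that("inheritance scalars scale diversity as expected", {
  set.seed(1)
  specs <- data.frame(n1 = c(10, 10), n2 = c(10, 10), length = c(800, 800))
  params <- assemblage_params(0.01, 0.01, 0.01, t = 0, h = c(1, 0.5))
  pis <- replicate(150, {
    prs <- simulate_assemblage(params, specs)
    c(pair_stats(prs[[1]])$pi_total, pair_stats(prs[[2]])$pi_total)
  })
  ratio <- mean(pis[2, ]) / mean(pis[1, ])
  expect_gt(ratio, 0.38)
  expect_lt(ratio, 0.62)
})

test_that("t = 0 with migration gives panmixia; deep t gives structure", {
  set.seed(2)
  specs <- data.frame(n1 = 8, n2 = 8, length = 800)
  sh <- simulate_assemblage(assemblage_params(0.01, 0.01, 0.01, t = 0, h = 1),
                            specs)
  expect_lt(abs(hudson_fst(sh[[1]], n_perm = 1)$fst), 0.35)
  deep <- simulate_assemblage(
    assemblage_params(0.006, 0.006, 0.002, t = 25, h = 1), specs)
  expect_gt(pair_stats(deep[[1]])$da, 0.005)
})

test_that("scale invariance: doubling thetas with h fixed doubles diversity", {
  set.seed(3)
  specs <- data.frame(n1 = 10, n2 = 10, length = 1000)
  m1 <- mean(replicate(120, pair_stats(simulate_assemblage(
    assemblage_params(0.004, 0.004, 0.004, 0, h = 1), specs)[[1]])$pi_total))
  m2 <- mean(replicate(120, pair_stats(simulate_assemblage(
    assemblage_params(0.008, 0.008, 0.008, 0, h = 1), specs)[[1]])$pi_total))
  expect_gt(m2 / m1, 1.6)
  expect_lt(m2 / m1, 2.4)
})

test_that("fit_assemblage recovers a planted divergence time", {
  set.seed(4)
  specs <- data.frame(n1 = rep(10, 4), n2 = rep(10, 4), length = rep(600, 4))
  truth <- assemblage_params(0.008, 0.008, 0.002, t = 12,
                             h = c(1, 0.8, 0.6, 0.9))
  prs <- simulate_assemblage(truth, specs)
  fit <- fit_assemblage(prs, prior = im_prior(t_upper = 40), n_sims = 4000,
                        n_accept = 100, seed = 5)
  expect_s3_class(fit, "assemblage_posterior")
  tp <- fit$posteriors$t
  # smoke-level recovery: the peak lands in the right region of the prior
  # (the 20-fit coverage property is asserted in the acceptance suite)
  expect_gt(tp$mode, 3)
  expect_lt(tp$mode, 36)
  expect_lte(tp$q025, tp$mode + 1e-9)
  expect_gte(tp$q975, tp$mode - 1e-9)
  # determinism
  fit2 <- fit_assemblage(prs, prior = im_prior(t_upper = 40), n_sims = 4000,
                         n_accept = 100, seed = 5)
  expect_identical(tp$mode, fit2$posteriors$t$mode)
})

test_that("a single species is a valid degenerate assemblage", {
  set.seed(6)
  specs <- data.frame(n1 = 8, n2 = 8, length = 500)
  prs <- simulate_assemblage(assemblage_params(0.006, 0.006, 0.002, 8, h = 1),
                             specs)
  fit <- fit_assemblage(prs, prior = im_prior(t_upper = 30), n_sims = 1500,
                        n_accept = 60, seed = 7)
  expect_equal(fit$k_species, 1)
  expect_null(fit$posteriors$h_2)
  expect_error(fit_assemblage(prs, n_sims = 10, n_accept = 60), "fewer")
})

test_that("compare_events aligns the two stages and flags missing intervals", {
  set.seed(8)
  specs <- data.frame(n1 = rep(8, 2), n2 = rep(8, 2), length = rep(500, 2))
  prs <- simulate_assemblage(assemblage_params(0.006, 0.006, 0.002, 10,
                                               h = c(1, 0.9)), specs)
  fit <- fit_assemblage(prs, prior = im_prior(t_upper = 30), n_sims = 1500,
                        n_accept = 60, seed = 9)
  ev <- data.frame(tau_mode = c(0.5, NA), tau_q025 = c(0.1, NA),
                   tau_q975 = c(1.2, NA))
  cmp <- compare_events(list(fit, fit), ev,
                        list(c(500, 500), c(500, 500)))
  expect_equal(nrow(cmp), 2)
  expect_false(cmp$flagged[1])
  expect_true(cmp$flagged[2])
  expect_equal(cmp$habc_mode_yr[1], tau_to_years(0.5))
  expect_gt(cmp$im_width_yr[1], 0)
})
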