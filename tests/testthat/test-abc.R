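# ABC rejection, regression adjustment, Psi estimation and Bayes factors.

make_ref <- function(n = 500, p = 6, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p)
}

test_that("a reference row equal to the observed point is accepted first", {
  ref <- make_ref()
  obs <- ref[137, ]
  acc <- abc_reject(ref, obs, 10)
  expect_equal(acc$idx[1], 137)
  expect_equal(acc$dist[1], 0)
  expect_equal(max(acc$weights), acc$weights[1])
})

test_that("n_accept = n - 1 keeps everything but the farthest row", {
  ref <- make_ref(100, 3)
  obs <- rep(0, 3)
  acc <- abc_reject(ref, obs, 99)
  sds <- apply(ref, 2, sd)
  d <- sqrt(rowSums(sweep(sweep(ref, 2, obs), 2, sds, "/")^2))
  expect_equal(sort(acc$idx), sort(order(d)[1:99]))
  expect_error(abc_reject(ref, obs, 100), "n_accept")
  expect_error(abc_reject(ref, c(NA, 0, 0), 5), "NaN|NA")
})

test_that("constant reference columns are dropped from the distance", {
  ref <- cbind(make_ref(200, 2), 7)
  acc <- abc_reject(ref, c(0, 0, 7), 20)
  expect_equal(acc$kept, 1:2)
})

test_that("planted truth enriches accepted Psi beyond the uniform prior", {
  set.seed(31)
  specs <- data.frame(n1 = rep(8, 6), n2 = rep(8, 6), length = rep(400, 6))
  pr <- hyper_prior(psi_max = 6, tau_upper = 3)
  truth <- draw_hyper(pr, 6, psi_fixed = 2)
  truth$event_times <- c(0.01, 2.0)
  truth$assignment <- rep(1:2, each = 3)
  truth$tau_pair <- truth$event_times[truth$assignment]
  truth$theta1 <- truth$theta2 <- rep(0.006, 6)
  truth$thetaA <- rep(0.0015, 6)
  truth$founding_frac1 <- truth$founding_frac2 <- rep(1, 6)
  obs <- simulate_dataset(truth, specs)
  ref <- reference_table(pr, specs, n_sims = 6000, seed = 5)
  acc <- abc_reject(as.matrix(ref[, codiverge:::ref_stat_cols(6)]),
                    flatten_summary(obs), 100)
  frac2 <- mean(ref$psi[acc$idx] == 2)
  expect_gt(frac2, 1 / 6) # enriched vs the uniform prior
})

test_that("regression adjustment is calibrated at the accepted mean", {
  set.seed(7)
  n <- 300
  X <- matrix(rnorm(n * 3), n, 3)
  theta <- exp(1 + X %*% c(0.5, -0.3, 0.2) + rnorm(n, 0, 0.05))
  acc <- list(idx = seq_len(n), weights = rep(1, n),
              x_std = sweep(X, 2, colMeans(X)))
  adj <- adjust_continuous(as.vector(theta), acc)
  # at the covariate mean the adjusted center matches the raw center
  expect_lt(abs(log(adj$median + 1e-6) - mean(log(theta + 1e-6))), 0.1)
  expect_true(adj$adjusted_flag)
  expect_true(all(adj$adjusted >= 0))
  expect_lte(adj$q025, adj$median)
  expect_lte(adj$median, adj$q975)
  # transform round trip on constants
  x <- rep(2.5, 60)
  acc0 <- list(idx = 1:60, weights = rep(1, 60),
               x_std = matrix(rnorm(120), 60, 2))
  adj0 <- adjust_continuous(x, acc0)
  expect_equal(unname(adj0$adjusted), x, tolerance = 1e-10)
})

test_that("Psi estimation handles point masses and symmetric cases", {
  acc <- list(idx = 1:50, weights = rep(1, 50),
              x_std = matrix(rnorm(100), 50, 2))
  expect_warning(e1 <- estimate_psi(rep(3L, 50), acc, categories = 1:5),
                 "point mass")
  expect_equal(unname(e1$posterior[3]), 1)
  expect_equal(e1$mode, 3L)
  # raw frequencies are exact bookkeeping: counts / n_accept under equal weights
  psi <- rep(c(1L, 2L), c(20, 30))
  e2 <- estimate_psi(psi, acc, categories = 1:2)
  expect_equal(unname(e2$raw), c(20, 30) / 50)
})

test_that("Bayes factors follow the definition and reciprocal identity", {
  expect_equal(bayes_factor(0.5, 0.5)$bf, 1)
  expect_equal(bayes_factor(0.2, 0.1)$bf, (0.2 / 0.8) / (0.1 / 0.9))
  b12 <- bayes_factor(0.3, 0.6)
  b21 <- bayes_factor(0.7, 0.4)
  expect_equal(b12$bf * b21$bf, 1, tolerance = 1e-12)
  expect_equal(bayes_factor(1, 0.5)$bf, Inf)
  expect_equal(jeffreys_label(2.059), "barely worth mentioning")
  expect_equal(jeffreys_label(8.189), "substantial")
  expect_equal(jeffreys_label(135.585), "decisive")
  expect_equal(jeffreys_label(0.273), "negative (supports the alternative)")
})
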