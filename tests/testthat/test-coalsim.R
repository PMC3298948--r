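# Hyper-prior draws and the coalescent simulator.

test_that("degenerate priors behave exactly", {
  set.seed(1)
  pr <- hyper_prior(psi_max = 1)
  d <- draw_hyper(pr, 5)
  expect_equal(d$psi, 1L)
  expect_equal(length(unique(d$tau_pair)), 1)
  pr0 <- hyper_prior(migration_upper = 0)
  d0 <- draw_hyper(pr0, 4)
  expect_true(all(d0$migration == 0))
  expect_error(hyper_prior(recomb_upper = 0.1), "recombination")
})

test_that("hyper-prior marginals reproduce their stated distributions", {
  set.seed(2)
  pr <- hyper_prior()
  n <- 4000
  psis <- integer(n)
  taus <- thetas <- numeric(n)
  for (i in 1:n) {
    d <- draw_hyper(pr, 10)
    psis[i] <- d$psi
    taus[i] <- d$event_times[1]
    thetas[i] <- d$theta_pair[1]
  }
  # Psi uniform on 1..10 within binomial error
  expect_gt(chisq.test(tabulate(psis, 10))$p.value, 0.001)
  expect_gt(ks.test(taus, "punif", 0, 3)$p.value, 0.01)
  expect_gt(ks.test(thetas, "punif", 0, 0.025)$p.value, 0.01)
  # theta1 + theta2 = 2 * theta_pair by construction
  d <- draw_hyper(pr, 10)
  expect_equal(d$theta1 + d$theta2, 2 * d$theta_pair, tolerance = 1e-12)
  expect_true(all(d$thetaA <= 0.25 * d$theta_pair + 1e-15))
})

test_that("surjective assignments cover every event and are uniform", {
  set.seed(3)
  for (i in 1:200) {
    psi <- sample(1:8, 1)
    a <- codiverge:::cpp_sample_surjection(8, psi)
    expect_equal(sort(unique(a)), seq_len(psi))
  }
  # K = 3, psi = 2: 6 surjections up to event labels; check uniformity of
  # the partition structure {which item is alone}x{label order} via chisq
  cnt <- table(replicate(3000, paste(codiverge:::cpp_sample_surjection(3, 2),
                                     collapse = "")))
  expect_equal(length(cnt), 6)
  expect_gt(chisq.test(as.vector(cnt))$p.value, 0.001)
})

test_that("zero mutation parameters with tau = 0 give identical sequences", {
  set.seed(4)
  pr <- simulate_pair(0, 0, 0, 0, pair_spec(4, 4, 100))
  expect_equal(length(unique(row_strings <- apply(rbind(pr$seqs1, pr$seqs2),
                                                  1, paste, collapse = ""))), 1)
})

test_that("panmixia limit gives near-zero Fst on average", {
  set.seed(5)
  fsts <- replicate(30, {
    pr <- simulate_pair(0.01, 0.01, 0.01, 0, pair_spec(8, 8, 500))
    hudson_fst(pr, n_perm = 1)$fst
  })
  expect_lt(abs(mean(fsts)), 0.08)
})

test_that("mean simulated net pi is nondecreasing in tau", {
  set.seed(6)
  taus <- c(0, 0.5, 1.5, 3)
  means <- vapply(taus, function(tau) {
    mean(replicate(40, codiverge:::cpp_sim_pair_stats(
      10, 10, 800, 0.006, 0.006, 0.0015, tau, 0, 0, 0.0125, 8,
      rep(0.25, 4))["net_pi"]))
  }, numeric(1))
  expect_true(all(diff(means) > -0.001))
  expect_gt(means[4], means[1])
})

test_that("simulated datasets are deterministic given the seed", {
  pr <- hyper_prior()
  specs <- lapply(1:4, function(i) pair_spec(6, 6, 300))
  set.seed(77); d1 <- draw_hyper(pr, 4); v1 <- simulate_dataset(d1, specs)
  set.seed(77); d2 <- draw_hyper(pr, 4); v2 <- simulate_dataset(d2, specs)
  expect_identical(v1, v2)
})

test_that("reference tables record omega and e_tau correctly", {
  specs <- data.frame(n1 = rep(4, 3), n2 = rep(4, 3), length = rep(120, 3))
  pr <- hyper_prior(psi_max = 3)
  tab <- reference_table(pr, specs, n_sims = 300, seed = 9, chunk_size = 100)
  expect_equal(nrow(tab), 300)
  # Omega = 0 exactly whenever Psi = 1 (invariant over every draw)
  expect_true(all(tab$omega[tab$psi == 1] == 0))
  # recomputation from the per-pair taus (population variance over pairs)
  taus <- as.matrix(tab[, paste0("tau_", 1:3)])
  etau <- rowMeans(taus)
  omg <- apply(taus, 1, function(x) {
    m <- mean(x); if (m <= 0) 0 else mean((x - m)^2) / m
  })
  expect_equal(tab$e_tau, etau, tolerance = 1e-12)
  expect_equal(tab$omega, omg, tolerance = 1e-12)
  # hand arithmetic: tau = {1, 3} over two pairs -> E = 2, Omega = 0.5
  expect_equal(mean(c(1, 3)), 2)
  expect_equal(mean((c(1, 3) - 2)^2) / 2, 0.5)
  # determinism: same seed, same table
  tab2 <- reference_table(pr, specs, n_sims = 300, seed = 9, chunk_size = 100)
  expect_identical(as.data.frame(tab), as.data.frame(tab2))
})

test_that("reference tables stream to CSV and resume by complete chunks", {
  specs <- data.frame(n1 = rep(4, 2), n2 = rep(4, 2), length = rep(100, 2))
  pr <- hyper_prior(psi_max = 2)
  f <- tempfile(fileext = ".csv")
  tab <- reference_table(pr, specs, n_sims = 200, seed = 5, chunk_size = 50,
                         file = f)
  expect_true(file.exists(f))
  expect_equal(nrow(tab), 200)
  # truncate to a partial chunk and resume: identical result
  lines <- readLines(f)
  writeLines(lines[1:120], f)
  tab2 <- reference_table(pr, specs, n_sims = 200, seed = 5, chunk_size = 50,
                          file = f)
  expect_equal(as.data.frame(tab), as.data.frame(tab2), tolerance = 1e-12)
})
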