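# Fu's Fs, R2, their Monte-Carlo p-values, the MK test and Hudson's Fst.

test_that("Fu's Fs matches the direct Stirling-number oracle on toys", {
  set.seed(11)
  for (rep in 1:25) {
    m <- random_alignment(5, 60, n_var = sample(2:6, 1))
    fs <- fus_fs(m)
    ofs <- oracle_fs(m)
    if (is.na(ofs)) expect_false(fs$applicable) else {
      expect_equal(fs$fs, ofs, tolerance = 1e-9)
    }
  }
})

test_that("Fs boundary and not-applicable cases are flagged", {
  expect_false(fus_fs(rep("ACGT", 5))$applicable)          # one haplotype
  expect_false(fus_fs(c("ACGT", "ACGA"))$applicable)       # n < 3
  expect_false(fus_fs(rep("AAAA", 4))$applicable)          # pi = 0
})

test_that("R2 handles the n=2 single-difference toy exactly", {
  m <- c("AAAA", "AAAT")
  r <- r2_statistic(m)
  # U = (1,1), khat = 1 -> sqrt(mean((1-0.5)^2))/1 = 0.5
  expect_equal(r$r2, 0.5)
  expect_true(is.na(r2_statistic(rep("AAAA", 3))$r2))
})

test_that("neutrality p-values are deterministic and near 0.5 at the null median", {
  set.seed(21)
  pr <- simulate_pair(0.01, 0.01, 0.01, 0, pair_spec(8, 8, 600))
  m <- rbind(pr$seqs1, pr$seqs2)
  a <- neutrality_pvalues(m, n_reps = 2000, seed = 7)
  b <- neutrality_pvalues(m, n_reps = 2000, seed = 7)
  expect_identical(a$p_fs, b$p_fs)
  expect_identical(a$p_r2, b$p_r2)
  # neutral data: p should be comfortably away from both tails on average
  set.seed(22)
  ps <- replicate(12, {
    pr <- simulate_pair(0.01, 0.01, 0.01, 0, pair_spec(10, 10, 600))
    neutrality_pvalues(rbind(pr$seqs1, pr$seqs2), n_reps = 400, seed = 1)$p_fs
  })
  expect_gt(mean(ps, na.rm = TRUE), 0.15)
  expect_lt(mean(ps, na.rm = TRUE), 0.85)
})

test_that("star-like (expansion) data give small Fs p-values", {
  # many singletons on a shallow genealogy: approximate expansion signal by
  # simulating a very recent bottleneck-like pair (tiny theta, no structure)
  set.seed(33)
  hits <- 0
  reps <- 10
  for (i in 1:reps) {
    n <- 30
    L <- 800
    anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    m <- matrix(rep(anc, n), n, L, byrow = TRUE)
    # each sequence gets private mutations: star genealogy
    for (j in 1:n) {
      s <- sample(L, rpois(1, 3) + 1)
      for (x in s) m[j, x] <- sample(setdiff(c("A", "C", "G", "T"), m[j, x]), 1)
    }
    p <- neutrality_pvalues(m, n_reps = 500, seed = i)
    if (!is.na(p$p_fs) && p$p_fs < 0.05) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.8)
})

test_that("MK table classification matches hand-classified codons", {
  fx <- worked_fixtures()$mk_toy
  mk <- mk_test(fx$ingroup, fx$outgroup)
  expect_equal(mk$syn_poly, fx$expected$syn_poly)
  expect_equal(mk$nonsyn_poly, fx$expected$nonsyn_poly)
  expect_equal(mk$syn_fixed, fx$expected$syn_fixed)
  expect_equal(mk$nonsyn_fixed, fx$expected$nonsyn_fixed)
  expect_equal(mk$p_value, fisher.test(matrix(c(1, 0, 0, 1), 2))$p.value)
})

test_that("MK degenerate tables give p = 1", {
  ing <- c("ATGAAA", "ATGAAA", "ATGAAA")
  mk0 <- mk_test(ing, "ATGAAA")
  expect_equal(mk0$syn_poly + mk0$nonsyn_poly + mk0$syn_fixed +
                 mk0$nonsyn_fixed, 0)
  expect_equal(mk0$p_value, 1)
  # balanced table: no association
  expect_equal(fisher.test(matrix(c(10, 10, 10, 10), 2))$p.value, 1)
})

test_that("Fst is 0 for identical compositions and 1 for fixed differences", {
  same <- pop_pair(c("ACGT", "ACGA"), c("ACGT", "ACGA"))
  f0 <- hudson_fst(same, n_perm = 99)
  expect_lt(abs(f0$fst), 1e-12)
  expect_gt(f0$p, 0.5)
  fixed <- pop_pair(c("AAAA", "AAAA"), c("AAAT", "AAAT"))
  f1 <- hudson_fst(fixed, n_perm = 99)
  expect_equal(f1$fst, 1)
})

test_that("deep splits give significant Fst permutation tests", {
  set.seed(44)
  hits <- 0
  for (i in 1:10) {
    pr <- simulate_pair(0.008, 0.008, 0.002, 2.0, pair_spec(8, 8, 800))
    f <- hudson_fst(pr, n_perm = 199, seed = i)
    if (f$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
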