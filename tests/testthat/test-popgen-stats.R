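# Polymorphism and divergence statistics against hand counts and
# brute-force oracles.

test_that("hand-enumerated toy values are reproduced", {
  expect_equal(nucleotide_diversity(c("ACGT", "ACGA", "ACGA")), 1 / 6)
  expect_equal(nucleotide_diversity(c("AAAA", "AAAA", "AAAA")), 0)
  expect_error(nucleotide_diversity("ACGT"), "insufficient data")
  # n=3, S=1, L=4: a_3 = 1.5
  expect_equal(watterson_theta(c("ACGT", "ACGA", "ACGA")), 1 / (1.5 * 4))
  expect_equal(watterson_theta(c("AAAA", "AAAA")), 0)
  p <- pop_pair(c(x = "AAAA"), c(y = "AAAT", z = "AAAT"))
  nd <- net_divergence(p)
  expect_equal(nd$dxy, 1 / 4)
  expect_equal(nd$pi2, 0)
  expect_equal(nd$da, 1 / 4)
  ident <- pop_pair("ACGT", "ACGT")
  nd0 <- net_divergence(ident)
  expect_equal(nd0$dxy, 0)
  expect_equal(nd0$da, 0)
})

test_that("haplotype statistics match closed forms", {
  h0 <- haplotype_stats(rep("ACGTA", 3))
  expect_equal(h0$hap_count, 1L)
  expect_equal(h0$hap_diversity, 0)
  h1 <- haplotype_stats(c("AAAA", "AAAT", "AATC", "ATCG"))
  expect_equal(h1$hap_count, 4L)
  expect_equal(h1$hap_diversity, 1) # (4/3)(1 - 4/16)
})

test_that("statistics agree with brute-force oracles on random fixtures", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    L <- sample(c(40, 80, 150), 1)
    m <- random_alignment(n, L, p_missing = ifelse(rep %% 3 == 0, 0.02, 0))
    expect_equal(nucleotide_diversity(m), oracle_pi(m), tolerance = 1e-9)
    expect_equal(watterson_theta(m), oracle_theta_w(m), tolerance = 1e-9)
    td <- tajimas_d(m)
    od <- oracle_tajima_d(m)
    if (is.na(od)) expect_false(td$defined) else {
      expect_equal(td$d, od, tolerance = 1e-9)
    }
    expect_equal(haplotype_stats(m)$hap_diversity, oracle_hd(m),
                 tolerance = 1e-9)
    r2 <- r2_statistic(m)$r2
    o2 <- oracle_r2(m)
    if (is.na(o2)) expect_true(is.na(r2)) else {
      expect_equal(r2, o2, tolerance = 1e-9)
    }
  }
})

test_that("pair statistics equal composed oracles and the da identity holds", {
  set.seed(202)
  for (rep in 1:40) {
    pr <- random_pair(n1 = sample(3:7, 1), n2 = sample(3:7, 1), L = 100,
                      p_missing = ifelse(rep %% 4 == 0, 0.02, 0))
    st <- pair_stats(pr)
    expect_equal(st$da, st$dxy - (st$pi_1 + st$pi_2) / 2, tolerance = 1e-12)
    m <- rbind(pr$seqs1, pr$seqs2)
    expect_equal(st$pi_total, oracle_pi(m), tolerance = 1e-9)
    expect_equal(st$dxy, oracle_dxy(pr$seqs1, pr$seqs2), tolerance = 1e-9)
    expect_true(st$s >= st$pars_inf)
    expect_true(st$hap_count <= pr$n1 + pr$n2)
  }
})

test_that("pi and thetaW are exactly invariant to relabeling", {
  set.seed(303)
  m <- random_alignment(8, 90)
  sh <- m[sample(nrow(m)), ]
  expect_identical(nucleotide_diversity(m), nucleotide_diversity(sh))
  expect_identical(watterson_theta(m), watterson_theta(sh))
  expect_identical(tajimas_d(m)$d, tajimas_d(sh)$d)
})

test_that("guarded 1/D behaves at the boundaries", {
  mono <- rep("ACGT", 5)
  td <- tajimas_d(mono)
  expect_false(td$defined)
  expect_equal(inv_tajima_d(mono), 0)
  expect_equal(inv_tajima_d(list(d = 5e-4, defined = TRUE)), 1000)
  expect_equal(inv_tajima_d(list(d = -5e-4, defined = TRUE)), -1000)
  expect_equal(inv_tajima_d(list(d = 2, defined = TRUE)), 0.5)
  expect_equal(tajd_denom(mono), 0)
})

test_that("estimator means are close to truth under neutral simulation", {
  set.seed(404)
  theta <- 0.008
  pis <- thws <- numeric(400)
  for (i in 1:400) {
    st <- codiverge:::cpp_sim_pair_stats(15, 15, 1000, theta, theta, theta,
                                         0, 0, 0, 0.0125, 8, rep(0.25, 4))
    pis[i] <- st["pi"]
    thws[i] <- st["theta_w"]
  }
  expect_lt(abs(mean(pis) - theta) / theta, 0.05)
  expect_lt(abs(mean(thws) - theta) / theta, 0.05)
})
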