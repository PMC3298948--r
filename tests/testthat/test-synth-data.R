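# Synthetic-study generation and round trips.

test_that("generated studies ingest cleanly and round-trip the truth", {
  dir <- tempfile("study")
  cfg <- study_preset("small")
  truth <- generate_study(cfg, seed = 3, dir = dir)
  expect_true(file.exists(file.path(dir, "truth.json")))
  expect_true(file.exists(file.path(dir, "config.yaml")))
  expect_warning(pairs <- read_study(dir), NA) # zero-warning ingestion
  expect_length(pairs, cfg$k)
  expect_equal(vapply(pairs, `[[`, integer(1), "n1"), cfg$n1)
  expect_equal(vapply(pairs, `[[`, integer(1), "length"), cfg$length)
  back <- jsonlite::read_json(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
  expect_equal(back$psi_true, truth$psi_true)
  expect_equal(back$event_times_true, truth$event_times_true)
  expect_equal(back$assignment_true, truth$assignment_true)
  expect_equal(back$theta1, truth$theta1)
  sv <- observed_vector(pairs)
  expect_equal(nrow(sv), cfg$k)
})

test_that("generation is byte-identical under a fixed seed", {
  d1 <- tempfile(); d2 <- tempfile()
  cfg <- study_preset("small")
  generate_study(cfg, seed = 11, dir = d1)
  generate_study(cfg, seed = 11, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("theta = 0 with tau = 0 yields monomorphic FASTAs", {
  dir <- tempfile()
  cfg <- study_preset("small")
  cfg$theta1 <- cfg$theta2 <- cfg$thetaA <- rep(0, 3)
  cfg$event_times <- c(0, 0)
  generate_study(cfg, seed = 1, dir = dir)
  pairs <- read_study(dir)
  for (p in pairs) {
    expect_equal(pair_stats(p)$s, 0L)
  }
})

test_that("the nullarbor10 preset matches its documented design", {
  cfg <- study_preset("nullarbor10")
  expect_equal(cfg$k, 10L)
  expect_equal(cfg$psi, 3L)
  expect_length(cfg$event_times, 3)
  expect_equal(range(cfg$length), c(865L, 1033L))
  expect_equal(tabulate(cfg$assignment, 3), c(5L, 3L, 2L))
})

test_that("worked fixtures carry their recorded oracle values", {
  fx <- worked_fixtures()
  expect_equal(nucleotide_diversity(fx$three_seq$seqs),
               fx$three_seq$expected$pi)
  expect_equal(haplotype_stats(fx$all_distinct4$seqs)$hap_diversity,
               fx$all_distinct4$expected$hap_diversity)
  st <- pair_stats(pop_pair(fx$simple_pair$seqs1, fx$simple_pair$seqs2))
  expect_equal(st$dxy, fx$simple_pair$expected$dxy)
  expect_equal(st$da, fx$simple_pair$expected$da)
})
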