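# Synthetic studies: complete co-divergence datasets (FASTA alignments,
# popmap, config, truth manifest) with the statistical structure the
# analysis assumes, so every stage is testable without any download.

#' Study design presets
#'
#' `"nullarbor10"` emulates the motivating 10-species design (sample sizes and
#' alignment lengths of the southern-Australian bird survey, three
#' co-divergence events at tau = 0.01/0.23/1.15 with 5/3/2 pairs and
#' realistic per-species thetas); `"small"` is a 3-species design (n = 8+8,
#' L = 300) sized for fast pipelines.
#'
#' @param name `"nullarbor10"` or `"small"`.
#' @return study config list: `k`, `n1`, `n2`, `length`, `psi`,
#'   `event_times`, `assignment`, `theta1`, `theta2`, `thetaA`,
#'   `migration`, `theta_ave`, `kappa`.
#' @export
study_preset <- function(name = c("nullarbor10", "small")) {
  name <- match.arg(name)
  if (name == "nullarbor10") {
    sp <- nullarbor_birds()$specs
    # assignment follows the observed depth ordering: 4 recent, 3 middle,
    # 2 old, with the 3rd-deepest pair joining the middle event
    list(k = 10L,
         n1 = pmax(sp$n1, 2L), n2 = pmax(sp$n2, 2L), length = sp$length,
         psi = 3L,
         event_times = c(0.01, 0.23, 1.15),
         assignment = c(3L, 3L, 2L, 2L, 2L, 1L, 1L, 1L, 1L, 1L),
         theta1 = rep(0.005, 10), theta2 = rep(0.005, 10),
         thetaA = rep(0.00125, 10), migration = rep(0, 10),
         theta_ave = 0.0125, kappa = 8)
  } else {
    list(k = 3L, n1 = rep(8L, 3), n2 = rep(8L, 3), length = rep(300L, 3),
         psi = 2L, event_times = c(0.05, 1.0), assignment = c(1L, 1L, 2L),
         theta1 = rep(0.005, 3), theta2 = rep(0.005, 3),
         thetaA = rep(0.00125, 3), migration = rep(0, 3),
         theta_ave = 0.0125, kappa = 8)
  }
}

#' Generate a complete synthetic study on disk
#'
#' Simulates each species under the configured co-divergence history and
#' writes one aligned FASTA per species, a single popmap, a YAML copy of the
#' configuration and a JSON truth manifest. Deterministic given `seed`.
#'
#' @param config study config (see [study_preset()]).
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return invisibly, the truth manifest list (also written to
#'   `truth.json`).
#' @export
generate_study <- function(config = study_preset("small"), seed = 1,
                           dir = tempfile("study")) {
  stopifnot(config$k >= 2, all(config$n1 >= 2), all(config$n2 >= 2),
            all(config$length > 0),
            length(config$assignment) == config$k,
            max(config$assignment) <= length(config$event_times))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop("cannot create output directory ", dir)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  popmap <- NULL
  for (s in seq_len(config$k)) {
    spec <- pair_spec(config$n1[s], config$n2[s], config$length[s],
                      kappa = config$kappa)
    tau <- config$event_times[config$assignment[s]]
    pr <- simulate_pair(config$theta1[s], config$theta2[s], config$thetaA[s],
                        tau, spec, theta_ave = config$theta_ave,
                        migration = config$migration[s],
                        species = sprintf("species%02d", s))
    ids1 <- rownames(pr$seqs1)
    ids2 <- rownames(pr$seqs2)
    lines <- character(0)
    for (i in seq_along(ids1)) {
      lines <- c(lines, paste0(">", ids1[i]),
                 paste(pr$seqs1[i, ], collapse = ""))
    }
    for (i in seq_along(ids2)) {
      lines <- c(lines, paste0(">", ids2[i]),
                 paste(pr$seqs2[i, ], collapse = ""))
    }
    writeLines(lines, file.path(dir, sprintf("species%02d.fasta", s)))
    popmap <- rbind(popmap,
                    data.frame(id = c(ids1, ids2),
                               pop = rep(c("pop1", "pop2"),
                                         c(length(ids1), length(ids2)))))
  }
  write.table(popmap, file.path(dir, "popmap.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  yaml::write_yaml(config, file.path(dir, "config.yaml"))
  truth <- list(psi_true = config$psi,
                event_times_true = config$event_times,
                assignment_true = config$assignment,
                theta1 = config$theta1, theta2 = config$theta2,
                thetaA = config$thetaA, migration = config$migration,
                seed = seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(truth)
}

#' Read a generated study back as population pairs
#'
#' @param dir a directory written by [generate_study()].
#' @return list of [pop_pair()] objects, one per `*.fasta` file.
#' @export
read_study <- function(dir) {
  fastas <- sort(list.files(dir, pattern = "\\.fasta$", full.names = TRUE))
  if (length(fastas) == 0) stop("no FASTA files in ", dir)
  popmap <- file.path(dir, "popmap.tsv")
  lapply(fastas, read_pair, popmap_path = popmap)
}

#' Small worked alignments with hand-verified statistics
#'
#' Toy alignments used throughout the documentation and tests, shipped with
#' their expected statistic values (hand-enumerated).
#'
#' @return list of fixtures; each has `seqs` (and for the pair fixture,
#'   `seqs1`/`seqs2`), plus an `expected` list of hand-computed values.
#' @export
worked_fixtures <- function() {
  list(
    three_seq = list(
      seqs = c(a = "ACGT", b = "ACGA", c = "ACGA"),
      expected = list(pi = 1 / 6, s = 1L, hap_count = 2L)),
    monomorphic = list(
      seqs = c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT"),
      expected = list(pi = 0, s = 0L, hap_count = 1L, hap_diversity = 0)),
    all_distinct4 = list(
      seqs = c(a = "AAAA", b = "AAAT", c = "AATC", d = "ATCG"),
      expected = list(hap_count = 4L, hap_diversity = 1)),
    simple_pair = list(
      seqs1 = c(x = "AAAA"),
      seqs2 = c(y = "AAAT", z = "AAAT"),
      expected = list(dxy = 1 / 4, da = 1 / 4)),
    # 6 codons; ingroup polymorphism CTT/CTC (Leu/Leu, synonymous) at codon
    # 2 and a fixed difference ATT(Ile) -> ACT(Thr) at codon 4 (nonsynonymous
    # under both the standard and vertebrate-mt codes)
    mk_toy = list(
      ingroup = c(i1 = "ATGCTTGGAATTAAACCC",
                  i2 = "ATGCTCGGAATTAAACCC",
                  i3 = "ATGCTTGGAATTAAACCC"),
      outgroup = c(o1 = "ATGCTTGGAACTAAACCC"),
      expected = list(syn_poly = 1, nonsyn_poly = 0,
                      syn_fixed = 0, nonsyn_fixed = 1)))
}
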