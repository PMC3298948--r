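Package: codiverge
Title: Hierarchical ABC and Assemblage Isolation-with-Migration Analysis
    of Co-Divergence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tests for temporal congruence of population divergence across a
    shared biogeographic barrier from single-locus mtDNA alignments. Computes
    per-population and per-pair polymorphism statistics and neutrality tests
    (pi, net divergence, Watterson's theta, Tajima's D, haplotype diversity,
    Fu's Fs, Ramos-Onsins and Rozas's R2, McDonald-Kreitman, Hudson's Fst),
    simulates finite-sites HKY sequence data for population pairs co-diverging
    at a small number of discrete times under a hierarchical coalescent model,
    estimates the number (Psi), dispersion (Omega) and mean (E[tau]) of
    co-divergence events by rejection/regression approximate Bayesian
    computation with Bayes-factor model comparison, fits an
    isolation-with-migration model jointly to a co-diverging species
    assemblage with per-species inheritance scalars, and converts
    mutation-scaled divergence times to years.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    nnet,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
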