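# codiverge

Two-stage comparative phylogeography from single-locus mtDNA data: did
co-distributed species diverge across a shared biogeographic barrier at the
same time, how many discrete co-divergence events were there, when were
they, and what demography accompanied them?

`codiverge` is built for the study design in which each of K species has
aligned sequences of one non-recombining locus (e.g. ND2, ~1 kb) from the
two populations flanking a barrier — the motivating system is 10 bird
species split by southern Australia's Nullarbor Plain into southwestern and
southeastern populations. It provides:

* **Polymorphism statistics and neutrality tests** per population pair:
  nucleotide diversity pi, net divergence Da, Watterson's theta, Tajima's D,
  haplotype diversity, Fu's Fs and Ramos-Onsins & Rozas's R2 with
  coalescent p-values, the McDonald–Kreitman test (vertebrate-mt code), and
  Hudson's Fst with a permutation test.
* **Hierarchical ABC** over a coalescent model of K population pairs
  co-diverging at Psi discrete times: the number of events Psi
  (polychotomous regression), the dispersion index Omega = Var(tau)/E(tau)
  and the mean divergence time E[tau] (local-linear-adjusted rejection
  sampling), Bayes factors on the Jeffreys scale, constrained-Psi event
  timing with species-to-event assignment, and taxon-subset support runs.
* **Assemblage isolation-with-migration**: one IM model
  (theta1, theta2, thetaA, m1, m2, t) fitted jointly to a co-diverging
  species assemblage, species acting as loci with per-species inheritance
  scalars h, by simulation-based inference.
* **Time conversions** to years from all three divergence scales (tau,
  per-locus IM t, and raw Da) under an avian mtDNA clock
  (2.1%/My between lineage pairs by default).

The core model: pair j diverged at time tau_{z(j)} drawn from one of Psi
shared event times (tau ~ U(0, 3) in 4·N_ave-generation units; z uniform
over surjective assignments), with per-pair nuisance demography
(theta ~ U(0, 0.025)/site, uneven descendant split, ancestral fraction
U(0, 0.25), founding bottlenecks U(0.01, 1) with exponential growth) and
finite-sites HKY mutation. Observed and simulated data are reduced to the
per-pair vector (pi, net pi, theta_W, Tajima-denominator), ordered by net
pi. See the methods vignette (`vignettes/codivergence-methods.Rmd`) for the
full model, units and design choices.

## Worked example

Generate a small synthetic study (3 species, 8+8 sequences of 300 bp, two
co-divergence events at tau = 0.05 and 1.0), summarise it, and estimate the
hyper-parameters:

```r
library(codiverge)

dir <- tempfile("study")
cfg <- study_preset("small")          # truth: Psi = 2, events {0.05, 1.0}
generate_study(cfg, seed = 42, dir = dir)
pairs <- read_study(dir)
sv <- observed_vector(pairs)
print(sv, digits = 3)
#>     species       pi   net_pi theta_w tajd_denom
#> 1 species02 0.000833 0.000000 0.00201     0.0111
#> 2 species01 0.001194 0.000119 0.00201     0.0111
#> 3 species03 0.018333 0.025000 0.01507     0.0305

fit <- habc_fit(sv, data.frame(n1 = cfg$n1, n2 = cfg$n2, length = cfg$length),
                prior = hyper_prior(psi_max = 3), n_sims = 20000,
                n_accept = 200, seed = 7)
fit
#> Hierarchical ABC posterior (200/20000 draws accepted)
#>   Psi posterior (polychotomous_regression):
#>      1      2      3
#> 0.0055 0.8697 0.1247
#>   Psi mode = 2
#>   Omega  mode 0.6497  (2.5%-97.5%: 0.0000-30.1531)
#>   E[tau] mode 0.4310  (2.5%-97.5%: 0.1830-0.9169)
#> BF(Psi = 1 vs Psi > 1) = 0.01107 [negative (supports the alternative)]
#> BF(Psi <= 2 vs Psi > 2) = 3.508 [substantial]
```

The fit recovers the planted two-event history: P(Psi = 2 | data) = 0.87,
simultaneous divergence is rejected (BF far below 1), and the mean
divergence time 0.431 sits between the two planted event times, converting
to `tau_to_years(0.431)` ≈ 513,000 years under the default clock.

The bundled observed dataset of the motivating study is available as
`nullarbor_birds()`; running `habc_fit()` on it with the default priors
reproduces the headline result (Psi posterior mode 3), and
`constrained_habc(..., psi_fixed = 3)` yields the three event times with
eight confidently assigned species and two ambiguous ones. The assemblage
stage is `fit_assemblage()` on a list of `pop_pair` objects;
`compare_events()` tabulates both stages' divergence times in years.

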