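# Bundled example data: observed mtDNA (ND2) summary statistics for 10 bird
# species whose populations are split between Australia's southwestern and
# southeastern mesic zones across the Nullarbor barrier, as printed in the
# comparative survey that motivates this package. Sample sizes and alignment
# lengths accompany the summary table so that the hierarchical ABC stage can
# be run directly on the printed observed vector without raw sequence data.

#' Observed summary statistics for the southern-Australian bird assemblage
#'
#' Per-species pooled summary statistics (nucleotide diversity, net
#' divergence, Watterson's theta and the per-site Tajima's D denominator —
#' the default msBayes summary set) for 10 bird species' SW/SE population
#' pairs across the Nullarbor barrier, together with their sample sizes and
#' alignment lengths.
#'
#' @return list with two data frames:
#'   * `observed`: `species`, `pi`, `net_pi`, `theta_w`, `tajd_denom`
#'     (printed order, deepest divergence first);
#'   * `specs`: `species`, `n1` (SW), `n2` (SE), `length` (bp).
#' @examples
#' d <- nullarbor_birds()
#' sv <- sort_observed(d$observed)
#' head(sv)
#' @export
nullarbor_birds <- function() {
  observed <- data.frame(
    species = c("Melithreptus_lunatus", "Petroica_boodang",
                "Phylidonyris_novaehollandiae", "Malurus_splendens",
                "Climacteris_rufus", "Gliciphila_melanops",
                "Glossopsitta_porphyrocephala", "Eopsaltria_griseogularis",
                "Malurus_pulcherrimus", "Drymodes_brunneopygia"),
    pi = c(0.024787, 0.012806, 0.009034, 0.007556, 0.002571,
           0.005678, 0.001258, 0.001143, 0.002312, 0.002602),
    net_pi = c(0.041916, 0.027713, 0.012496, 0.010777, 0.002367,
               0.000836, 0.000396, 0.000298, 0, 0),
    theta_w = c(0.015394, 0.0105, 0.008135, 0.008051, 0.003542,
                0.008516, 0.00344, 0.001777, 0.00376, 0.003686),
    tajd_denom = c(0.036908, 0.032003, 0.026547, 0.027008, 0.014701,
                   0.026703, 0.016245, 0.012167, 0.012275, 0.014251),
    stringsAsFactors = FALSE)
  specs <- data.frame(
    species = observed$species,
    n1 = c(14L, 10L, 10L, 14L, 6L, 11L, 9L, 12L, 2L, 3L),
    n2 = c(16L, 28L, 19L, 34L, 26L, 16L, 14L, 15L, 8L, 11L),
    length = c(1033L, 1020L, 1033L, 987L, 1022L, 865L, 1024L, 1022L,
               1022L, 865L),
    stringsAsFactors = FALSE)
  list(observed = observed, specs = specs)
}

#' Apply the ABC ordering rule to an observed summary table
#'
#' Sorts a data frame of per-pair summary statistics ascending by `net_pi`
#' (ties broken by `pi`), the same rule [observed_vector()] and
#' [reference_table()] use, and gives it the `summary_vector` class.
#'
#' @param df data frame with columns `species`, `pi`, `net_pi`, `theta_w`
#'   and a fourth statistic column.
#' @return sorted `summary_vector` data frame.
#' @export
sort_observed <- function(df) sort_summary_vector(df)
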