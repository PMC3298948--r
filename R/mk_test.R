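# McDonald-Kreitman test: synonymous/non-synonymous classification of
# polymorphic (within-ingroup) vs fixed (ingroup vs outgroup) differences,
# with a two-sided Fisher exact test on the 2x2 table.

# NCBI translation tables, codon index = 16*b1 + 4*b2 + b3 with T=0 C=1 A=2 G=3
GENETIC_CODES <- list(
  standard =
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  vertebrate_mt =
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIMMTTTTNNKKSS**VVVVAAAADDEEGGGG")

translate_codon <- function(codon, code) {
  idx <- match(strsplit(codon, "")[[1]], c("T", "C", "A", "G"))
  if (anyNA(idx)) return(NA_character_)
  substr(code, 16 * (idx[1] - 1) + 4 * (idx[2] - 1) + idx[3], 16 * (idx[1] - 1) + 4 * (idx[2] - 1) + idx[3])
}

# average (syn, nonsyn) counts over minimal mutational paths between two
# codons, skipping paths that pass through a stop codon; NULL if all paths
# blocked
codon_path_counts <- function(from, to, code) {
  diff_pos <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
  k <- length(diff_pos)
  if (k == 0) return(c(syn = 0, nonsyn = 0))
  perms <- if (k == 1) list(diff_pos) else {
    if (k == 2) list(diff_pos, rev(diff_pos)) else {
      idx <- expand.grid(a = 1:3, b = 1:3, c = 1:3)
      idx <- idx[apply(idx, 1, function(r) length(unique(r)) == 3), ]
      lapply(seq_len(nrow(idx)), function(i) diff_pos[unlist(idx[i, ])])
    }
  }
  acc <- c(syn = 0, nonsyn = 0)
  nok <- 0
  for (ord in perms) {
    cur <- from
    path <- c(syn = 0, nonsyn = 0)
    ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(to, p, p)
      aa1 <- translate_codon(cur, code)
      aa2 <- translate_codon(nxt, code)
      if (is.na(aa1) || is.na(aa2) || aa2 == "*") { ok <- FALSE; break }
      if (aa1 == aa2) path["syn"] <- path["syn"] + 1
      else path["nonsyn"] <- path["nonsyn"] + 1
      cur <- nxt
    }
    if (ok) { acc <- acc + path; nok <- nok + 1 }
  }
  if (nok == 0) return(NULL)
  acc / nok
}

#' McDonald-Kreitman test
#'
#' Classifies coding variation as synonymous/non-synonymous and polymorphic
#' (variable within the ingroup) vs fixed (ingroup monomorphic and different
#' from the outgroup), then tests the 2x2 table with a two-sided Fisher exact
#' test. Codons with several variable positions are counted by enumerating
#' minimal mutational paths and averaging the synonymous/non-synonymous
#' split over paths; paths through stop codons are dropped, and codons whose
#' paths all hit stops are skipped with a warning.
#'
#' @param ingroup aligned ingroup sequences (see [seq_matrix()]).
#' @param outgroup a single aligned outgroup sequence (string).
#' @param frame_offset 0-based offset of the first complete codon.
#' @param code genetic code: `"vertebrate_mt"` (default, appropriate for
#'   mtDNA protein-coding loci) or `"standard"`.
#' @return list of class `mk_table`: `syn_poly`, `nonsyn_poly`, `syn_fixed`,
#'   `nonsyn_fixed`, `p_value`.
#' @export
mk_test <- function(ingroup, outgroup, frame_offset = 0,
                    code = c("vertebrate_mt", "standard")) {
  code <- GENETIC_CODES[[match.arg(code)]]
  m <- seq_matrix(ingroup)
  og <- seq_matrix(outgroup)
  if (nrow(og) != 1) stop("outgroup must be a single sequence")
  if (ncol(og) != ncol(m)) stop("outgroup must be aligned to the ingroup")
  usable <- ncol(m) - frame_offset
  n_codon <- usable %/% 3
  if (n_codon < 1) stop("alignment too short for a complete codon")
  counts <- c(syn_poly = 0, nonsyn_poly = 0, syn_fixed = 0, nonsyn_fixed = 0)
  skipped <- 0
  for (cd in seq_len(n_codon)) {
    cols <- frame_offset + (3 * (cd - 1) + 1):(3 * cd)
    sub <- m[, cols, drop = FALSE]
    oc <- paste(og[1, cols], collapse = "")
    if (any(!sub %in% c("A", "C", "G", "T")) ||
        any(!og[1, cols] %in% c("A", "C", "G", "T"))) next
    haps <- unique(apply(sub, 1, paste, collapse = ""))
    # replace T-coding: sequences use ACGT with T; translation table indexed
    # by T directly, so nothing to convert
    poly_pos <- which(apply(sub, 2, function(x) length(unique(x)) > 1))
    # polymorphic changes: each non-major codon against the major codon,
    # restricted to within-ingroup variable positions
    if (length(poly_pos) > 0) {
      tab <- table(apply(sub, 1, paste, collapse = ""))
      major <- names(tab)[which.max(tab)]
      ok_all <- TRUE
      for (h in setdiff(haps, major)) {
        pc <- codon_path_counts(major, h, code)
        if (is.null(pc)) { ok_all <- FALSE; break }
        counts["syn_poly"] <- counts["syn_poly"] + pc["syn"]
        counts["nonsyn_poly"] <- counts["nonsyn_poly"] + pc["nonsyn"]
      }
      if (!ok_all) { skipped <- skipped + 1; next }
    }
    # fixed changes: positions monomorphic in the ingroup but != outgroup
    mono_pos <- setdiff(1:3, poly_pos)
    ing_codon <- apply(sub, 2, function(x) x[1])
    fixed_pos <- mono_pos[ing_codon[mono_pos] != og[1, cols][mono_pos]]
    if (length(fixed_pos) > 0) {
      target <- ing_codon
      target[fixed_pos] <- og[1, cols][fixed_pos]
      pc <- codon_path_counts(paste(ing_codon, collapse = ""),
                              paste(target, collapse = ""), code)
      if (is.null(pc)) { skipped <- skipped + 1; next }
      counts["syn_fixed"] <- counts["syn_fixed"] + pc["syn"]
      counts["nonsyn_fixed"] <- counts["nonsyn_fixed"] + pc["nonsyn"]
    }
  }
  if (skipped > 0) {
    warning(skipped, " codon(s) skipped (all mutational paths hit a stop codon)")
  }
  tab <- matrix(c(counts["syn_poly"], counts["nonsyn_poly"],
                  counts["syn_fixed"], counts["nonsyn_fixed"]), 2, 2)
  p <- if (sum(tab) == 0) 1 else stats::fisher.test(round(tab))$p.value
  out <- c(as.list(counts), list(p_value = p))
  names(out) <- c("syn_poly", "nonsyn_poly", "syn_fixed", "nonsyn_fixed",
                  "p_value")
  class(out) <- "mk_table"
  out
}

#' @export
print.mk_table <- function(x, ...) {
  cat("McDonald-Kreitman 2x2 table\n")
  cat(sprintf("            poly   fixed\n  syn     %6.2f  %6.2f\n  nonsyn  %6.2f  %6.2f\n",
              x$syn_poly, x$syn_fixed, x$nonsyn_poly, x$nonsyn_fixed))
  cat(sprintf("  Fisher exact p = %.4g\n", x$p_value))
  invisible(x)
}
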