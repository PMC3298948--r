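# Internal helpers shared by the polymorphism statistics.
#
# All statistics use "complete deletion": a site is analysed only if every
# sequence in the sample under analysis carries an unambiguous base (A/C/G/T)
# there. The per-site denominators use the number of retained sites.

VALID_CHARS <- c("A", "C", "G", "T", "N", "-")

#' Coerce sequences to an aligned character matrix
#'
#' Accepts a character vector of equal-length strings, a character matrix
#' (one row per sequence), or a `DNAbin` object from \pkg{ape}. Bases are
#' upper-cased; anything outside `A,C,G,T,N,-` is an error.
#'
#' @param seqs sequences in any of the accepted forms.
#' @return character matrix, one row per sequence, one column per site.
#' @export
seq_matrix <- function(seqs) {
  if (inherits(seqs, "DNAbin")) {
    seqs <- toupper(sapply(as.character(as.list(seqs)), paste, collapse = ""))
  }
  if (length(seqs) == 0) stop("insufficient data: no sequences")
  if (is.matrix(seqs)) {
    m <- toupper(seqs)
  } else if (is.character(seqs)) {
    seqs <- toupper(seqs)
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1) {
      stop("alignment error: sequences have unequal lengths (",
           paste(unique(lens), collapse = ", "), ")")
    }
    m <- matrix("", nrow = length(seqs), ncol = lens[1])
    for (i in seq_along(seqs)) m[i, ] <- strsplit(seqs[i], "")[[1]]
    rownames(m) <- names(seqs)
  } else {
    stop("cannot interpret 'seqs' as aligned sequences")
  }
  bad <- setdiff(unique(as.vector(m)), VALID_CHARS)
  if (length(bad) > 0) {
    stop("invalid characters in alignment: ", paste(bad, collapse = ", "))
  }
  m
}

# columns where every sequence has an unambiguous base
retained_sites <- function(m) {
  if (ncol(m) == 0) return(integer(0))
  which(apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T"))))
}

# alignment restricted to retained sites
clean_matrix <- function(m) m[, retained_sites(m), drop = FALSE]

check_min_seqs <- function(m, k, what) {
  if (nrow(m) < k) {
    stop("insufficient data: ", what, " needs at least ", k,
         " sequences, got ", nrow(m))
  }
}

# string form (used for haplotype identity)
row_strings <- function(m) apply(m, 1, paste, collapse = "")
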