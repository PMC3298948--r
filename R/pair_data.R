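#' One species' population pair
#'
#' Container for a single species' aligned sequences split into the two
#' descendant populations on either side of a barrier (conventionally
#' `pop1` = southwest, `pop2` = southeast). This is the unit of the
#' comparative analysis.
#'
#' @param seqs1,seqs2 aligned sequences for each population: character vector
#'   of equal-length strings, character matrix, or `DNAbin`.
#' @param species species label.
#' @return an object of class `pop_pair` with elements `species`, `seqs1`,
#'   `seqs2` (character matrices), `n1`, `n2` and `length` (alignment columns).
#' @examples
#' p <- pop_pair(c(a = "ACGT"), c(b = "ACGA", c = "ACGA"), species = "toy")
#' p$n1; p$n2; p$length
#' @export
pop_pair <- function(seqs1, seqs2, species = "species") {
  m1 <- seq_matrix(seqs1)
  m2 <- seq_matrix(seqs2)
  if (nrow(m1) < 1 || nrow(m2) < 1) {
    stop("insufficient data: both populations need at least one sequence")
  }
  if (ncol(m1) != ncol(m2)) {
    stop("alignment error: populations have different alignment lengths (",
         ncol(m1), " vs ", ncol(m2), ")")
  }
  structure(
    list(species = species, seqs1 = m1, seqs2 = m2,
         n1 = nrow(m1), n2 = nrow(m2), length = ncol(m1)),
    class = "pop_pair")
}

#' @export
print.pop_pair <- function(x, ...) {
  cat("pop_pair '", x$species, "': ", x$n1, " + ", x$n2,
      " sequences, ", x$length, " aligned sites\n", sep = "")
  invisible(x)
}

# pooled alignment, pop1 rows first
pooled_matrix <- function(pair) rbind(pair$seqs1, pair$seqs2)

#' Read a population pair from a FASTA alignment and a popmap
#'
#' The popmap is a two-column, tab- or whitespace-separated text file with
#' one row per sequence: `sequence_id  population_label`. Exactly two
#' population labels must be present (sorted alphabetically, the first
#' becomes `pop1`) unless `pops` names them explicitly.
#'
#' @param fasta_path path to a plain multi-record aligned FASTA file.
#' @param popmap_path path to the popmap file.
#' @param species species label; defaults to the FASTA file name.
#' @param pops optional character vector of length 2 naming the labels to use
#'   as `pop1` and `pop2`, in that order.
#' @return a [pop_pair()].
#' @export
read_pair <- function(fasta_path, popmap_path, species = NULL, pops = NULL) {
  if (is.null(species)) {
    species <- sub("\\.(fa|fasta|fna)$", "", basename(fasta_path),
                   ignore.case = TRUE)
  }
  dna <- ape::read.FASTA(fasta_path)
  if (length(dna) == 0) stop("no sequences in ", fasta_path)
  seqs <- toupper(vapply(as.character(as.list(dna)),
                         paste, character(1), collapse = ""))
  names(seqs) <- names(dna)
  if (length(unique(nchar(seqs))) > 1) {
    stop("alignment error: FASTA records in ", fasta_path,
         " have unequal lengths")
  }
  pm <- read.table(popmap_path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("id", "pop"))
  missing <- setdiff(names(seqs), pm$id)
  if (length(missing) > 0) {
    stop("mapping error: sequence id(s) missing from popmap: ",
         paste(missing, collapse = ", "))
  }
  labs <- pm$pop[match(names(seqs), pm$id)]
  if (is.null(pops)) {
    pops <- sort(unique(labs))
  }
  if (length(setdiff(unique(labs), pops)) > 0 || length(pops) != 2) {
    stop("mapping error: popmap must assign exactly two population labels; ",
         "found: ", paste(unique(labs), collapse = ", "))
  }
  s1 <- seqs[labs == pops[1]]
  s2 <- seqs[labs == pops[2]]
  if (length(s1) < 1 || length(s2) < 1) {
    stop("mapping error: population '",
         pops[which(c(length(s1), length(s2)) < 1)[1]], "' has no sequences")
  }
  pop_pair(s1, s2, species = species)
}
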