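## Internal helpers shared across modules.  All genomic coordinates inside
## the package are 0-based half-open; GFF3 (1-based inclusive) and BED
## (0-based half-open) are converted at the I/O boundary.

.check_dna <- function(x, arg = deparse(substitute(x))) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single character string", arg), call. = FALSE)
  x <- toupper(x)
  if (grepl("[^ACGT]", x))
    stop(sprintf("'%s' contains non-ACGT characters", arg), call. = FALSE)
  x
}

.check_prob <- function(p, arg = deparse(substitute(p))) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop(sprintf("'%s' must be in [0, 1]", arg), call. = FALSE)
  p
}

#' Generate a random nucleotide sequence
#'
#' Draws an i.i.d. uniform ACGT sequence.  Used as neutral background for
#' synthetic genomes; uniform composition avoids accidental homology with
#' planted elements.
#'
#' @param n Sequence length in bp.
#' @return A single character string of length `n`.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Reverse-complement a nucleotide string
#'
#' @param x A single ACGT character string.
#' @return The reverse complement, as a character string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## substring on 0-based half-open coordinates
.substr0 <- function(x, start, end) substr(x, start + 1L, end)

## substitute k random positions of a string with different bases
.mutate_positions <- function(x, pos) {
  v <- strsplit(x, "")[[1]]
  for (i in pos) {
    v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  }
  paste(v, collapse = "")
}

## per-site substitution at rate p (substitutions only)
.diverge <- function(x, p) {
  if (p <= 0) return(x)
  n <- nchar(x)
  hit <- which(stats::runif(n) < p)
  if (length(hit) == 0L) return(x)
  .mutate_positions(x, hit)
}

## nucleotide scoring matrix used throughout (match +1, mismatch -2)
.submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                           baseOnly = TRUE)
}
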