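#' Synthetic consensus sequence of a Mariam-like miniature element
#'
#' A fixed 307-bp synthetic element used as the default consensus by the
#' simulation module.  It reproduces the structural properties reported for
#' the wheat miniature element Mariam: 307 bp long, no terminal inverted
#' repeats, no SINE hallmarks (no internal Pol-III A/B boxes, no poly-A
#' tail), and an in-frame TAA stop codon placed so that, when the element
#' inserts at the planned exonic target site, translation terminates at
#' nucleotide 41 of the inserted sequence.  The sequence itself is
#' synthetic (randomly generated under those constraints), not a natural
#' element.
#'
#' @return A 307-character ACGT string.
#' @export
mite_consensus <- function() {
  paste0(
    "ATACCGTCCGTGGTTATACATACAGGCGTATCGACCTGTAATTTAAGTGATGCAAATTGAGG",
    "CTCGGTGGAAGCCGGTGAAATACACGAGATTGACATGGTGCTTTCCACTAGACTAGATCAAG",
    "GAAGGGAAGGGGTTTCTTCGTTCAAAAAATGTTCCGACTTCTATACACTAATTCATGAATAA",
    "CACGTTTGCTAACGTTGCGATAGTTATCAGGATCCCCTTTGGCTGGAAATCCTCCTGGGATG",
    "CCTGGGTATAGTTTCGGTCAGCCGTGGACATTCATGGGGGACTTGTTCTTGCTGTATAA"
  )
}

#' Default target-site motif
#'
#' The 9-bp sequence duplicated on both sides of the index insertion
#' (the motif `CCAAGAACT`); planted at the exonic target site of the
#' simulated host gene so that insertion creates a recognizable
#' target-site duplication.
#'
#' @return A 9-character string.
#' @export
target_site_motif <- function() "CCAAGAACT"

#' Default host-gene plan for the simulator
#'
#' Describes a 7-exon gene whose coding sequence starts in exon 1 and ends
#' in exon 7, with the element insertion target inside exon 6.  All
#' offsets are 0-based.  The geometry is chosen so that:
#'
#' * the reference CDS is 843 nt (280 aa product plus stop);
#' * the 9-bp target-site motif sits at CDS position 701-709 (1-based),
#'   so an element inserted there, with its duplicated target site, puts
#'   element nucleotide 39-41 (an engineered TAA) in frame, truncating
#'   the product to 249 aa with the stop at position 41 of the inserted
#'   307 nucleotides;
#' * RT-PCR primers anchored in exon 5 and exon 7 give a 626-bp spliced
#'   product from the reference allele and a 942-bp product from the
#'   insertion allele (626 + 307 + 9).
#'
#' @return A list with components `exon_len` (7 mRNA exon lengths, bp),
#'   `intron_len` (single intron length, bp), `utr5_len`, `cds_len`,
#'   `insertion_mrna_offset` (0-based mRNA offset of the target site),
#'   `target_exon`, `fwd_primer_start`, `fwd_primer_len`,
#'   `rev_primer_end`, `rev_primer_len` (mRNA coordinates of the
#'   exon-5/exon-7 primer pair), and `target_site` (the 9-mer motif).
#' @export
default_gene_plan <- function() {
  list(
    exon_len = c(130L, 120L, 110L, 100L, 160L, 250L, 300L),
    intron_len = 85L,
    utr5_len = 60L,
    cds_len = 843L,
    insertion_mrna_offset = 760L,
    target_exon = 6L,
    fwd_primer_start = 470L,
    fwd_primer_len = 20L,
    rev_primer_end = 1096L,
    rev_primer_len = 26L,
    target_site = target_site_motif()
  )
}

## mRNA offset -> genomic offset within the gene (0-based, plus strand)
.mrna_to_gene_offset <- function(plan, mrna_offset) {
  cum <- cumsum(plan$exon_len)
  exon <- findInterval(mrna_offset, c(0L, cum), rightmost.closed = FALSE)
  mrna_offset + (exon - 1L) * plan$intron_len
}

## Build the gene's mRNA: designed CDS (stop-free ORF with the target-site
## motif at CDS 701..709) flanked by random UTRs.  Relies on the caller's
## RNG state for reproducibility.
.build_gene_mrna <- function(plan) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  sense <- setdiff(codons, stops)
  n_cod <- plan$cds_len %/% 3L
  cds <- c("ATG", sample(sense, n_cod - 2L, replace = TRUE), "TAA")
  cds <- paste(cds, collapse = "")
  ## place the target-site motif at CDS 701..709 (1-based)
  substr(cds, 701L, 709L) <- plan$target_site
  ## codon 234 (CDS 700..702) now ends "CC" and cannot be a stop; codon 237
  ## (709..711) begins with the motif's final T, so resample its two free
  ## bases until the codon is not a stop
  repeat {
    tail2 <- paste(sample(c("A", "C", "G", "T"), 2L, replace = TRUE),
                   collapse = "")
    if (!(paste0("T", tail2) %in% stops)) break
  }
  substr(cds, 710L, 711L) <- tail2
  utr5 <- random_dna(plan$utr5_len)
  utr3_len <- sum(plan$exon_len) - plan$utr5_len - plan$cds_len
  paste0(utr5, cds, random_dna(utr3_len))
}
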