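#' Write a simulated reference (and optional panel) to disk
#'
#' Writes the genome as 60-column wrapped FASTA, the gene models as GFF3
#' (1-based inclusive), the TE annotation and planted-element truth as
#' BED (0-based half-open), the truth table as TSV, and, when a panel is
#' given, one FASTA per accession plus the panel truth TSV.  With a fixed
#' simulation seed the written files are byte-identical across runs.
#'
#' @param reference A `mite_reference` from [generate_reference()].
#' @param dir Output directory (created if needed).
#' @param panel Optional `mite_panel` from [generate_accession_panel()].
#' @return Invisibly, the vector of files written.
#' @export
write_simulation <- function(reference, dir, panel = NULL) {
  stopifnot(inherits(reference, "mite_reference"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  f <- function(x) file.path(dir, x)

  gen <- Biostrings::DNAStringSet(reference$genome)
  Biostrings::writeXStringSet(gen, f("genome.fa"), width = 60L)
  files <- c(files, f("genome.fa"))

  rtracklayer::export(reference$genes, f("genes.gff3"), format = "gff3")
  files <- c(files, f("genes.gff3"))

  rtracklayer::export(reference$tes, f("tes.bed"), format = "bed")
  files <- c(files, f("tes.bed"))

  truth_bed <- GenomicRanges::GRanges(
    reference$truth$chromosome,
    IRanges::IRanges(start = reference$truth$element_start + 1L,
                     end = reference$truth$element_end),
    strand = reference$truth$strand,
    name = reference$truth$copy_id)
  rtracklayer::export(truth_bed, f("element_truth.bed"), format = "bed")
  utils::write.table(reference$truth, f("truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  el <- Biostrings::DNAStringSet(stats::setNames(reference$element,
                                                 "consensus"))
  Biostrings::writeXStringSet(el, f("element.fa"), width = 60L)
  files <- c(files, f("element_truth.bed"), f("truth.tsv"), f("element.fa"))

  if (!is.null(panel)) {
    pd <- f("panel")
    dir.create(pd, showWarnings = FALSE)
    for (acc in names(panel$sequences)) {
      ss <- Biostrings::DNAStringSet(panel$sequences[[acc]])
      fn <- file.path(pd, paste0(acc, ".fa"))
      Biostrings::writeXStringSet(ss, fn, width = 60L)
      files <- c(files, fn)
    }
    utils::write.table(panel$panel_truth, f("panel_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, f("panel_truth.tsv"))
  }
  invisible(files)
}
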