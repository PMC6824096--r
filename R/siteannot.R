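#' Annotate the genomic context of insertion hits
#'
#' Classifies each insertion as `exon` (overlapping CDS), `UTR`
#' (overlapping an exon outside the CDS), `intron` (inside a gene but not
#' an exon), `gene_proximal` (within `proximity_window` bp of a gene),
#' `TE_adjacent` (overlapping or within `proximity_window` bp of an
#' annotated TE), or `intergenic`, with precedence in that order.
#' Distances use half-open interval arithmetic: the gap between the
#' insertion span and the nearest feature edge, 0 when inside.
#'
#' @param hits Hit data.frame from [search_copies()] (needs `hit_id`,
#'   `chromosome`, `start`, `end`; 0-based half-open), or a
#'   `GRanges`.
#' @param genes `GRanges` of gene-model features with a `type` column
#'   (`gene`, `exon`, `CDS`, ...), as returned by
#'   [generate_reference()] or `rtracklayer::import` of a GFF3 file.
#' @param tes `GRanges` of annotated TE intervals (e.g. from a BED
#'   file), or `NULL`.
#' @param proximity_window Adjacency window in bp (default 500, applied
#'   to genes and TEs alike).
#' @return A data.frame: `insertion_id`, `context_class`, `feature_id`,
#'   `distance` (bp, 0 if inside), `feature_strand`.
#' @export
annotate_site <- function(hits, genes, tes = NULL, proximity_window = 500L) {
  if (is.data.frame(hits)) {
    gr <- GenomicRanges::GRanges(
      hits$chromosome,
      IRanges::IRanges(start = hits$start + 1L, end = hits$end),
      insertion_id = if (!is.null(hits$hit_id)) hits$hit_id
                     else sprintf("ins%03d", seq_len(nrow(hits))))
  } else {
    gr <- hits
    if (is.null(gr$insertion_id))
      gr$insertion_id <- sprintf("ins%03d", seq_along(gr))
  }
  type <- if (!is.null(genes$type)) as.character(genes$type)
          else rep("gene", length(genes))
  gene_r <- genes[type == "gene"]
  exon_r <- genes[type == "exon"]
  cds_r <- genes[type == "CDS"]
  if (length(gene_r) == 0L) gene_r <- genes
  utr_r <- GenomicRanges::setdiff(exon_r, cds_r, ignore.strand = TRUE)

  out <- vector("list", length(gr))
  for (i in seq_along(gr)) {
    h <- gr[i]
    cls <- "intergenic"; feat <- NA_character_
    dist <- NA_integer_; fstrand <- NA_character_
    absent <- !(as.character(GenomeInfoDb::seqnames(h)) %in%
                as.character(GenomeInfoDb::seqlevels(genes)))
    if (absent)
      warning("chromosome ", as.character(GenomeInfoDb::seqnames(h)),
              " absent from the gene annotation; classified intergenic",
              call. = FALSE)
    nearest_info <- function(subject) {
      if (length(subject) == 0L) return(NULL)
      if (!(as.character(GenomeInfoDb::seqnames(h)) %in%
            as.character(GenomeInfoDb::seqlevels(subject)))) return(NULL)
      d <- GenomicRanges::distanceToNearest(h, subject, ignore.strand = TRUE)
      if (length(d) == 0L) return(NULL)
      j <- S4Vectors::subjectHits(d)[1L]
      list(distance = S4Vectors::mcols(d)$distance[1L], idx = j)
    }
    ov <- function(subject)
      length(subject) > 0L &&
        length(GenomicRanges::findOverlaps(h, subject,
                                           ignore.strand = TRUE)) > 0L
    if (!absent && ov(cds_r)) {
      cls <- "exon"; dist <- 0L
      j <- S4Vectors::subjectHits(GenomicRanges::findOverlaps(
        h, cds_r, ignore.strand = TRUE))[1L]
      feat <- as.character(cds_r$ID[j])
      fstrand <- as.character(BiocGenerics::strand(cds_r)[j])
    } else if (!absent && ov(utr_r)) {
      cls <- "UTR"; dist <- 0L
      feat <- NA_character_; fstrand <- NA_character_
    } else if (!absent && ov(gene_r)) {
      cls <- "intron"; dist <- 0L
      j <- S4Vectors::subjectHits(GenomicRanges::findOverlaps(
        h, gene_r, ignore.strand = TRUE))[1L]
      feat <- as.character(gene_r$ID[j])
      fstrand <- as.character(BiocGenerics::strand(gene_r)[j])
    } else {
      ng <- if (!absent) nearest_info(gene_r) else NULL
      if (!is.null(ng) && ng$distance > 0L &&
          ng$distance <= proximity_window) {
        cls <- "gene_proximal"; dist <- as.integer(ng$distance)
        feat <- as.character(gene_r$ID[ng$idx])
        fstrand <- as.character(BiocGenerics::strand(gene_r)[ng$idx])
      } else if (!is.null(tes) && length(tes) > 0L) {
        nt <- nearest_info(tes)
        if (!is.null(nt) && nt$distance <= proximity_window) {
          cls <- "TE_adjacent"; dist <- as.integer(nt$distance)
          feat <- if (!is.null(tes$name)) as.character(tes$name[nt$idx])
                  else NA_character_
          fstrand <- as.character(BiocGenerics::strand(tes)[nt$idx])
        }
      }
    }
    out[[i]] <- data.frame(insertion_id = gr$insertion_id[i],
                           context_class = cls, feature_id = feat,
                           distance = dist, feature_strand = fstrand,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
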