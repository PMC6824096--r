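#' Build a gene model from GFF3-style features
#'
#' Extracts the exon and CDS spans of one gene from a feature `GRanges`
#' (as produced by [generate_reference()] or `rtracklayer::import` of a
#' GFF3 file) and converts them to the package's internal 0-based
#' half-open convention.  Validates that exons are ordered and
#' non-overlapping, that the CDS lies within exons, and that the
#' reference CDS length is a multiple of 3.
#'
#' @param genes Feature `GRanges` with `type` and `ID` columns.
#' @param gene_id Gene identifier (matched against exon/CDS `ID`
#'   prefixes or `Parent`s).
#' @return A list of class `gene_model`: `gene_id`, `chromosome`,
#'   `strand`, `exons` (matrix with `start`, `end` columns, 0-based
#'   half-open), `cds` (same shape).
#' @export
as_gene_model <- function(genes, gene_id) {
  type <- as.character(genes$type)
  ids <- as.character(genes$ID)
  sel <- startsWith(ids, gene_id)
  if (!any(sel)) stop("gene_id not found in annotation", call. = FALSE)
  pick <- function(what) {
    g <- genes[sel & type == what]
    g <- g[order(BiocGenerics::start(g))]
    cbind(start = BiocGenerics::start(g) - 1L, end = BiocGenerics::end(g))
  }
  exons <- pick("exon")
  cds <- pick("CDS")
  if (nrow(exons) == 0L) stop("gene has no exon features", call. = FALSE)
  if (any(diff(as.vector(t(exons))) < 0))
    stop("exons overlap or are unordered", call. = FALSE)
  for (i in seq_len(nrow(cds))) {
    inside <- any(cds[i, "start"] >= exons[, "start"] &
                  cds[i, "end"] <= exons[, "end"])
    if (!inside) stop("CDS outside exons", call. = FALSE)
  }
  if (nrow(cds) > 0L && sum(cds[, "end"] - cds[, "start"]) %% 3L != 0L)
    stop("reference CDS length not a multiple of 3", call. = FALSE)
  gidx <- which(sel & type == "gene")[1L]
  structure(list(gene_id = gene_id,
                 chromosome = as.character(
                   GenomeInfoDb::seqnames(genes)[gidx]),
                 strand = as.character(BiocGenerics::strand(genes)[gidx]),
                 exons = exons, cds = cds),
            class = "gene_model")
}

#' Recover the ancestral (empty-site) allele of the simulated host gene
#'
#' The simulated reference genome carries the element inside exon 6 of
#' its host gene, so its annotated gene is the insertion-bearing allele.
#' This helper excises the inserted segment (element plus one target-site
#' copy) from the chromosome, leaving a single copy of the target site,
#' and returns the reference-allele gene model with coordinates on that
#' ancestral chromosome -- the natural starting point for
#' [splice_transcript()] and [orf_report()], where the insertion allele
#' is reconstructed on demand with [insertion_allele()].
#'
#' @param reference A `mite_reference` from [generate_reference()].
#' @return A list: `genome` (named character vector with the ancestral
#'   chromosome), `gene` (a `gene_model`), `insertion_position` (0-based
#'   target-site offset on the ancestral chromosome), `element`,
#'   `tsd_length`.
#' @export
ancestral_gene <- function(reference) {
  stopifnot(inherits(reference, "mite_reference"))
  tr <- reference$truth[reference$truth$exonic, , drop = FALSE]
  if (nrow(tr) != 1L)
    stop("reference does not carry exactly one exonic copy", call. = FALSE)
  tsd <- reference$config$tsd_length
  el_len <- tr$element_end - tr$element_start
  cut_lo <- tr$insert_position + tsd
  cut_hi <- cut_lo + el_len + tsd
  grow <- el_len + tsd
  chrom <- reference$genome[[tr$chromosome]]
  anc <- paste0(.substr0(chrom, 0L, cut_lo),
                .substr0(chrom, cut_hi, nchar(chrom)))
  genome <- reference$genome
  genome[[tr$chromosome]] <- anc

  shift <- function(spans) {
    spans[, "start"] <- spans[, "start"] -
      ifelse(spans[, "start"] >= cut_hi, grow, 0L)
    spans[, "end"] <- spans[, "end"] -
      ifelse(spans[, "end"] >= cut_hi, grow, 0L)
    spans
  }
  gm <- as_gene_model_unchecked(reference$genes, reference$gene_id)
  gm$exons <- shift(gm$exons)
  gm$cds <- shift(gm$cds)
  ## re-validate the ancestral model
  stopifnot(sum(gm$cds[, "end"] - gm$cds[, "start"]) %% 3L == 0L)
  list(genome = genome, gene = gm,
       insertion_position = tr$insert_position,
       element = reference$element, tsd_length = tsd)
}

## gene model extraction without the reference-allele CDS/3 check
as_gene_model_unchecked <- function(genes, gene_id) {
  type <- as.character(genes$type)
  ids <- as.character(genes$ID)
  sel <- startsWith(ids, gene_id)
  pick <- function(what) {
    g <- genes[sel & type == what]
    g <- g[order(BiocGenerics::start(g))]
    cbind(start = BiocGenerics::start(g) - 1L, end = BiocGenerics::end(g))
  }
  gidx <- which(sel & type == "gene")[1L]
  structure(list(gene_id = gene_id,
                 chromosome = as.character(
                   GenomeInfoDb::seqnames(genes)[gidx]),
                 strand = as.character(BiocGenerics::strand(genes)[gidx]),
                 exons = pick("exon"), cds = pick("CDS")),
            class = "gene_model")
}

#' Describe an insertion allele for transcript reconstruction
#'
#' @param position 0-based genomic offset of the target site.
#' @param element Element sequence (ACGT string).
#' @param tsd_length Target-site duplication length in bp (default 9).
#' @return A list of class `allele_spec`.
#' @export
insertion_allele <- function(position, element, tsd_length = 9L) {
  structure(list(type = "with_insertion", position = as.integer(position),
                 element = .check_dna(element),
                 tsd_length = as.integer(tsd_length)),
            class = "allele_spec")
}

#' Reference allele marker
#' @return A list of class `allele_spec`.
#' @export
reference_allele <- function() {
  structure(list(type = "reference"), class = "allele_spec")
}

#' Splice-aware transcript reconstruction
#'
#' Builds the mature mRNA of a gene by concatenating its exon sequences
#' (reverse-complemented for minus-strand genes).  For an insertion
#' allele the element is planted at the given exonic position with its
#' target-site duplication; the exonic insertion is retained in the
#' mature mRNA, which therefore grows by element length + TSD length
#' exactly.  An insertion whose duplicated target site would span a
#' splice junction is an unsupported case and raises an error.
#'
#' @param gene A `gene_model` from [as_gene_model()].
#' @param genome Named character vector, `DNAStringSet`, or FASTA path.
#' @param allele [reference_allele()] or [insertion_allele()].
#' @return The mRNA as a character string, with attributes
#'   `element_span` and `inserted_span` (0-based half-open transcript
#'   coordinates; `inserted_span` covers the novel nucleotides, i.e.
#'   element plus one extra target-site copy) for insertion alleles.
#' @export
splice_transcript <- function(gene, genome, allele = reference_allele()) {
  stopifnot(inherits(gene, "gene_model"), inherits(allele, "allele_spec"))
  genome <- .as_genome(genome)
  chrom <- genome[[gene$chromosome]]
  exons <- gene$exons
  element_span <- inserted_span <- NULL
  if (allele$type == "with_insertion") {
    p <- allele$position
    t <- allele$tsd_length
    el_len <- nchar(allele$element)
    exon_idx <- which(exons[, "start"] <= p & p + t <= exons[, "end"])
    if (length(exon_idx) == 0L)
      stop("insertion target site spans a splice junction or lies ",
           "outside exons: unsupported case", call. = FALSE)
    exon_idx <- exon_idx[1L]
    chrom <- plant_insertion(chrom, allele$element, p, t)$sequence
    grow <- el_len + t
    exons[exon_idx, "end"] <- exons[exon_idx, "end"] + grow
    after <- seq_len(nrow(exons)) > exon_idx
    exons[after, ] <- exons[after, , drop = FALSE] + grow
    ## transcript offset of the target site
    prior <- if (exon_idx > 1L)
      sum(gene$exons[seq_len(exon_idx - 1L), "end"] -
          gene$exons[seq_len(exon_idx - 1L), "start"]) else 0L
    m_p <- unname(prior + (p - gene$exons[exon_idx, "start"]))
    element_span <- c(m_p + t, m_p + t + el_len)
    inserted_span <- c(m_p + t, m_p + 2L * t + el_len)
  }
  parts <- vapply(seq_len(nrow(exons)), function(i)
    .substr0(chrom, exons[i, "start"], exons[i, "end"]), character(1))
  mrna <- paste(parts, collapse = "")
  if (gene$strand == "-") {
    L <- nchar(mrna)
    if (!is.null(element_span)) {
      element_span <- c(L - element_span[2], L - element_span[1])
      inserted_span <- c(L - inserted_span[2], L - inserted_span[1])
    }
    mrna <- revcomp(mrna)
  }
  attr(mrna, "element_span") <- element_span
  attr(mrna, "inserted_span") <- inserted_span
  mrna
}

.first_stop <- function(mrna, cds_start_offset) {
  cds <- .substr0(mrna, cds_start_offset, nchar(mrna))
  cds <- substr(cds, 1L, (nchar(cds) %/% 3L) * 3L)
  if (nchar(cds) < 3L) return(list(aa = 0L, stop = NA_integer_))
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           no.init.codon = TRUE))
  k <- regexpr("*", aa, fixed = TRUE)
  if (k < 0) return(list(aa = nchar(aa), stop = NA_integer_))
  ## transcript 0-based end of the stop codon
  list(aa = as.integer(k) - 1L,
       stop = cds_start_offset + 3L * as.integer(k))
}

#' ORF truncation report for an insertion-bearing transcript
#'
#' Translates an insertion-allele mRNA from its CDS start, locates the
#' first in-frame stop codon, and compares the protein to the reference
#' allele (the same transcript with the inserted segment excised).  When
#' the premature stop falls inside the element, its position is reported
#' 1-based within the element's nucleotides (the position of the stop
#' codon's final base).
#'
#' @param mrna Insertion-allele mRNA, e.g. from [splice_transcript()]
#'   (its `element_span`/`inserted_span` attributes are used as
#'   defaults).
#' @param cds_start_offset 0-based transcript offset of the CDS start.
#' @param element_span,inserted_span 0-based half-open transcript spans
#'   of the element and of the full novel segment (element plus one
#'   target-site copy); `NULL` for a reference-only report.
#' @return A list of class `orf_report`: `allele`, `transcript_length`,
#'   `premature_stop`, `stop_position_in_insertion`,
#'   `protein_length_reference`, `protein_length_insertion`,
#'   `lost_cds_fraction`, `non_stop` (no stop before transcript end).
#' @export
orf_report <- function(mrna, cds_start_offset,
                       element_span = attr(mrna, "element_span"),
                       inserted_span = attr(mrna, "inserted_span")) {
  mrna_chr <- as.character(mrna)
  ins <- .first_stop(mrna_chr, cds_start_offset)
  if (is.null(inserted_span)) {
    return(structure(list(allele = "reference",
                          transcript_length = nchar(mrna_chr),
                          premature_stop = FALSE,
                          stop_position_in_insertion = NA_integer_,
                          protein_length_reference = ins$aa,
                          protein_length_insertion = NA_integer_,
                          lost_cds_fraction = 0,
                          non_stop = is.na(ins$stop)),
                     class = "orf_report"))
  }
  ref_mrna <- paste0(.substr0(mrna_chr, 0L, inserted_span[1]),
                     .substr0(mrna_chr, inserted_span[2], nchar(mrna_chr)))
  ref <- .first_stop(ref_mrna, cds_start_offset)
  stop_in_el <- !is.na(ins$stop) && !is.null(element_span) &&
    ins$stop > element_span[1] && ins$stop <= element_span[2]
  premature <- !is.na(ins$stop) && ins$aa < ref$aa
  structure(list(allele = "with_insertion",
                 transcript_length = nchar(mrna_chr),
                 premature_stop = premature,
                 stop_position_in_insertion = if (stop_in_el)
                   ins$stop - element_span[1] else NA_integer_,
                 protein_length_reference = ref$aa,
                 protein_length_insertion = ins$aa,
                 lost_cds_fraction = if (ref$aa > 0)
                   max(0, 1 - ins$aa / ref$aa) else NA_real_,
                 non_stop = is.na(ins$stop)),
            class = "orf_report")
}

#' qPCR primer efficiency from a standard-curve slope
#'
#' `E = ((10^(-1/y)) - 1) * 100` percent, where `y` is the slope of CT
#' against log10 template amount.  A slope of `-1/log10(2) = -3.3219`
#' corresponds to perfect doubling (100%).
#'
#' @param slope Standard-curve slope (nonzero).
#' @return Efficiency in percent.
#' @export
primer_efficiency <- function(slope) {
  if (!is.finite(slope) || slope == 0) stop("slope must be nonzero",
                                            call. = FALSE)
  ((10^(-1 / slope)) - 1) * 100
}

#' Relative expression by the comparative 2^-ddCt method
#'
#' `RQ = 2^-[(CTtarget - CTcontrol)_sample - (CTtarget - CTcontrol)_calibrator]`,
#' normalizing the target gene to an endogenous control and to a
#' calibrator accession (whose RQ is exactly 1).  Rows with missing CT
#' values are excluded with a warning.  Adding a constant to every CT
#' leaves RQ unchanged.
#'
#' @param ct Data.frame with columns `accession`, `ct_target`,
#'   `ct_control` and optionally `group` (as from
#'   [generate_ct_table()]).
#' @param calibrator Accession id of the calibrator; defaults to the
#'   accession flagged `is_calibrator`, else the first row.
#' @return The input data.frame (complete rows) with `dct` and `rq`
#'   columns appended.
#' @export
relative_expression <- function(ct, calibrator = NULL) {
  stopifnot(all(c("accession", "ct_target", "ct_control") %in% names(ct)))
  bad <- !is.finite(ct$ct_target) | !is.finite(ct$ct_control)
  if (any(bad)) {
    warning(sum(bad), " row(s) with missing CT excluded", call. = FALSE)
    ct <- ct[!bad, , drop = FALSE]
  }
  if (is.null(calibrator)) {
    calibrator <- if (!is.null(ct$is_calibrator) && any(ct$is_calibrator))
      ct$accession[ct$is_calibrator][1L] else ct$accession[1L]
  }
  if (!calibrator %in% ct$accession)
    stop("calibrator accession not present", call. = FALSE)
  ct$dct <- ct$ct_target - ct$ct_control
  ddct <- ct$dct - ct$dct[ct$accession == calibrator][1L]
  ct$rq <- 2^(-ddct)
  ct
}

#' One-way ANOVA with Tukey HSD on relative expression
#'
#' Fits `rq ~ group` by one-way ANOVA and runs Tukey's honestly
#' significant difference test on the group means.  Groups with a single
#' observation are excluded with a warning.
#'
#' @param rq Numeric response (e.g. the `rq` column from
#'   [relative_expression()]).
#' @param group Grouping factor (e.g. population).
#' @return A list of class `anova_tukey`: `F`, `p_value`, `df`, `tukey`
#'   (data.frame: `contrast`, `diff`, `lwr`, `upr`, `p_adj`), `fit`.
#' @export
anova_tukey <- function(rq, group) {
  group <- as.factor(group)
  counts <- table(group)
  if (any(counts < 2L)) {
    drop <- names(counts)[counts < 2L]
    warning("group(s) with a single observation excluded: ",
            paste(drop, collapse = ", "), call. = FALSE)
    keep <- !(group %in% drop)
    rq <- rq[keep]; group <- droplevels(group[keep])
  }
  if (nlevels(group) < 2L) stop("need at least 2 groups", call. = FALSE)
  fit <- stats::aov(rq ~ group)
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(contrast = rownames(tk),
                      diff = tk[, "diff"], lwr = tk[, "lwr"],
                      upr = tk[, "upr"], p_adj = tk[, "p adj"],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(F = an[["F value"]][1L],
                 p_value = an[["Pr(>F)"]][1L],
                 df = c(an[["Df"]][1L], an[["Df"]][2L]),
                 tukey = tukey, fit = fit),
            class = "anova_tukey")
}
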