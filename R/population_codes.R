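#' Published population codes for the Mariam insertion survey
#'
#' The published site-specific-PCR summary of Mariam insertional
#' polymorphism: 11 insertion loci scored across five wild emmer
#' populations (Mt. Hermon, Amiad, Tabgha, Jaba, Mt. Amasa; 9 accessions
#' each) and a panel of 8 bread wheat accessions, coded per population as
#' 0 (empty site in all accessions), 1 (full site in some accessions) or
#' 2 (full site in all accessions).  Locus `A2-MH` is the index insertion
#' first found in two Mt. Hermon accessions.
#'
#' @return An 11 x 6 integer matrix; rownames are locus ids, colnames
#'   `MtHermon`, `Amiad`, `Tabgha`, `Jaba`, `MtAmasa`, `BreadWheat`.
#' @export
emmer_population_codes <- function() {
  codes <- rbind(
    "A2-MH" = c(1, 0, 0, 0, 0, 0),
    "A4-1"  = c(0, 1, 1, 0, 0, 1),
    "A4-4"  = c(1, 1, 1, 1, 1, 0),
    "A5-6"  = c(2, 2, 2, 2, 2, 2),
    "A6-2"  = c(0, 1, 1, 0, 0, 0),
    "A7-5"  = c(0, 1, 1, 0, 1, 0),
    "B1-2"  = c(0, 0, 0, 0, 0, 2),
    "B1-4"  = c(1, 1, 2, 1, 1, 1),
    "B3-4"  = c(0, 1, 1, 0, 0, 0),
    "B7-4"  = c(0, 1, 1, 1, 0, 0),
    "B7-6"  = c(0, 1, 1, 0, 0, 0))
  storage.mode(codes) <- "integer"
  colnames(codes) <- c("MtHermon", "Amiad", "Tabgha", "Jaba", "MtAmasa",
                       "BreadWheat")
  codes
}

#' Summarize a locus x population 0/1/2 code matrix
#'
#' Tallies the patterns of an insertional-polymorphism code matrix whose
#' last column is an outgroup panel (e.g. bread wheat): loci fixed
#' present (code 2) in every column, and loci absent from the outgroup
#' (code 0) yet polymorphic (code 1) in at least `min_poly_pops` of the
#' in-group populations, optionally excluding an index locus that is
#' described separately.
#'
#' @param codes Integer matrix of 0/1/2 codes, loci as rows; the last
#'   column is treated as the outgroup panel.
#' @param exclude Locus ids (rownames) excluded from the
#'   outgroup-absent tally (default none).
#' @param min_poly_pops Minimum number of in-group populations with code
#'   1 (default 2).
#' @return A list: `n_fixed_present`, `fixed_present` (locus ids),
#'   `n_outgroup_absent_polymorphic`, `outgroup_absent_polymorphic`
#'   (locus ids).
#' @export
summarize_population_codes <- function(codes, exclude = character(0),
                                       min_poly_pops = 2L) {
  codes <- as.matrix(codes)
  if (!all(codes %in% 0:2)) stop("codes must be 0, 1 or 2", call. = FALSE)
  if (is.null(rownames(codes)))
    rownames(codes) <- sprintf("L%02d", seq_len(nrow(codes)))
  ingroup <- codes[, -ncol(codes), drop = FALSE]
  outgroup <- codes[, ncol(codes)]
  fixed <- rownames(codes)[apply(codes == 2L, 1, all)]
  cand <- outgroup == 0L &
    rowSums(ingroup == 1L) >= min_poly_pops &
    !(rownames(codes) %in% exclude)
  list(n_fixed_present = length(fixed),
       fixed_present = fixed,
       n_outgroup_absent_polymorphic = sum(cand),
       outgroup_absent_polymorphic = rownames(codes)[cand])
}
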