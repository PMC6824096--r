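#' In-silico PCR
#'
#' Reports every amplicon a primer pair would produce from a template:
#' each forward-primer match paired with each downstream reverse-primer
#' site (the reverse complement of the reverse primer) within
#' `max_product_size`, in both template orientations.  Product length
#' includes both primers.  Primer matching is exact by default; with
#' `max_mismatch > 0` mismatches are tolerated anywhere except the three
#' 3'-terminal bases of each primer.
#'
#' @param template Template sequence (ACGT string).
#' @param forward,reverse Primers, both written 5'->3' on their own
#'   strands (the reverse primer on the opposite strand), >= 15 bp.
#' @param max_mismatch Mismatches tolerated per primer (default 0).
#' @param max_product_size Maximum amplicon size in bp (default 5000).
#' @return A data.frame with one row per product: `start`, `end` (0-based
#'   half-open on the template), `length`, `orientation` (`"fwd"` when the
#'   forward primer is on the given strand, `"rev"` otherwise).  Zero rows
#'   when the primers do not amplify.
#' @export
insilico_pcr <- function(template, forward, reverse, max_mismatch = 0L,
                         max_product_size = 5000L) {
  template <- .check_dna(template)
  forward <- .check_dna(forward)
  reverse <- .check_dna(reverse)
  if (nchar(forward) < 15L || nchar(reverse) < 15L)
    stop("primers must be at least 15 bp", call. = FALSE)
  subj <- Biostrings::DNAString(template)

  match_sites <- function(primer) {
    ## primer annealing sites on the plus strand, 3'-anchored
    hits <- Biostrings::matchPattern(Biostrings::DNAString(primer), subj,
                                     max.mismatch = max_mismatch)
    if (max_mismatch > 0L && length(hits) > 0L) {
      anchor <- substr(primer, nchar(primer) - 2L, nchar(primer))
      ok <- vapply(seq_along(hits), function(i) {
        s <- as.character(hits[[i]])
        substr(s, nchar(s) - 2L, nchar(s)) == anchor
      }, logical(1))
      hits <- hits[ok]
    }
    hits
  }
  products <- function(fwd, rev, orientation) {
    f <- match_sites(fwd)
    r_rc <- revcomp(rev)
    r <- Biostrings::matchPattern(Biostrings::DNAString(r_rc), subj,
                                  max.mismatch = max_mismatch)
    if (max_mismatch > 0L && length(r) > 0L) {
      ## 3' end of the reverse primer maps to the start of its rc site
      anchor <- substr(r_rc, 1L, 3L)
      ok <- vapply(seq_along(r), function(i)
        substr(as.character(r[[i]]), 1L, 3L) == anchor, logical(1))
      r <- r[ok]
    }
    if (length(f) == 0L || length(r) == 0L) return(NULL)
    out <- list()
    for (i in seq_along(f)) {
      fs <- IRanges::start(f)[i] - 1L
      for (j in seq_along(r)) {
        re <- IRanges::end(r)[j]
        len <- re - fs
        if (re > fs + nchar(fwd) && len <= max_product_size)
          out[[length(out) + 1L]] <- data.frame(
            start = fs, end = re, length = len,
            orientation = orientation, stringsAsFactors = FALSE)
      }
    }
    if (length(out) == 0L) NULL else do.call(rbind, out)
  }
  res <- rbind(products(forward, reverse, "fwd"),
               products(reverse, forward, "rev"))
  if (is.null(res))
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), orientation = character(0),
                      stringsAsFactors = FALSE))
  res <- unique(res)
  res[order(res$start, res$end), , drop = FALSE]
}

#' Score a locus across accessions and summarize per population
#'
#' Converts per-accession amplicon lengths into binary full/empty calls
#' (1 when a product matches the expected full-site size within `tol`,
#' 0 when it matches the empty-site size) and summarizes each population
#' with the standard 0/1/2 code: 0 when the site is empty in every
#' accession, 2 when full in every accession, 1 otherwise.  Accessions
#' whose products match neither size are flagged unscored and excluded
#' from the codes.
#'
#' @param amplicons Named list, one element per accession, each a numeric
#'   vector of product lengths (possibly empty).
#' @param expected_full,expected_empty Expected amplicon sizes in bp;
#'   must differ by more than `2 * tol`.
#' @param tol Size-matching tolerance in bp (default 10).
#' @param populations Named character vector mapping accession ->
#'   population; when `NULL` all accessions form one population.
#' @return A list: `calls` (named integer vector, NA = unscored),
#'   `unscored` (accession ids), `codes` (named integer vector of 0/1/2
#'   per population).
#' @export
score_locus <- function(amplicons, expected_full, expected_empty,
                        tol = 10L, populations = NULL) {
  if (abs(expected_full - expected_empty) <= 2L * tol)
    stop("expected sizes must differ by more than 2 * tol", call. = FALSE)
  acc <- names(amplicons)
  if (is.null(acc)) acc <- sprintf("acc%d", seq_along(amplicons))
  calls <- vapply(amplicons, function(lens) {
    if (length(lens) == 0L) return(NA_integer_)
    if (any(abs(lens - expected_full) <= tol)) return(1L)
    if (any(abs(lens - expected_empty) <= tol)) return(0L)
    NA_integer_
  }, integer(1))
  names(calls) <- acc
  if (is.null(populations)) {
    populations <- rep("all", length(acc))
    names(populations) <- acc
  }
  pops <- unique(populations[acc])
  codes <- vapply(pops, function(p) {
    v <- calls[acc[populations[acc] == p]]
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(NA_integer_)
    if (all(v == 1L)) return(2L)
    if (all(v == 0L)) return(0L)
    1L
  }, integer(1))
  names(codes) <- pops
  list(calls = calls, unscored = acc[is.na(calls)], codes = codes)
}

#' Score a whole accession panel by in-silico PCR
#'
#' Runs [insilico_pcr()] for every locus of a primer panel against every
#' accession's locus sequences and assembles the loci x accessions
#' presence/absence matrix plus per-population 0/1/2 codes.
#'
#' @param panel A `mite_panel` from [generate_accession_panel()].
#' @param primers Primer panel data.frame from [panel_primers()]
#'   (`locus_id`, `forward`, `reverse`, `expected_full`,
#'   `expected_empty`).
#' @param tol Size tolerance in bp (default 10).
#' @return A list: `matrix` (loci x accessions 0/1, NA = unscored),
#'   `codes` (loci x populations 0/1/2), `populations`.
#' @export
score_panel <- function(panel, primers, tol = 10L) {
  stopifnot(inherits(panel, "mite_panel"))
  acc <- names(panel$sequences)
  mat <- matrix(NA_integer_, nrow(primers), length(acc),
                dimnames = list(primers$locus_id, acc))
  codes <- NULL
  for (l in seq_len(nrow(primers))) {
    locus <- primers$locus_id[l]
    amps <- lapply(acc, function(a) {
      tmpl <- panel$sequences[[a]][[locus]]
      if (is.null(tmpl)) return(numeric(0))
      insilico_pcr(tmpl, primers$forward[l], primers$reverse[l])$length
    })
    names(amps) <- acc
    sc <- score_locus(amps, primers$expected_full[l],
                      primers$expected_empty[l], tol = tol,
                      populations = panel$populations)
    mat[l, ] <- sc$calls[acc]
    codes <- rbind(codes, sc$codes)
  }
  rownames(codes) <- primers$locus_id
  list(matrix = mat, codes = codes, populations = panel$populations)
}

#' Bray-Curtis dissimilarity between accessions
#'
#' `d(i, j) = sum |x_ik - x_jk| / sum (x_ik + x_jk)` over loci.  On
#' binary presence/absence data this equals one minus the Sorensen
#' similarity.  A pair of all-zero accessions has no shared support; its
#' dissimilarity is defined as 1 and a warning is raised.
#'
#' @param x Accessions x loci numeric matrix (accessions as rows).
#' @return A symmetric accession x accession matrix with zero diagonal.
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 accessions", call. = FALSE)
  ## vegdist flags empty rows itself; the all-zero convention is defined
  ## below, so only the package's own warning is surfaced
  d <- withCallingHandlers(
    as.matrix(vegan::vegdist(x, method = "bray")),
    warning = function(w) {
      if (grepl("empty rows|missing values", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (any(is.nan(d))) {
    warning("accession pair(s) with all-zero profiles; dissimilarity set to 1",
            call. = FALSE)
    d[is.nan(d)] <- 1
  }
  diag(d) <- 0
  d
}

#' Agglomerative clustering of accessions
#'
#' Group-average (UPGMA) hierarchical clustering of a dissimilarity
#' matrix, with deterministic tie-breaking by lowest accession index
#' (the ordering `stats::hclust` applies to equal-height merges).
#'
#' @param d Symmetric dissimilarity matrix (e.g. from [bray_curtis()]).
#' @param method Linkage passed to `stats::hclust` (default
#'   `"average"`).
#' @return An `hclust` object.
#' @export
cluster_accessions <- function(d, method = "average") {
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("dissimilarity matrix must be symmetric", call. = FALSE)
  stats::hclust(stats::as.dist(d), method = method)
}
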