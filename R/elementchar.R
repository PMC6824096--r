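#' Detect a target-site duplication in the flanks of an insertion
#'
#' Searches for the longest k-mer, `k_min <= k <= k_max`, that occurs as
#' a suffix of the upstream flank and a prefix of the downstream flank
#' with at most `max_mismatch` mismatches, each copy starting within
#' `boundary_slack` bp of the element boundary.  Ties are broken toward
#' fewer mismatches, then smaller total offset from the boundaries.
#' The strict default (`max_mismatch = 0`, k in 8..12, slack 2 bp)
#' reproduces a binary clear/absent TSD call.
#'
#' @param upstream_flank,downstream_flank Sequences immediately 5' and 3'
#'   of the element (genome strand; the element boundary is the end of
#'   `upstream_flank` and the start of `downstream_flank`).
#' @param k_min,k_max TSD length range searched (bp).
#' @param max_mismatch Maximum mismatches tolerated between the two
#'   copies.
#' @param boundary_slack Maximum distance (bp) of each copy from the
#'   element boundary.
#' @return A list of class `tsd_call`: `found`, `tsd_length`,
#'   `tsd_upstream`, `tsd_downstream`, `mismatches`, `offsets`
#'   (upstream, downstream distance from the boundary), `reason` when not
#'   found.
#' @export
detect_tsd <- function(upstream_flank, downstream_flank,
                       k_min = 8L, k_max = 12L, max_mismatch = 0L,
                       boundary_slack = 2L) {
  upstream_flank <- .check_dna(upstream_flank)
  downstream_flank <- .check_dna(downstream_flank)
  if (k_min > k_max) stop("k_min must be <= k_max", call. = FALSE)
  not_found <- function(reason)
    structure(list(found = FALSE, tsd_length = NA_integer_,
                   tsd_upstream = NA_character_,
                   tsd_downstream = NA_character_,
                   mismatches = NA_integer_, offsets = c(NA_integer_,
                                                         NA_integer_),
                   reason = reason), class = "tsd_call")
  if (nchar(upstream_flank) < k_min || nchar(downstream_flank) < k_min)
    return(not_found("flank shorter than k_min"))
  ulen <- nchar(upstream_flank)
  best <- NULL
  for (k in seq(min(k_max, nchar(upstream_flank), nchar(downstream_flank)),
                k_min)) {
    for (off_u in 0:boundary_slack) {
      if (ulen - off_u - k < 0) next
      up <- .substr0(upstream_flank, ulen - off_u - k, ulen - off_u)
      for (off_d in 0:boundary_slack) {
        if (off_d + k > nchar(downstream_flank)) next
        down <- .substr0(downstream_flank, off_d, off_d + k)
        mm <- sum(strsplit(up, "")[[1]] != strsplit(down, "")[[1]])
        if (mm > max_mismatch) next
        cand <- list(k = k, mm = mm, off = c(off_u, off_d),
                     up = up, down = down)
        if (is.null(best) ||
            cand$mm < best$mm ||
            (cand$mm == best$mm && sum(cand$off) < sum(best$off)))
          best <- cand
      }
    }
    if (!is.null(best)) break  # longest k wins; ties resolved within k
  }
  if (is.null(best)) return(not_found("no matching duplication"))
  structure(list(found = TRUE, tsd_length = best$k,
                 tsd_upstream = best$up, tsd_downstream = best$down,
                 mismatches = best$mm, offsets = best$off, reason = NA),
            class = "tsd_call")
}

#' Detect terminal inverted repeats
#'
#' Aligns the element's 5' terminal window against the reverse complement
#' of its 3' terminal window (local alignment, +1/-2 scoring) and calls a
#' TIR when the best match is at least `min_tir` bp long with identity at
#' least `min_identity` percent.
#'
#' @param element Element sequence, length >= `2 * min_tir`.
#' @param min_tir Minimum TIR length (bp, default 10).
#' @param max_window Terminal window scanned at each end (bp, default 30).
#' @param min_identity Minimum percent identity (default 80).
#' @return A list of class `tir_call`: `found`, `tir_length`, `identity`,
#'   `arm5`, `arm3`.
#' @export
detect_tir <- function(element, min_tir = 10L, max_window = 30L,
                       min_identity = 80) {
  element <- .check_dna(element)
  if (nchar(element) < 2L * min_tir)
    stop("element too short for TIR detection", call. = FALSE)
  w <- min(max_window, nchar(element) %/% 2L)
  left <- Biostrings::DNAString(substr(element, 1L, w))
  right <- Biostrings::reverseComplement(
    Biostrings::DNAString(substr(element, nchar(element) - w + 1L,
                                 nchar(element))))
  aln <- Biostrings::pairwiseAlignment(left, right, type = "local",
                                       substitutionMatrix = .submat(),
                                       gapOpening = 5, gapExtension = 2)
  arm5 <- as.character(Biostrings::alignedPattern(aln))
  len <- nchar(arm5)  # alignment columns, including internal gaps
  idy <- if (len > 0) Biostrings::pid(aln, type = "PID1") else 0
  found <- len >= min_tir && idy >= min_identity
  structure(list(found = found,
                 tir_length = len,
                 identity = idy,
                 arm5 = arm5,
                 arm3 = as.character(Biostrings::alignedSubject(aln))),
            class = "tir_call")
}

#' Screen an element for SINE hallmarks
#'
#' Looks for a 3' poly-A tail (a run of at least `polya_min` adenines
#' with at most one interruption inside the 3'-terminal `tail_window`
#' bp) and an internal RNA Pol-III promoter: an A-box (consensus
#' `TRGCNNARYNNG`, <= 2 mismatches) and a B-box (consensus `GTTCGANNC`,
#' <= 1 mismatch) in the 5' half, 25-75 bp apart.
#'
#' @param element Element sequence (non-empty).
#' @param polya_min Minimum adenine count in the tail run (default 8).
#' @param tail_window 3' window searched for the tail (bp, default 20).
#' @return A list of class `sine_report`: `polyA_found`, `polyA_position`
#'   (1-based start of the run, or NA), `a_box_found`, `a_box_position`,
#'   `b_box_found`, `b_box_position`, `pol3_promoter` (both boxes with
#'   proper spacing).
#' @export
sine_features <- function(element, polya_min = 8L, tail_window = 20L) {
  element <- .check_dna(element)
  n <- nchar(element)
  ## poly-A: window of polya_min+1 with <= 1 non-A inside the 3' tail
  tail0 <- max(0L, n - tail_window)
  tail_seq <- strsplit(.substr0(element, tail0, n), "")[[1]]
  polyA_found <- FALSE; polyA_pos <- NA_integer_
  if (length(tail_seq) >= polya_min) {
    ## windows with >= polya_min adenines and <= 1 interruption
    for (w_len in c(polya_min, polya_min + 1L)) {
      if (w_len > length(tail_seq)) next
      for (i in seq_len(length(tail_seq) - w_len + 1L)) {
        w <- tail_seq[i:(i + w_len - 1L)]
        if (sum(w == "A") >= polya_min && sum(w != "A") <= 1L &&
            w[1] == "A" && w[w_len] == "A") {
          polyA_found <- TRUE
          polyA_pos <- tail0 + i
          break
        }
      }
      if (polyA_found) break
    }
  }
  ## Pol-III internal promoter boxes in the 5' half
  half <- Biostrings::DNAString(substr(element, 1L, max(12L, n %/% 2L)))
  a_hits <- Biostrings::matchPattern(Biostrings::DNAString("TRGCNNARYNNG"),
                                     half, max.mismatch = 2, fixed = FALSE)
  b_hits <- Biostrings::matchPattern(Biostrings::DNAString("GTTCGANNC"),
                                     half, max.mismatch = 1, fixed = FALSE)
  a_found <- length(a_hits) > 0L
  b_found <- length(b_hits) > 0L
  a_pos <- if (a_found) IRanges::start(a_hits)[1L] else NA_integer_
  b_pos <- if (b_found) IRanges::start(b_hits)[1L] else NA_integer_
  pol3 <- FALSE
  if (a_found && b_found) {
    gaps <- outer(IRanges::start(b_hits), IRanges::end(a_hits), "-") - 1L
    pol3 <- any(gaps >= 25L & gaps <= 75L)
  }
  structure(list(polyA_found = polyA_found, polyA_position = polyA_pos,
                 a_box_found = a_found, a_box_position = a_pos,
                 b_box_found = b_found, b_box_position = b_pos,
                 pol3_promoter = pol3),
            class = "sine_report")
}

#' Position frequency matrix and information content of aligned sites
#'
#' Builds a per-position nucleotide frequency matrix from equal-length
#' aligned target sites (e.g. the TSD 9-mers of a set of insertions) and
#' the per-position information content `IC = 2 - H` bits, optionally
#' with the small-sample correction `e(n) = 3 / (2 ln 2 n)` subtracted.
#'
#' @param sites Character vector (>= 2) of equal-length ACGT strings.
#' @param small_sample_correction Subtract the small-sample correction
#'   from every column's IC (clamped at 0)?  Default `FALSE`.
#' @return A list of class `logo_matrix`: `freq` (4 x L matrix, columns
#'   sum to 1), `ic` (length-L numeric, bits), `n_sequences`,
#'   `correction` (the value subtracted, 0 if disabled).
#' @export
flank_logo <- function(sites, small_sample_correction = FALSE) {
  if (length(sites) < 2L) stop("need at least 2 sequences", call. = FALSE)
  sites <- vapply(sites, .check_dna, character(1), arg = "sites")
  L <- unique(nchar(sites))
  if (length(L) != 1L) stop("sequences must have equal length", call. = FALSE)
  m <- do.call(rbind, strsplit(sites, ""))
  freq <- apply(m, 2, function(col) {
    tab <- table(factor(col, levels = c("A", "C", "G", "T")))
    as.numeric(tab) / length(col)
  })
  rownames(freq) <- c("A", "C", "G", "T")
  H <- apply(freq, 2, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  corr <- if (small_sample_correction) 3 / (2 * log(2) * length(sites)) else 0
  ic <- pmax(0, 2 - H - corr)
  structure(list(freq = freq, ic = ic, n_sequences = length(sites),
                 correction = corr),
            class = "logo_matrix")
}

#' Pairwise percent-identity matrix of element copies
#'
#' Global (Needleman-Wunsch) alignment of every pair with the package's
#' +1/-2 scoring; identity is matches over alignment columns, so gap
#' columns count as mismatches.  Reports both the mean and the minimum
#' off-diagonal identity, since "conservation over X%" may refer to
#' either.
#'
#' @param copies Character vector (>= 2) of element sequences.
#' @return A list of class `identity_matrix`: `identity` (symmetric
#'   percent matrix, diagonal 100), `mean_identity`, `min_identity`.
#' @export
pairwise_identity_matrix <- function(copies) {
  if (length(copies) < 2L) stop("need at least 2 sequences", call. = FALSE)
  copies <- vapply(copies, .check_dna, character(1), arg = "copies")
  if (any(nchar(copies) == 0L)) stop("empty sequence", call. = FALSE)
  n <- length(copies)
  idm <- matrix(100, n, n)
  submat <- .submat()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(copies[i]), Biostrings::DNAString(copies[j]),
        type = "global", substitutionMatrix = submat,
        gapOpening = 5, gapExtension = 2)
      idm[i, j] <- idm[j, i] <- Biostrings::pid(aln, type = "PID1")
    }
  }
  off <- idm[upper.tri(idm)]
  structure(list(identity = idm, mean_identity = mean(off),
                 min_identity = min(off)),
            class = "identity_matrix")
}

#' Classify an element from its structural-feature reports
#'
#' Deterministic rule table combining the TSD, TIR and SINE screens:
#' a TIR-bearing element is a TIR-superfamily candidate; a TIR-less
#' element with SINE hallmarks is a SINE candidate; a TIR-less,
#' SINE-featureless element with a 9-bp TSD is a Mutator-derived MITE
#' candidate (9-bp TSDs are the Mutator superfamily signature); anything
#' else is an unclassified miniature element.
#'
#' @param tsd A `tsd_call` from [detect_tsd()].
#' @param tir A `tir_call` from [detect_tir()].
#' @param sine A `sine_report` from [sine_features()].
#' @param length Element length in bp (reported in the rationale).
#' @return A list: `label`, `rationale`.
#' @export
classify_element <- function(tsd, tir, sine, length) {
  sine_any <- isTRUE(sine$polyA_found) || isTRUE(sine$pol3_promoter)
  if (isTRUE(tir$found)) {
    label <- "TIR-superfamily candidate (by TSD length)"
    why <- sprintf("TIR of %d bp at %.0f%% identity", tir$tir_length,
                   tir$identity)
  } else if (sine_any) {
    label <- "SINE candidate"
    why <- "no TIR; SINE hallmarks present"
  } else if (isTRUE(tsd$found) && identical(tsd$tsd_length, 9L)) {
    label <- "Mutator-derived MITE candidate (TSD only)"
    why <- sprintf("%d bp, no TIR, no SINE features, 9-bp TSD (%s)",
                   length, tsd$tsd_upstream)
  } else {
    label <- "unclassified miniature element"
    why <- sprintf("%d bp, no TIR, no SINE features, no 9-bp TSD", length)
  }
  list(label = label, rationale = why)
}
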