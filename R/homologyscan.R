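#' Homology-search parameters
#'
#' Parameters of the seeded local-alignment search used to retrieve
#' element copies from a genome: e-value cutoff, permitted unaligned
#' query length per end for the full-length call, flank length, seed word
#' size, alignment scores and Karlin-Altschul parameters.  Defaults
#' follow the retrieval protocol used for the Mariam survey (e-value
#' 1e-3, end tolerance 20 nt, 1000-bp flanks) with blastn-like +1/-2
#' scoring and its ungapped Karlin-Altschul estimates
#' (lambda = 0.625, K = 0.41).
#'
#' @param evalue_max Maximum e-value for a reported hit (> 0).
#' @param end_mismatch_tol Maximum unaligned query length (bp) permitted
#'   at each end for a hit to count as full length.
#' @param flank_length Flank length (bp) retrieved on each side.
#' @param word_size Exact-match seed length (>= 4).
#' @param match,mismatch Match/mismatch scores.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param ka_lambda,ka_K Karlin-Altschul parameters for the scoring.
#' @return A list of class `search_params`.
#' @export
search_params <- function(evalue_max = 1e-3, end_mismatch_tol = 20L,
                          flank_length = 1000L, word_size = 11L,
                          match = 1, mismatch = -2,
                          gap_open = 5, gap_extend = 2,
                          ka_lambda = 0.625, ka_K = 0.41) {
  if (evalue_max <= 0) stop("evalue_max must be > 0", call. = FALSE)
  if (end_mismatch_tol < 0) stop("end_mismatch_tol must be >= 0", call. = FALSE)
  if (word_size < 4L) stop("word_size must be >= 4", call. = FALSE)
  structure(list(evalue_max = evalue_max,
                 end_mismatch_tol = as.integer(end_mismatch_tol),
                 flank_length = as.integer(flank_length),
                 word_size = as.integer(word_size),
                 match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 ka_lambda = ka_lambda, ka_K = ka_K),
            class = "search_params")
}

#' Karlin-Altschul e-value
#'
#' `E = K * m * n * exp(-lambda * S)` for raw alignment score `S`, query
#' length `m` and searched genome length `n`.  Strictly decreasing in the
#' score and linear in the genome length.
#'
#' @param raw_score Raw alignment score.
#' @param query_len Query length in bp (> 0).
#' @param genome_len Total searched length in bp (> 0).
#' @param params A [search_params()] providing `ka_lambda` and `ka_K`.
#' @return The expected number of chance alignments scoring >= `raw_score`.
#' @export
ka_evalue <- function(raw_score, query_len, genome_len,
                      params = search_params()) {
  if (query_len <= 0 || genome_len <= 0)
    stop("query_len and genome_len must be positive", call. = FALSE)
  params$ka_K * query_len * genome_len * exp(-params$ka_lambda * raw_score)
}

.bit_score <- function(raw_score, params) {
  (params$ka_lambda * raw_score - log(params$ka_K)) / log(2)
}

## coerce genome input to a named character vector
.as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- names(genome)
  } else if (is.character(genome) && length(genome) == 1L &&
             !grepl("[ACGTacgt]{20}", genome) && file.exists(genome)) {
    ss <- Biostrings::readDNAStringSet(genome)
    out <- as.character(ss)
    names(out) <- sub("\\s.*$", "", names(ss))
  } else if (is.character(genome)) {
    out <- toupper(genome)
  } else stop("unsupported genome input", call. = FALSE)
  if (is.null(names(out)) || any(!nzchar(names(out))))
    names(out) <- sprintf("seq%d", seq_along(out))
  out
}

## best local alignments of q within window [w0, w1) of chrom (0-based),
## recursing left/right of each accepted alignment so that several copies
## inside one window are all reported
.window_hits <- function(q, chrom_seq, w0, w1, strand, genome_len, params,
                         submat) {
  if (w1 - w0 < params$word_size) return(NULL)
  subj <- Biostrings::DNAString(.substr0(chrom_seq, w0, w1))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(q), subj, type = "local",
    substitutionMatrix = submat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  raw <- BiocGenerics::score(aln)
  ev <- ka_evalue(raw, nchar(q), genome_len, params)
  if (ev > params$evalue_max) return(NULL)
  srng <- Biostrings::subject(aln)
  s0 <- w0 + IRanges::start(srng) - 1L
  s1 <- w0 + IRanges::end(srng)
  prng <- Biostrings::pattern(aln)
  hit <- data.frame(
    start = s0, end = s1, strand = strand,
    raw_score = raw,
    bit_score = .bit_score(raw, params),
    evalue = ev,
    qstart = IRanges::start(prng),
    qend = IRanges::end(prng),
    pident = Biostrings::pid(aln, type = "PID1"),
    stringsAsFactors = FALSE)
  rbind(hit,
        .window_hits(q, chrom_seq, w0, s0, strand, genome_len, params, submat),
        .window_hits(q, chrom_seq, s1, w1, strand, genome_len, params, submat))
}

#' Retrieve element copies from a genome by seeded homology search
#'
#' Finds all local alignments of a consensus query against both strands
#' of every chromosome: exact `word_size`-mer seeds locate candidate
#' regions, each region is aligned with affine-gap local alignment
#' (+1/-2, gap open/extend 5/2 by default), and alignments are kept when
#' their Karlin-Altschul e-value is at most `evalue_max`.  Hits
#' overlapping by more than half their span are merged to the
#' best-scoring record (one insertion locus, one record), then sorted by
#' chromosome and start.
#'
#' @param query Consensus element sequence (ACGT string), length
#'   >= `word_size` and not a homopolymer.
#' @param genome Named character vector, `DNAStringSet`, or FASTA path.
#' @param params A [search_params()].
#' @return A data.frame of hits: `hit_id`, `chromosome`, `start`, `end`
#'   (0-based half-open aligned span), `strand`, `raw_score`,
#'   `bit_score`, `evalue`, `qstart`, `qend` (1-based query coverage,
#'   query orientation), `pident`, `is_full_length`, plus `full_start`,
#'   `full_end`: the aligned span projected to the full query extent
#'   (the natural element boundaries for flank extraction and TSD
#'   calling, since local alignment trims mismatching element ends).
#' @export
search_copies <- function(query, genome, params = search_params()) {
  query <- .check_dna(query)
  if (nchar(query) < params$word_size)
    stop("query shorter than word_size", call. = FALSE)
  if (length(unique(strsplit(query, "")[[1]])) == 1L)
    stop("degenerate homopolymer query", call. = FALSE)
  genome <- .as_genome(genome)
  if (length(genome) == 0L || all(nchar(genome) == 0L))
    return(.empty_hits())
  genome_len <- sum(nchar(genome))
  qlen <- nchar(query)
  submat <- .submat()

  strands <- list(`+` = query, `-` = revcomp(query))
  res <- list()
  for (chrom in names(genome)) {
    cseq <- genome[[chrom]]
    if (nchar(cseq) < params$word_size) next
    subj <- Biostrings::DNAString(cseq)
    for (st in names(strands)) {
      q <- strands[[st]]
      words <- unique(vapply(seq_len(qlen - params$word_size + 1L),
                             function(i) substr(q, i, i + params$word_size - 1L),
                             character(1)))
      pd <- Biostrings::PDict(words)
      m <- Biostrings::matchPDict(pd, subj)
      r <- BiocGenerics::unlist(m)
      if (length(r) == 0L) next
      cand <- IRanges::reduce(r, min.gapwidth = qlen)
      cand <- IRanges::restrict(
        cand + qlen, start = 1L, end = nchar(cseq))
      cand <- IRanges::reduce(cand)
      for (k in seq_along(cand)) {
        w0 <- IRanges::start(cand)[k] - 1L
        w1 <- IRanges::end(cand)[k]
        h <- .window_hits(q, cseq, w0, w1, st, genome_len, params, submat)
        if (!is.null(h)) {
          h$chromosome <- chrom
          res[[length(res) + 1L]] <- h
        }
      }
    }
  }
  if (length(res) == 0L) return(.empty_hits())
  hits <- do.call(rbind, res)

  ## minus-strand query coverage back to original query orientation
  minus <- hits$strand == "-"
  if (any(minus)) {
    qs <- hits$qstart[minus]; qe <- hits$qend[minus]
    hits$qstart[minus] <- qlen - qe + 1L
    hits$qend[minus] <- qlen - qs + 1L
  }
  hits <- .dedup_hits(hits)
  hits <- hits[order(hits$chromosome, hits$start), , drop = FALSE]
  hits$is_full_length <- vapply(seq_len(nrow(hits)), function(i)
    call_full_length(hits[i, ], qlen, params$end_mismatch_tol), logical(1))
  hits$hit_id <- sprintf("hit%03d", seq_len(nrow(hits)))
  ## projected full-query extent: local alignments trim mismatching
  ## query ends, so the element boundary is start - (unaligned 5' query)
  ## and end + (unaligned 3' query), clipped at the contig
  clen <- nchar(genome)[hits$chromosome]
  trim5 <- ifelse(hits$strand == "+", hits$qstart - 1L, qlen - hits$qend)
  trim3 <- ifelse(hits$strand == "+", qlen - hits$qend, hits$qstart - 1L)
  hits$full_start <- pmax(0L, hits$start - trim5)
  hits$full_end <- pmin(as.integer(clen), hits$end + trim3)
  rownames(hits) <- NULL
  hits[, c("hit_id", "chromosome", "start", "end", "strand", "raw_score",
           "bit_score", "evalue", "qstart", "qend", "pident",
           "is_full_length", "full_start", "full_end")]
}

.empty_hits <- function() {
  data.frame(hit_id = character(0), chromosome = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             raw_score = numeric(0), bit_score = numeric(0),
             evalue = numeric(0), qstart = integer(0), qend = integer(0),
             pident = numeric(0), is_full_length = logical(0),
             stringsAsFactors = FALSE)
}

## merge hits overlapping > 50% of the shorter span: keep the best score
.dedup_hits <- function(hits) {
  hits <- hits[order(-hits$raw_score), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(hits))) {
      if (j == i || !keep[j]) next
      if (hits$chromosome[j] != hits$chromosome[i]) next
      ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j])
      if (ov <= 0) next
      shorter <- min(hits$end[i] - hits$start[i], hits$end[j] - hits$start[j])
      if (ov > 0.5 * shorter) keep[j] <- FALSE
    }
  }
  hits[keep, , drop = FALSE]
}

#' Call whether a hit covers the full query
#'
#' A hit is full length when the unaligned query length at each end is at
#' most `end_mismatch_tol` (the end-tolerance convention of
#' homology-based MITE retrieval).
#'
#' @param hit A one-row hit data.frame with `qstart`, `qend` (1-based).
#' @param query_len Query length in bp.
#' @param end_mismatch_tol Permitted unaligned bp per query end.
#' @return Logical flag.
#' @export
call_full_length <- function(hit, query_len, end_mismatch_tol = 20L) {
  (hit$qstart - 1L) <= end_mismatch_tol &&
    (query_len - hit$qend) <= end_mismatch_tol
}

#' Extract flanking sequences of a hit
#'
#' Retrieves `flank_length` bp upstream and downstream of the hit on the
#' genome strand, truncated (never padded) at chromosome ends, with the
#' truncation recorded.
#'
#' @param genome Named character vector, `DNAStringSet`, or FASTA path.
#' @param hit One-row hit data.frame (`chromosome`, `start`, `end`).
#' @param flank_length Flank length in bp.
#' @return A list: `upstream`, `downstream` (genome-strand strings),
#'   `upstream_clipped`, `downstream_clipped` (logical).
#' @export
extract_flanks <- function(genome, hit, flank_length = 1000L) {
  genome <- .as_genome(genome)
  cseq <- genome[[hit$chromosome]]
  if (is.null(cseq) || is.na(cseq))
    stop("chromosome not present in genome", call. = FALSE)
  L <- nchar(cseq)
  if (hit$start < 0 || hit$end > L || hit$start >= hit$end)
    stop("hit coordinates outside the contig", call. = FALSE)
  up0 <- max(0L, hit$start - flank_length)
  down1 <- min(L, hit$end + flank_length)
  list(upstream = .substr0(cseq, up0, hit$start),
       downstream = .substr0(cseq, hit$end, down1),
       upstream_clipped = (hit$start - flank_length) < 0L,
       downstream_clipped = (hit$end + flank_length) > L)
}
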