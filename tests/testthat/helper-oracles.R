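## Independent oracles used by the unit and acceptance tests.  These
## deliberately re-derive results by brute force or closed form and do
## not call the package code paths they check (shared primitives like
## revcomp are coordinate-free string utilities).

## exhaustive TSD search over all (k, upstream offset, downstream offset)
brute_tsd <- function(up, down, k_min = 8L, k_max = 12L, max_mm = 0L,
                      slack = 2L) {
  best <- NULL
  ulen <- nchar(up)
  for (k in seq(k_max, k_min)) {
    for (ou in 0:slack) {
      if (ulen - ou - k < 0) next
      a <- substr(up, ulen - ou - k + 1L, ulen - ou)
      for (od in 0:slack) {
        if (od + k > nchar(down)) next
        b <- substr(down, od + 1L, od + k)
        mm <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
        if (mm > max_mm) next
        cand <- list(k = k, mm = mm, off = c(ou, od), seq = a)
        better <- is.null(best) || cand$k > best$k ||
          (cand$k == best$k && (cand$mm < best$mm ||
            (cand$mm == best$mm && sum(cand$off) < sum(best$off))))
        if (better) best <- cand
      }
    }
  }
  best
}

## sliding-window local-alignment scan over all positions, both strands,
## filtered by the Karlin-Altschul e-value written out in closed form
brute_search <- function(query, genome, evalue_max = 1e-3) {
  qlen <- nchar(query)
  glen <- sum(nchar(genome))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  hits <- list()
  for (chrom in names(genome)) {
    cseq <- genome[[chrom]]
    L <- nchar(cseq)
    starts <- seq(1L, max(1L, L - 1L), by = max(1L, qlen %/% 2L))
    for (st in c("+", "-")) {
      q <- Biostrings::DNAString(if (st == "+") query else revcomp(query))
      for (w0 in starts) {
        w1 <- min(L, w0 + 2L * qlen - 1L)
        aln <- Biostrings::pairwiseAlignment(
          q, Biostrings::DNAString(substr(cseq, w0, w1)), type = "local",
          substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
        S <- BiocGenerics::score(aln)
        E <- 0.41 * qlen * glen * exp(-0.625 * S)
        if (E > evalue_max) next
        hits[[length(hits) + 1L]] <- data.frame(
          chromosome = chrom,
          start = w0 - 1L + IRanges::start(Biostrings::subject(aln)) - 1L,
          end = w0 - 1L + IRanges::end(Biostrings::subject(aln)),
          strand = st, raw_score = S, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) return(NULL)
  h <- unique(do.call(rbind, hits))
  h <- h[order(-h$raw_score), , drop = FALSE]
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(h))) {
      if (j == i || !keep[j]) next
      if (h$chromosome[j] != h$chromosome[i]) next
      ov <- min(h$end[i], h$end[j]) - max(h$start[i], h$start[j])
      if (ov > 0 &&
          ov > 0.5 * min(h$end[i] - h$start[i], h$end[j] - h$start[j]))
        keep[j] <- FALSE
    }
  }
  h <- h[keep, , drop = FALSE]
  h <- h[order(h$chromosome, h$start), , drop = FALSE]
  rownames(h) <- NULL
  h
}

## plant a diverged copy of an element into a sequence (plain string ops,
## no TSD) and return the new sequence
splice_in <- function(seq, insert, pos0) {
  paste0(substr(seq, 1L, pos0), insert,
         substr(seq, pos0 + 1L, nchar(seq)))
}

## diverge a sequence at a given per-site substitution rate
mutate_seq <- function(x, rate) {
  v <- strsplit(x, "")[[1]]
  hit <- which(stats::runif(length(v)) < rate)
  for (k in hit) v[k] <- sample(setdiff(c("A", "C", "G", "T"), v[k]), 1L)
  paste(v, collapse = "")
}

## hand-rolled average-linkage agglomeration: merge heights for small n
brute_upgma_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dm <- mean(d[clusters[[i]], clusters[[j]]])
        if (dm < bd) { bd <- dm; best <- c(i, j) }
      }
    }
    heights <- c(heights, bd)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1L]] <- merged
  }
  sort(heights)
}

## a small default simulation kept fast for unit tests
small_config <- function(seed = 1L, ...) {
  simulation_config(n_chromosomes = 2L, chrom_length = 40000L,
                    copies_per_genome = 6L, seed = seed, ...)
}
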