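#' Simulation configuration for synthetic wheat-like genomes
#'
#' Collects the parameters of the synthetic-genome generator: a multi-
#' chromosome background carrying a low-copy 307-bp miniature element with
#' 9-bp target-site duplications (TSDs), one copy inside exon 6 of a
#' 7-exon host gene, population-structured presence/absence across
#' accession panels, and qPCR CT tables with group-level expression
#' shifts.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Chromosome length in bp.
#' @param element Consensus element sequence (ACGT string); default
#'   [mite_consensus()].
#' @param tsd_length Target-site duplication length in bp (default 9).
#' @param copies_per_genome Number of element copies planted in the
#'   reference genome, including the exonic index copy (default 12,
#'   a tetraploid-wheat-like copy number).
#' @param copy_divergence Per-site substitution probability applied to
#'   each non-index copy, in `[0, 1]` (default 0.03, giving > 90% mean
#'   pairwise identity among copies).
#' @param tsd_decay_fraction Fraction of copies whose downstream TSD copy
#'   is mutated beyond recognition (>= 3 substitutions), in `[0, 1]`.
#'   Default 0.5: about half the copies retain a clear TSD.
#' @param n_populations Number of accession populations (default 5).
#' @param accessions_per_population Accessions sampled per population
#'   (default 9).
#' @param presence_profile Optional loci x populations matrix of
#'   probabilities that an accession carries the full (element-bearing)
#'   site.  `NULL` (default) draws a mixture of fixed, population-specific
#'   and broadly polymorphic locus archetypes.
#' @param panel_flank Flank length (bp) kept around each locus in the
#'   accession panel sequences (default 400).
#' @param gene_plan Host-gene geometry; default [default_gene_plan()].
#' @param seed Integer seed; a fixed seed makes all generated objects
#'   byte-identical across runs.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_chromosomes = 3L,
                              chrom_length = 100000L,
                              element = mite_consensus(),
                              tsd_length = 9L,
                              copies_per_genome = 12L,
                              copy_divergence = 0.03,
                              tsd_decay_fraction = 0.5,
                              n_populations = 5L,
                              accessions_per_population = 9L,
                              presence_profile = NULL,
                              panel_flank = 400L,
                              gene_plan = default_gene_plan(),
                              seed = 1L) {
  element <- .check_dna(element)
  if (nchar(element) < tsd_length + 3L)
    stop("element must be at least tsd_length + 3 bp long", call. = FALSE)
  .check_prob(copy_divergence)
  .check_prob(tsd_decay_fraction)
  if (!is.null(presence_profile)) .check_prob(presence_profile)
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length),
              element = element,
              element_length = nchar(element),
              tsd_length = as.integer(tsd_length),
              copies_per_genome = as.integer(copies_per_genome),
              copy_divergence = copy_divergence,
              tsd_decay_fraction = tsd_decay_fraction,
              n_populations = as.integer(n_populations),
              accessions_per_population = as.integer(accessions_per_population),
              presence_profile = presence_profile,
              panel_flank = as.integer(panel_flank),
              gene_plan = gene_plan,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Plant a transposon-like insertion with a target-site duplication
#'
#' Inserts `element` into `sequence` at a 0-based `position`, duplicating
#' the `tsd_length` bases that start at `position` on both sides of the
#' element, as a staggered-cut integration would.  The output is
#' `prefix..position+tsd_length | element | suffix from position`, so the
#' target site appears once before and once after the element and the
#' sequence grows by exactly `nchar(element) + tsd_length`.
#'
#' @param sequence Host sequence (ACGT string).
#' @param element Element sequence (ACGT string, non-empty).
#' @param position 0-based offset of the target site;
#'   `0 <= position <= nchar(sequence) - tsd_length`.
#' @param tsd_length TSD length in bp; 0 gives a plain insertion.
#' @return A list with `sequence` (the post-insertion string) and
#'   `record` (a one-row data.frame with `insert_position`,
#'   `tsd_sequence`, `element_start`, `element_end`; element coordinates
#'   are 0-based half-open in the output sequence).
#' @export
plant_insertion <- function(sequence, element, position, tsd_length = 9L) {
  sequence <- .check_dna(sequence)
  element <- .check_dna(element)
  if (nchar(element) == 0L) stop("element must be non-empty", call. = FALSE)
  position <- as.integer(position)
  tsd_length <- as.integer(tsd_length)
  if (tsd_length < 0L) stop("tsd_length must be >= 0", call. = FALSE)
  if (position < 0L || position > nchar(sequence) - tsd_length)
    stop("position out of range for this sequence and tsd_length",
         call. = FALSE)
  tsd <- .substr0(sequence, position, position + tsd_length)
  out <- paste0(.substr0(sequence, 0L, position + tsd_length),
                element,
                .substr0(sequence, position, nchar(sequence)))
  rec <- data.frame(insert_position = position,
                    tsd_sequence = tsd,
                    element_start = position + tsd_length,
                    element_end = position + tsd_length + nchar(element),
                    stringsAsFactors = FALSE)
  list(sequence = out, record = rec)
}

## place n copies on chromosomes, avoiding an exclusion zone on chr1 and
## keeping copies well separated; bounded retries
.place_copies <- function(n, n_chrom, chrom_len, margin, min_gap,
                          exclude_chr1, max_tries = 2000L) {
  chosen_chr <- integer(0)
  chosen_pos <- integer(0)
  tries <- 0L
  while (length(chosen_pos) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not place all element copies without overlap; ",
           "reduce copies_per_genome or increase chrom_length",
           call. = FALSE)
    chr <- sample.int(n_chrom, 1L)
    pos <- sample.int(chrom_len - 2L * margin, 1L) + margin
    if (chr == 1L && pos >= exclude_chr1[1] && pos <= exclude_chr1[2]) next
    same <- chosen_chr == chr
    if (any(abs(chosen_pos[same] - pos) < min_gap)) next
    chosen_chr <- c(chosen_chr, chr)
    chosen_pos <- c(chosen_pos, pos)
  }
  data.frame(chrom = chosen_chr, pos = chosen_pos)
}

#' Generate a synthetic reference genome with planted element copies
#'
#' Builds `n_chromosomes` of i.i.d. uniform ACGT background, embeds one
#' 7-exon host gene on chromosome 1 (per the config's `gene_plan`), and
#' plants `copies_per_genome` copies of the consensus element, each with a
#' 9-bp target-site duplication.  One copy (the undiverged index copy)
#' goes inside exon 6 of the host gene at the planned target-site motif;
#' the rest are intergenic, mutated at `copy_divergence`, and planted on a
#' random strand.  A fraction `tsd_decay_fraction` of copies has its
#' downstream TSD copy disrupted by >= 3 substitutions, so a strict TSD
#' detector no longer calls it.  Gene-model coordinates are reported on
#' the post-insertion genome.
#'
#' @param config A [simulation_config()].
#' @return A list of class `mite_reference` with components `genome`
#'   (named character vector of chromosome sequences), `genes` (GFF3-style
#'   `GRanges` with gene/mRNA/exon/CDS features), `tes` (`GRanges` of
#'   unrelated annotated TE intervals), `truth` (data.frame: `copy_id`,
#'   `chromosome`, `insert_position`, `strand`, `tsd_sequence`,
#'   `tsd_intact`, `locus_id`, `element_start`, `element_end`, `exonic`),
#'   plus `element`, `gene_id` and the `config`.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  plan <- config$gene_plan
  tsd <- config$tsd_length
  el_len <- config$element_length
  ins_len <- el_len + tsd
  n_copies <- config$copies_per_genome

  chrom_names <- sprintf("chr%d", seq_len(config$n_chromosomes))
  genome <- vapply(chrom_names, function(x) random_dna(config$chrom_length),
                   character(1))

  ## --- host gene on chr1 (pre-insertion coordinates) ---
  mrna <- .build_gene_mrna(plan)
  cumE <- c(0L, cumsum(plan$exon_len))
  gene_seq <- character(0)
  for (i in seq_along(plan$exon_len)) {
    gene_seq <- c(gene_seq, .substr0(mrna, cumE[i], cumE[i + 1L]))
    if (i < length(plan$exon_len)) {
      intron <- random_dna(plan$intron_len)
      substr(intron, 1L, 2L) <- "GT"
      substr(intron, plan$intron_len - 1L, plan$intron_len) <- "AG"
      gene_seq <- c(gene_seq, intron)
    }
  }
  gene_seq <- paste(gene_seq, collapse = "")
  gene_start <- 2000L
  gene_len <- nchar(gene_seq)
  genome["chr1"] <- paste0(.substr0(genome["chr1"], 0L, gene_start),
                           gene_seq,
                           .substr0(genome["chr1"], gene_start + gene_len,
                                    config$chrom_length))
  genome["chr1"] <- .substr0(genome["chr1"], 0L, config$chrom_length)

  ## --- copy placement (pre-insertion coordinates) ---
  exonic_pos <- gene_start +
    .mrna_to_gene_offset(plan, plan$insertion_mrna_offset)
  margin <- config$panel_flank + 1200L
  placed <- .place_copies(n_copies - 1L, config$n_chromosomes,
                          config$chrom_length, margin, 2500L,
                          exclude_chr1 = c(gene_start - 2500L,
                                           gene_start + gene_len + 2500L))
  copies <- rbind(data.frame(chrom = 1L, pos = exonic_pos), placed)
  copies$exonic <- c(TRUE, rep(FALSE, nrow(placed)))
  copies$strand <- c("+", sample(c("+", "-"), nrow(placed), replace = TRUE))
  copies$seq <- c(config$element,
                  vapply(seq_len(nrow(placed)), function(i)
                    .diverge(config$element, config$copy_divergence),
                    character(1)))

  ## TSD decay assignment: keep the index copy intact when possible
  n_intact <- round((1 - config$tsd_decay_fraction) * n_copies)
  n_decay <- n_copies - n_intact
  decay_idx <- if (n_decay >= n_copies) seq_len(n_copies)
               else 1L + sample.int(n_copies - 1L, min(n_decay, n_copies - 1L))
  copies$tsd_intact <- !(seq_len(n_copies) %in% decay_idx)

  ## plant ascending per chromosome, tracking the running shift
  ord <- order(copies$chrom, copies$pos)
  copies <- copies[ord, , drop = FALSE]
  shift <- integer(config$n_chromosomes)
  truth <- vector("list", n_copies)
  for (i in seq_len(n_copies)) {
    ch <- copies$chrom[i]
    fpos <- copies$pos[i] + shift[ch]
    elem <- if (copies$strand[i] == "+") copies$seq[i] else revcomp(copies$seq[i])
    pl <- plant_insertion(genome[ch], elem, fpos, tsd)
    genome[ch] <- pl$sequence
    tsd_seq <- pl$record$tsd_sequence
    if (!copies$tsd_intact[i]) {
      ## disrupt the downstream TSD copy with 3 substitutions
      down0 <- fpos + tsd + nchar(elem)
      seg <- .substr0(genome[ch], down0, down0 + tsd)
      seg <- .mutate_positions(seg, sample.int(tsd, 3L))
      s <- genome[ch]
      substr(s, down0 + 1L, down0 + tsd) <- seg
      genome[ch] <- s
    }
    shift[ch] <- shift[ch] + tsd + nchar(elem)
    truth[[i]] <- data.frame(
      copy_id = NA_character_,
      chromosome = chrom_names[ch],
      insert_position = fpos,
      strand = copies$strand[i],
      tsd_sequence = tsd_seq,
      tsd_intact = copies$tsd_intact[i],
      locus_id = NA_character_,
      element_start = fpos + tsd,
      element_end = fpos + tsd + nchar(elem),
      exonic = copies$exonic[i],
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  truth$copy_id <- sprintf("copy%02d", seq_len(nrow(truth)))
  truth$locus_id <- sprintf("L%02d", seq_len(nrow(truth)))

  ## --- final gene model (post-insertion coordinates) ---
  n_before_gene <- sum(truth$chromosome == "chr1" &
                       truth$insert_position < gene_start &
                       !truth$exonic)
  gs <- gene_start + n_before_gene * ins_len
  exon_start <- exon_end <- integer(7L)
  for (i in 1:7) {
    exon_start[i] <- gs + cumE[i] + (i - 1L) * plan$intron_len +
      if (i > plan$target_exon) ins_len else 0L
    exon_end[i] <- exon_start[i] + plan$exon_len[i] +
      if (i == plan$target_exon) ins_len else 0L
  }
  cds_m <- c(plan$utr5_len, plan$utr5_len + plan$cds_len)
  cds_start <- cds_end <- rep(NA_integer_, 7L)
  for (i in 1:7) {
    lo <- max(cumE[i], cds_m[1]); hi <- min(cumE[i + 1L], cds_m[2])
    if (lo >= hi) next
    cds_start[i] <- exon_start[i] + (lo - cumE[i])
    cds_end[i] <- exon_start[i] + (hi - cumE[i]) +
      if (i == plan$target_exon) ins_len else 0L
  }
  keep <- !is.na(cds_start)
  gene_id <- "GENE1"
  feat <- function(type, start0, end0, id, parent, phase = NA_integer_) {
    GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(start = start0 + 1L, end = end0),
      strand = "+", type = type, ID = id,
      Parent = IRanges::CharacterList(
        if (is.na(parent)) list(character(0)) else list(parent)),
      phase = phase)
  }
  gr <- c(
    feat("gene", exon_start[1], exon_end[7], gene_id, NA),
    feat("mRNA", exon_start[1], exon_end[7], paste0(gene_id, ".1"), gene_id))
  for (i in 1:7)
    gr <- c(gr, feat("exon", exon_start[i], exon_end[i],
                     sprintf("%s.1.exon%d", gene_id, i),
                     paste0(gene_id, ".1")))
  cds_sofar <- 0L
  for (i in which(keep)) {
    gr <- c(gr, feat("CDS", cds_start[i], cds_end[i],
                     sprintf("%s.1.cds%d", gene_id, i),
                     paste0(gene_id, ".1"),
                     phase = (3L - cds_sofar %% 3L) %% 3L))
    cds_sofar <- cds_sofar + (cds_end[i] - cds_start[i])
  }
  GenomeInfoDb::seqlevels(gr) <- chrom_names
  names(gr) <- NULL

  ## --- unrelated annotated TE intervals (annotation only) ---
  n_te <- 20L
  te_chr <- sample.int(config$n_chromosomes, n_te, replace = TRUE)
  te_start <- vapply(te_chr, function(ch)
    sample.int(config$chrom_length - 4000L, 1L), integer(1))
  te_len <- sample(500:3000, n_te, replace = TRUE)
  ## put a third of them right next to element copies
  near <- sample(which(!truth$exonic), min(4L, sum(!truth$exonic)))
  for (j in seq_along(near)) {
    te_chr[j] <- match(truth$chromosome[near[j]], chrom_names)
    te_start[j] <- truth$element_end[near[j]] + sample(50:400, 1L)
  }
  tes <- GenomicRanges::GRanges(
    chrom_names[te_chr],
    IRanges::IRanges(start = te_start + 1L, end = te_start + te_len),
    strand = "*", name = sprintf("TE%02d", seq_len(n_te)))
  GenomeInfoDb::seqlevels(tes) <- chrom_names

  structure(list(genome = genome, genes = gr, tes = tes, truth = truth,
                 element = config$element, gene_id = gene_id,
                 gene_plan = plan, config = config),
            class = "mite_reference")
}

#' Generate an accession panel with population-structured presence/absence
#'
#' For every planted locus in a reference genome, extracts the locus
#' region (element plus `panel_flank` bp on each side) and builds, for
#' each accession, either the full-site haplotype or the empty-site
#' haplotype in which the element and one TSD copy are excised, leaving
#' exactly one copy of the target site.  Presence is an independent
#' Bernoulli draw from the locus x population `presence_profile`.
#' Accessions are simulated homozygous (wild emmer is predominantly
#' self-pollinating).
#'
#' @param reference A `mite_reference` from [generate_reference()].
#' @param config The same [simulation_config()]; its `presence_profile`
#'   (loci x populations) is used when supplied, otherwise a mixture of
#'   fixed, population-specific and broadly polymorphic archetypes is
#'   drawn.
#' @return A list of class `mite_panel` with `sequences` (per-accession
#'   named character vectors, one sequence per locus), `panel_truth`
#'   (data.frame: `locus_id`, `accession_id`, `population`, `present`),
#'   `populations` (accession -> population map) and `profile` (the
#'   probability matrix used).
#' @export
generate_accession_panel <- function(reference, config = reference$config) {
  stopifnot(inherits(reference, "mite_reference"))
  set.seed(config$seed + 1000003L)
  truth <- reference$truth
  tsd <- config$tsd_length
  flank <- config$panel_flank
  n_pop <- config$n_populations
  n_acc <- config$accessions_per_population
  n_loci <- nrow(truth)

  profile <- config$presence_profile
  if (is.null(profile)) {
    profile <- matrix(0, n_loci, n_pop)
    for (l in seq_len(n_loci)) {
      arche <- sample(c("fixed", "popspec", "poly"), 1L,
                      prob = c(0.15, 0.45, 0.40))
      profile[l, ] <- switch(arche,
        fixed = rep(1, n_pop),
        popspec = { p <- rep(0.05, n_pop)
                    p[sample.int(n_pop, 1L)] <- 0.9; p },
        poly = { p <- rep(0, n_pop)
                 k <- sample(2:max(2L, n_pop - 2L), 1L)
                 p[sample.int(n_pop, k)] <- stats::runif(k, 0.3, 0.8); p })
    }
  }
  if (!all(dim(profile) == c(n_loci, n_pop)))
    stop("presence_profile must be a loci x populations matrix",
         call. = FALSE)
  rownames(profile) <- truth$locus_id

  acc_id <- as.vector(outer(seq_len(n_acc), seq_len(n_pop),
                            function(a, p) sprintf("P%d_A%d", p, a)))
  pop_of <- rep(sprintf("P%d", seq_len(n_pop)), each = n_acc)
  names(pop_of) <- acc_id

  ## locus haplotypes from the reference
  full_hap <- empty_hap <- character(n_loci)
  for (l in seq_len(n_loci)) {
    chrom <- reference$genome[truth$chromosome[l]]
    pos <- truth$insert_position[l]
    el_len <- truth$element_end[l] - truth$element_start[l]
    lo <- max(0L, pos - flank)
    hi <- min(nchar(chrom), pos + 2L * tsd + el_len + flank)
    full_hap[l] <- .substr0(chrom, lo, hi)
    cut_lo <- (pos - lo) + tsd
    cut_hi <- cut_lo + el_len + tsd
    empty_hap[l] <- paste0(.substr0(full_hap[l], 0L, cut_lo),
                           .substr0(full_hap[l], cut_hi, nchar(full_hap[l])))
  }

  sequences <- vector("list", length(acc_id))
  names(sequences) <- acc_id
  rows <- vector("list", length(acc_id))
  for (a in seq_along(acc_id)) {
    pop <- match(pop_of[a], sprintf("P%d", seq_len(n_pop)))
    present <- unname(stats::runif(n_loci) < profile[, pop])
    seqs <- ifelse(present, full_hap, empty_hap)
    names(seqs) <- truth$locus_id
    sequences[[a]] <- seqs
    rows[[a]] <- data.frame(locus_id = truth$locus_id,
                            accession_id = acc_id[a],
                            population = unname(pop_of[a]),
                            present = present,
                            stringsAsFactors = FALSE)
  }
  structure(list(sequences = sequences,
                 panel_truth = do.call(rbind, rows),
                 populations = pop_of,
                 profile = profile),
            class = "mite_panel")
}

#' Derive a site-specific primer panel from the reference genome
#'
#' Picks exact-match primers from the flanks of every planted locus
#' (forward on the upstream flank, reverse as the reverse complement of
#' the downstream flank) and computes the expected full-site and
#' empty-site amplicon lengths.
#'
#' @param reference A `mite_reference`.
#' @param primer_len Primer length in bp (default 20).
#' @param gap Distance in bp between each primer and the target site
#'   (default 180).
#' @return A data.frame: `locus_id`, `forward`, `reverse`,
#'   `expected_full`, `expected_empty` (bp).
#' @export
panel_primers <- function(reference, primer_len = 20L, gap = 180L) {
  stopifnot(inherits(reference, "mite_reference"))
  truth <- reference$truth
  tsd <- reference$config$tsd_length
  out <- vector("list", nrow(truth))
  for (l in seq_len(nrow(truth))) {
    chrom <- reference$genome[truth$chromosome[l]]
    pos <- truth$insert_position[l]
    el_len <- truth$element_end[l] - truth$element_start[l]
    end2 <- pos + 2L * tsd + el_len
    fwd <- .substr0(chrom, pos - gap - primer_len, pos - gap)
    rev <- revcomp(.substr0(chrom, end2 + gap, end2 + gap + primer_len))
    full <- 2L * (gap + primer_len) + el_len + 2L * tsd
    out[[l]] <- data.frame(locus_id = truth$locus_id[l],
                           forward = fwd, reverse = rev,
                           expected_full = full,
                           expected_empty = full - el_len - tsd,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Simulate a qPCR CT table with group-level expression shifts
#'
#' Draws target-gene and endogenous-control CT values for a groups x
#' accessions design.  Group `effects` are added to the target CT only
#' (one extra cycle halves apparent expression), noise is i.i.d. normal
#' on both genes, and the calibrator accession is flagged.
#'
#' @param groups Character vector of group names.
#' @param n_per_group Accessions per group.
#' @param effects Numeric per-group shift (CT cycles) added to the target
#'   gene; length 1 or `length(groups)`.
#' @param noise_sd CT noise standard deviation (applied to both genes).
#' @param base_target,base_control Baseline mean CT values.
#' @param calibrator Accession id used as calibrator; default the first
#'   accession of the first group.
#' @param seed Optional integer seed.
#' @return A data.frame: `accession`, `group`, `ct_target`, `ct_control`,
#'   `is_calibrator`.
#' @export
generate_ct_table <- function(groups, n_per_group, effects = 0,
                              noise_sd = 0.2, base_target = 24,
                              base_control = 20, calibrator = NULL,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  effects <- rep_len(effects, length(groups))
  acc <- as.vector(t(outer(groups, seq_len(n_per_group),
                           function(g, i) paste0(g, "_", i))))
  grp <- rep(groups, each = n_per_group)
  shift <- rep(effects, each = n_per_group)
  n <- length(acc)
  tab <- data.frame(
    accession = acc,
    group = grp,
    ct_target = base_target + shift + stats::rnorm(n, 0, noise_sd),
    ct_control = base_control + stats::rnorm(n, 0, noise_sd),
    stringsAsFactors = FALSE)
  if (is.null(calibrator)) calibrator <- acc[1L]
  tab$is_calibrator <- tab$accession == calibrator
  tab
}
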