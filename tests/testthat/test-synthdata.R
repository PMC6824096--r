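test_that("plant_insertion duplicates the target site and conserves length", {
  p <- plant_insertion("AAACCAAGAACTGGG", "TTTT", 3, 9)
  expect_identical(p$sequence, "AAACCAAGAACTTTTTCCAAGAACTGGG")
  expect_identical(p$record$tsd_sequence, "CCAAGAACT")

  ## tsd_length = 0 gives a plain insertion
  p0 <- plant_insertion("ACGTACGT", "GGG", 4, 0)
  expect_identical(nchar(p0$sequence), 8L + 3L)
  expect_identical(p0$sequence, "ACGTGGGACGT")

  ## length conservation over random cases
  set.seed(11)
  for (i in 1:20) {
    s <- random_dna(sample(50:200, 1))
    e <- random_dna(sample(5:50, 1))
    t <- sample(0:9, 1)
    pos <- sample(0:(nchar(s) - t), 1)
    out <- plant_insertion(s, e, pos, t)
    expect_identical(nchar(out$sequence), nchar(s) + nchar(e) + t)
    ## the t bases at pos appear before and after the element
    expect_identical(substr(out$sequence, pos + 1, pos + t),
                     substr(s, pos + 1, pos + t))
    expect_identical(substr(out$sequence, pos + t + nchar(e) + 1,
                            pos + 2 * t + nchar(e)),
                     substr(s, pos + 1, pos + t))
  }

  expect_error(plant_insertion("ACGT", "TT", 5, 2), "out of range")
  expect_error(plant_insertion("ACGN", "TT", 0, 2), "non-ACGT")
})

test_that("plant_insertion round-trips through the TSD detector", {
  set.seed(21)
  for (i in 1:10) {
    bg <- random_dna(1000)
    pos <- sample(100:800, 1)
    out <- plant_insertion(bg, mite_consensus(), pos, 9)
    expect_identical(nchar(out$sequence), 1000L + 307L + 9L)
    up <- substr(out$sequence, pos - 49, pos + 9)
    down <- substr(out$sequence, pos + 9 + 307 + 1, pos + 9 + 307 + 60)
    call <- detect_tsd(up, down, k_min = 8, k_max = 12)
    expect_true(call$found)
    expect_identical(call$tsd_length, 9L)
    expect_identical(call$tsd_upstream, substr(bg, pos + 1, pos + 9))
  }
})

test_that("generate_reference plants the configured copies with truth", {
  cfg <- small_config(seed = 3)
  ref <- generate_reference(cfg)
  expect_identical(nrow(ref$truth), 6L)
  ## half the copies retain intact TSDs (tsd_decay_fraction = 0.5)
  expect_identical(sum(ref$truth$tsd_intact), 3L)
  ## every copy sits where truth says: the element flanked by its site
  for (i in seq_len(nrow(ref$truth))) {
    tr <- ref$truth[i, ]
    chrom <- ref$genome[[tr$chromosome]]
    expect_identical(substr(chrom, tr$insert_position + 1,
                            tr$insert_position + 9),
                     tr$tsd_sequence)
    if (tr$tsd_intact)
      expect_identical(substr(chrom, tr$element_end + 1, tr$element_end + 9),
                       tr$tsd_sequence)
  }
  ## the index copy lies in exon 6 at the canonical motif
  idx <- ref$truth[ref$truth$exonic, ]
  expect_identical(idx$tsd_sequence, target_site_motif())
  ## chromosome length grew by exactly the planted material
  expect_identical(nchar(ref$genome[["chr1"]]),
                   cfg$chrom_length +
                     316L * sum(ref$truth$chromosome == "chr1"))
})

test_that("simulation is deterministic for a fixed seed", {
  a <- generate_reference(small_config(seed = 7))
  b <- generate_reference(small_config(seed = 7))
  expect_identical(a$genome, b$genome)
  expect_identical(a$truth, b$truth)
  pa <- generate_accession_panel(a)
  pb <- generate_accession_panel(b)
  expect_identical(pa$sequences, pb$sequences)
  expect_identical(pa$panel_truth, pb$panel_truth)
  ## a different seed changes the genome
  expect_false(identical(
    a$genome, generate_reference(small_config(seed = 8))$genome))
})

test_that("divergence zero gives copies identical to the consensus", {
  ref <- generate_reference(small_config(seed = 5, copy_divergence = 0))
  copies <- vapply(seq_len(nrow(ref$truth)), function(i) {
    tr <- ref$truth[i, ]
    s <- substr(ref$genome[[tr$chromosome]], tr$element_start + 1,
                tr$element_end)
    if (tr$strand == "-") revcomp(s) else s
  }, character(1))
  expect_true(all(copies == mite_consensus()))
  idm <- pairwise_identity_matrix(copies)
  expect_true(all(idm$identity == 100))
})

test_that("accession panel realizes extreme presence profiles", {
  cfg1 <- small_config(seed = 9, n_populations = 2,
                       accessions_per_population = 3,
                       presence_profile = matrix(1, 6, 2))
  ref <- generate_reference(cfg1)
  pan1 <- generate_accession_panel(ref, cfg1)
  expect_true(all(pan1$panel_truth$present))

  cfg0 <- small_config(seed = 9, n_populations = 2,
                       accessions_per_population = 3,
                       presence_profile = matrix(0, 6, 2))
  pan0 <- generate_accession_panel(ref, cfg0)
  expect_false(any(pan0$panel_truth$present))

  ## empty haplotypes carry exactly one copy of the target site
  tr <- ref$truth[1, ]
  hap <- pan0$sequences[[1]][[tr$locus_id]]
  n_site <- length(gregexpr(tr$tsd_sequence, hap, fixed = TRUE)[[1]])
  expect_identical(n_site, 1L)
  ## and are shorter than full haplotypes by element + one TSD copy
  full <- pan1$sequences[[1]][[tr$locus_id]]
  expect_identical(nchar(full) - nchar(hap), 316L)
})

test_that("population-structured profiles yield the intended codes", {
  ## a locus present at high rate in the five in-group populations and
  ## absent from the outgroup panel codes as (1,1,1,1,1,0)
  profile <- matrix(0, 6, 6)
  profile[1, 1:5] <- 0.6
  cfg <- small_config(seed = 13, n_populations = 6,
                      accessions_per_population = 9,
                      presence_profile = profile)
  ref <- generate_reference(cfg)
  pan <- generate_accession_panel(ref, cfg)
  pt <- pan$panel_truth[pan$panel_truth$locus_id == ref$truth$locus_id[1], ]
  calls <- as.integer(pt$present)
  names(calls) <- pt$accession_id
  amps <- lapply(calls, function(x) if (x == 1) 500 else 200)
  sc <- score_locus(amps, 500, 200, tol = 10, populations = pan$populations)
  expect_identical(unname(sc$codes[sprintf("P%d", 1:6)]),
                   c(1L, 1L, 1L, 1L, 1L, 0L))
})

test_that("CT tables follow the 2^-ddCt closed forms", {
  ## zero noise, zero effect: RQ is exactly 1 everywhere
  tab <- generate_ct_table(c("g1", "g2"), 4, effects = 0, noise_sd = 0,
                           seed = 1)
  rq <- relative_expression(tab)
  expect_true(all(rq$rq == 1))

  ## +1 CT on the target only halves RQ in that group
  tab2 <- generate_ct_table(c("g1", "g2"), 4, effects = c(0, 1),
                            noise_sd = 0, seed = 1)
  rq2 <- relative_expression(tab2)
  expect_equal(as.numeric(tapply(rq2$rq, rq2$group, mean)), c(1, 0.5))
})

test_that("group shifts of 1 CT are detected by ANOVA with high power", {
  hits <- vapply(1:200, function(s) {
    tab <- generate_ct_table(c("a", "b"), 5, effects = c(0, 1),
                             noise_sd = 0.2, seed = 40000 + s)
    rq <- relative_expression(tab)
    anova_tukey(rq$rq, rq$group)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("written simulation files are deterministic and well formed", {
  d1 <- file.path(tempdir(), "sim1"); d2 <- file.path(tempdir(), "sim2")
  ref <- generate_reference(small_config(seed = 2))
  write_simulation(ref, d1)
  write_simulation(ref, d2)
  expect_identical(readLines(file.path(d1, "genome.fa")),
                   readLines(file.path(d2, "genome.fa")))
  ## GFF3 round-trips through rtracklayer with consistent coordinates
  gff <- rtracklayer::import(file.path(d1, "genes.gff3"))
  exon6 <- gff[gff$type == "exon"][6]
  expect_identical(BiocGenerics::width(exon6),
                   ref$gene_plan$exon_len[6] + 316L)
  unlink(c(d1, d2), recursive = TRUE)
})
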