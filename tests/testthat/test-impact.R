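ref_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_reference(simulation_config(seed = 1))
    cache
  }
})

test_that("spliced transcripts conserve exon arithmetic", {
  ref <- ref_fixture()
  anc <- ancestral_gene(ref)
  plan <- ref$gene_plan
  mr0 <- splice_transcript(anc$gene, anc$genome)
  expect_identical(nchar(mr0), sum(plan$exon_len))
  mr1 <- splice_transcript(anc$gene, anc$genome,
                           insertion_allele(anc$insertion_position,
                                            anc$element, anc$tsd_length))
  expect_identical(nchar(mr1) - nchar(mr0), 307L + 9L)
  ## the novel segment is element plus one extra target-site copy
  sp <- attr(mr1, "inserted_span")
  expect_identical(sp[2] - sp[1], 316L)
  expect_identical(substr(as.character(mr1), sp[1] + 1, sp[1] + 307),
                   anc$element)
  ## removing the novel segment restores the reference mRNA
  expect_identical(paste0(substr(mr1, 1, sp[1]),
                          substr(mr1, sp[2] + 1, nchar(mr1))),
                   as.character(mr0))
  ## an insertion across a splice junction is refused
  intron_pos <- anc$gene$exons[1, "end"] + 10L
  expect_error(
    splice_transcript(anc$gene, anc$genome,
                      insertion_allele(intron_pos, anc$element, 9L)),
    "unsupported")
})

test_that("RT-PCR on the two alleles differs by element plus TSD", {
  ref <- ref_fixture()
  anc <- ancestral_gene(ref)
  plan <- ref$gene_plan
  mr0 <- splice_transcript(anc$gene, anc$genome)
  mr1 <- splice_transcript(anc$gene, anc$genome,
                           insertion_allele(anc$insertion_position,
                                            anc$element, anc$tsd_length))
  fwd <- substr(mr0, plan$fwd_primer_start + 1,
                plan$fwd_primer_start + plan$fwd_primer_len)
  rev <- revcomp(substr(mr0, plan$rev_primer_end - plan$rev_primer_len + 1,
                        plan$rev_primer_end))
  a0 <- insilico_pcr(mr0, fwd, rev)
  a1 <- insilico_pcr(mr1, fwd, rev)
  expect_identical(a1$length - a0$length, 316L)
})

test_that("ORF truncation is localized inside the element", {
  ref <- ref_fixture()
  anc <- ancestral_gene(ref)
  plan <- ref$gene_plan
  mr0 <- splice_transcript(anc$gene, anc$genome)
  rep0 <- orf_report(mr0, plan$utr5_len)
  expect_identical(rep0$protein_length_reference,
                   plan$cds_len %/% 3L - 1L)
  expect_false(rep0$premature_stop)
  expect_false(rep0$non_stop)

  mr1 <- splice_transcript(anc$gene, anc$genome,
                           insertion_allele(anc$insertion_position,
                                            anc$element, anc$tsd_length))
  rep1 <- orf_report(mr1, plan$utr5_len)
  expect_true(rep1$premature_stop)
  expect_identical(rep1$stop_position_in_insertion, 41L)
  expect_identical(rep1$protein_length_insertion, 249L)
  expect_identical(rep1$protein_length_reference, 280L)
  expect_gt(rep1$lost_cds_fraction, 0.1)

  ## an insertion without in-frame stops flags an altered C-terminus
  ## rather than truncation: build one from non-stop codons
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  set.seed(71)
  ## pad the ends so no codon spanning the insertion junctions can be a
  ## stop at this locus (309 + 9 = 318 nt, a multiple of 3)
  benign <- paste0("CC", paste(sample(setdiff(codons, stops), 102,
                                      replace = TRUE), collapse = ""), "C")
  mr2 <- splice_transcript(anc$gene, anc$genome,
                           insertion_allele(anc$insertion_position,
                                            benign, 9L))
  rep2 <- orf_report(mr2, plan$utr5_len)
  expect_false(rep2$premature_stop)
  expect_identical(rep2$protein_length_insertion,
                   rep2$protein_length_reference + 318L %/% 3L)
})

test_that("primer efficiency follows the standard-curve formula", {
  expect_equal(primer_efficiency(-1 / log10(2)), 100, tolerance = 1e-9)
  expect_equal(primer_efficiency(-3.321928), 100, tolerance = 1e-3)
  expect_equal(primer_efficiency(-1), 900)
  expect_equal(primer_efficiency(-10), (10^0.1 - 1) * 100)
  expect_error(primer_efficiency(0), "nonzero")
})

test_that("relative expression is calibrated and scale free", {
  ct <- data.frame(accession = c("cal", "s1", "s2"),
                   ct_target = c(24, 25, 23.5),
                   ct_control = c(20, 20, 20))
  rq <- relative_expression(ct, calibrator = "cal")
  expect_identical(rq$rq[1], 1)
  expect_equal(rq$rq[2], 0.5)     # one cycle above the calibrator
  expect_equal(rq$rq[3], 2^1.5 / 2)
  ## adding a constant to every CT changes nothing
  ct2 <- ct
  ct2$ct_target <- ct2$ct_target + 3.7
  ct2$ct_control <- ct2$ct_control + 3.7
  expect_equal(relative_expression(ct2, "cal")$rq, rq$rq)
  ## missing CT rows are excluded with a warning
  ct3 <- rbind(ct, data.frame(accession = "bad", ct_target = NA,
                              ct_control = 20))
  expect_warning(rq3 <- relative_expression(ct3, "cal"), "excluded")
  expect_identical(nrow(rq3), 3L)
  expect_error(relative_expression(ct, "nope"), "calibrator")
})

test_that("one-way ANOVA with Tukey flags the shifted population", {
  set.seed(72)
  ## same-mean groups: no signal
  g0 <- data.frame(rq = rnorm(15, 1, 0.1), grp = rep(c("x", "y", "z"), 5))
  a0 <- anova_tukey(g0$rq, g0$grp)
  expect_gt(a0$p_value, 0.05)

  ## two far-apart groups: overwhelming signal
  g1 <- data.frame(rq = c(rnorm(5, 0, 0.1), rnorm(5, 10, 0.1)),
                   grp = rep(c("a", "b"), each = 5))
  a1 <- anova_tukey(g1$rq, g1$grp)
  expect_lt(a1$p_value, 1e-3)
  expect_lt(a1$tukey$p_adj[1], 0.001)

  ## a five-population design with one low population mirrors the
  ## population-specific expression drop
  set.seed(73)
  pops <- c("Hermon", "Amiad", "Tabgha", "Jaba", "Amasa")
  tab <- generate_ct_table(pops, 9, effects = c(1.2, 0, 0, 0, 0),
                           noise_sd = 0.3, seed = 74)
  rq <- relative_expression(tab, calibrator = "Amiad_1")
  at <- anova_tukey(rq$rq, rq$group)
  expect_lt(at$p_value, 0.05)
  herm <- at$tukey[grepl("Hermon", at$tukey$contrast), ]
  expect_true(any(herm$p_adj[grepl("Amiad", herm$contrast)] < 0.05))

  ## single-observation groups are excluded with a warning
  expect_warning(
    a2 <- anova_tukey(c(1, 2, 1.1, 2.1, 5), c("a", "b", "a", "b", "c")),
    "single observation")
  expect_equal(a2$df[1], 1)
})
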