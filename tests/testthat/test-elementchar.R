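test_that("the TSD detector finds the canonical 9-bp duplication", {
  up <- paste0(random_dna(40), "CCAAGAACT")
  down <- paste0("CCAAGAACT", random_dna(40))
  set.seed(41)
  call <- detect_tsd(up, down, k_min = 4, k_max = 15)
  expect_true(call$found)
  expect_identical(call$tsd_length, 9L)
  expect_identical(call$tsd_upstream, "CCAAGAACT")
  expect_identical(call$mismatches, 0L)

  ## a 2-bp duplication (the Fortuna-style TA site) at k_min = 2
  set.seed(42)
  up2 <- paste0(random_dna(30), "TA")
  down2 <- paste0("TA", random_dna(30))
  call2 <- detect_tsd(up2, down2, k_min = 2, k_max = 2)
  expect_true(call2$found)
  expect_identical(call2$tsd_upstream, "TA")

  ## flanks shorter than k_min: not found with a reason
  short <- detect_tsd("ACG", "ACG", k_min = 8, k_max = 12)
  expect_false(short$found)
  expect_match(short$reason, "shorter")
})

test_that("detect_tsd equals the brute-force (k, offset) search", {
  set.seed(43)
  for (i in 1:60) {
    up <- random_dna(30)
    down <- random_dna(30)
    if (i %% 3 == 0) {
      ## plant a duplication with random length and offsets
      k <- sample(8:12, 1)
      site <- random_dna(k)
      ou <- sample(0:2, 1); od <- sample(0:2, 1)
      substr(up, 30 - ou - k + 1, 30 - ou) <- site
      substr(down, od + 1, od + k) <- site
    }
    got <- detect_tsd(up, down, k_min = 8, k_max = 12)
    want <- brute_tsd(up, down)
    if (is.null(want)) {
      expect_false(got$found)
    } else {
      expect_true(got$found)
      expect_identical(got$tsd_length, want$k)
      expect_identical(got$mismatches, want$mm)
      expect_identical(got$offsets, want$off)
      expect_identical(got$tsd_upstream, want$seq)
    }
  }
})

test_that("TIR detection calls designed repeats and rejects random ends", {
  set.seed(44)
  core <- random_dna(200)
  tir <- "GGCCTTAACGTG"
  with_tir <- paste0(tir, core, revcomp(tir))
  call <- detect_tir(with_tir, min_tir = 10, max_window = 30,
                     min_identity = 80)
  expect_true(call$found)
  expect_gte(call$tir_length, 12)
  expect_equal(call$identity, 100)

  for (i in 1:5) expect_false(detect_tir(random_dna(307))$found)
  expect_false(detect_tir(mite_consensus())$found)
  expect_error(detect_tir(random_dna(15), min_tir = 10), "too short")
})

test_that("SINE hallmark screen detects constructed features only", {
  set.seed(45)
  tailpoly <- paste0(random_dna(290), strrep("A", 12), random_dna(5))
  expect_true(sine_features(tailpoly)$polyA_found)
  ## one interruption inside the run is tolerated
  broken <- paste0(random_dna(290), "AAAAGAAAA", random_dna(4))
  expect_true(sine_features(broken)$polyA_found)

  ## constructed internal Pol-III promoter: A box then B box 40 bp apart
  abox <- "TAGCAAAGTCAG"  # matches TRGCNNARYNNG
  bbox <- "GTTCGAATC"     # matches GTTCGANNC
  pol3 <- paste0(random_dna(10), abox, random_dna(40), bbox,
                 random_dna(240))
  rep <- sine_features(pol3)
  expect_true(rep$a_box_found)
  expect_true(rep$b_box_found)
  expect_true(rep$pol3_promoter)

  ## the consensus element carries none of the hallmarks
  neg <- sine_features(mite_consensus())
  expect_false(neg$polyA_found)
  expect_false(neg$pol3_promoter)
})

test_that("logo matrices have valid frequencies and entropy bounds", {
  ## identical sites: 2 bits at every column
  same <- rep("CCAAGAACT", 10)
  lg <- flank_logo(same)
  expect_true(all(abs(colSums(lg$freq) - 1) < 1e-9))
  expect_equal(unname(lg$ic), rep(2, 9))

  ## near-uniform columns approach zero information
  set.seed(46)
  unif <- vapply(1:4000, function(i) random_dna(6), character(1))
  expect_lt(max(flank_logo(unif)$ic), 0.01)

  ## permutation invariance across sequences
  sites <- vapply(1:30, function(i) random_dna(9), character(1))
  l1 <- flank_logo(sites)
  l2 <- flank_logo(sample(sites))
  expect_equal(l1$freq, l2$freq)
  expect_equal(l1$ic, l2$ic)

  ## conserved positions stand out against shuffled sites, matching a
  ## direct entropy computation
  set.seed(47)
  mixed <- c(rep("CCAAGAACT", 16),
             vapply(1:17, function(i)
               paste(sample(strsplit("CCAAGAACT", "")[[1]]), collapse = ""),
               character(1)))
  lm <- flank_logo(mixed)
  direct_ic <- apply(do.call(rbind, strsplit(mixed, "")), 2, function(col) {
    p <- table(factor(col, levels = c("A", "C", "G", "T"))) / length(col)
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
  expect_equal(unname(lm$ic), unname(direct_ic))
  expect_true(all(lm$ic >= 0 & lm$ic <= 2))

  expect_error(flank_logo(c("ACGT", "ACG")), "equal length")
})

test_that("pairwise identity uses global alignment columns", {
  expect_equal(pairwise_identity_matrix(c("ACGTACGTAC",
                                          "ACGTACGTAC"))$identity[1, 2], 100)
  ## one substitution in ten columns: 90%
  expect_equal(pairwise_identity_matrix(c("ACGTACGTAC",
                                          "ACGTACCTAC"))$identity[1, 2], 90)
  ## copies at 3% divergence from one consensus stay above 90% pairwise
  set.seed(48)
  copies <- vapply(1:8, function(i) mutate_seq(mite_consensus(), 0.03),
                   character(1))
  idm <- pairwise_identity_matrix(copies)
  expect_gte(idm$mean_identity, 90)
  expect_true(isSymmetric(idm$identity))
  expect_true(all(diag(idm$identity) == 100))
})

test_that("element classification follows the deterministic rule table", {
  set.seed(49)
  no_tsd <- detect_tsd(random_dna(30), random_dna(30))
  up <- paste0(random_dna(30), "CCAAGAACT")
  down <- paste0("CCAAGAACT", random_dna(30))
  tsd9 <- detect_tsd(up, down)
  tir_neg <- detect_tir(mite_consensus())
  tir_pos <- detect_tir(paste0("GGCCTTAACGTG", random_dna(200),
                               revcomp("GGCCTTAACGTG")))
  sine_neg <- sine_features(mite_consensus())
  sine_pos <- sine_features(paste0(random_dna(10), "TAGCAAAGTCAG",
                                   random_dna(40), "GTTCGAATC",
                                   random_dna(200), strrep("A", 12)))

  expect_identical(
    classify_element(tsd9, tir_neg, sine_neg, 307)$label,
    "Mutator-derived MITE candidate (TSD only)")
  expect_identical(
    classify_element(tsd9, tir_pos, sine_neg, 307)$label,
    "TIR-superfamily candidate (by TSD length)")
  expect_identical(
    classify_element(no_tsd, tir_neg, sine_pos, 307)$label,
    "SINE candidate")
  expect_identical(
    classify_element(no_tsd, tir_neg, sine_neg, 307)$label,
    "unclassified miniature element")
  ## pure function: identical reports give identical labels
  expect_identical(classify_element(tsd9, tir_neg, sine_neg, 307),
                   classify_element(tsd9, tir_neg, sine_neg, 307))
})
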