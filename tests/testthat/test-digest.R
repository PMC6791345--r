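test_that("a site-free linear molecule stays one fragment with blunt ends", {
  fr <- digest(strrep("ACGT", 250), "XbaI", registry = reg)
  expect_equal(nrow(fr), 1L)
  expect_equal(fr$left_kind, "terminal")
  expect_equal(fr$right_kind, "terminal")
  expect_equal(fr$left_polarity, "blunt")
  expect_equal(nchar(fr$top_seq), 1000L)
})

test_that("the plasmid amplicon digests into three fragments with the expected ends", {
  # amplicon between the 215F/774R primer sites of the bundled plasmid
  # stand-in; cut positions follow from the planted anchors:
  # EcoRI top cut at 396 (relative 182), XbaI at 423 (relative 209)
  p <- read_fasta(system.file("extdata", "pUC19_synthetic.fasta",
                              package = "triplerad"))
  amp <- substr(p$seq, 215, 774)
  expect_equal(nchar(amp), 560L)
  fr <- digest(amp, c("XbaI", "EcoRI-HF"), registry = reg)
  expect_equal(nrow(fr), 3L)
  expect_equal(fr$length, c(181L, 27L, 352L))
  mid <- fr[2, ]
  expect_equal(mid$left_enzyme, "EcoRI-HF")
  expect_equal(mid$right_enzyme, "XbaI")
  expect_equal(mid$left_overhang, "AATT")
  expect_equal(mid$right_overhang, "CTAG")
  expect_equal(paste0(fr$top_seq, collapse = ""), amp)
})

test_that("digestion conserves the top strand and fragment counts", {
  set.seed(42)
  for (i in 1:25) {
    s <- random_dna(50000)
    fr <- digest(s, c("XbaI", "EcoRI-HF", "NheI"), registry = reg)
    n_sites <- length(brute_force_sites(s, "TCTAGA")) +
      length(brute_force_sites(s, "GAATTC")) +
      length(brute_force_sites(s, "GCTAGC"))
    expect_equal(nrow(fr), n_sites + 1L)
    expect_equal(paste0(fr$top_seq, collapse = ""), s)
  }
  # the same conservation holds on many short sequences
  for (i in 1:100) {
    s <- random_dna(3000)
    fr <- digest(s, c("DdeI", "MseI"), registry = reg)
    expect_equal(paste0(fr$top_seq, collapse = ""), s)
  }
})

test_that("circular digestion yields k fragments and conserves sequence", {
  set.seed(11)
  s <- random_dna(30000)
  fr_l <- digest(s, c("XbaI", "EcoRI-HF"), registry = reg)
  fr_c <- digest(s, c("XbaI", "EcoRI-HF"), topology = "circular",
                 registry = reg)
  k <- nrow(fr_l) - 1L
  expect_equal(nrow(fr_c), k)
  expect_equal(sum(fr_c$length), nchar(s))
  expect_true(all(fr_c$left_kind == "cut"))
  # uncut circle
  un <- digest(strrep("A", 2000), "XbaI", topology = "circular",
               registry = reg)
  expect_equal(nrow(un), 1L)
})

test_that("re-digesting digest products makes no further cuts", {
  set.seed(13)
  s <- random_dna(40000)
  enzymes <- c("XbaI", "EcoRI-HF", "NheI")
  fr <- digest(s, enzymes, registry = reg)
  for (i in seq_len(nrow(fr))) {
    if (nchar(fr$top_seq[i]) < 10) next
    again <- digest(fr$top_seq[i], enzymes, registry = reg)
    expect_equal(nrow(again), 1L)
  }
})

test_that("intersecting cut intervals raise an ambiguity error", {
  # BfaI (C^TAG) cuts inside the XbaI site (T^CTAGA): intervals overlap
  s <- paste0(strrep("A", 100), "TCTAGA", strrep("A", 100))
  expect_error(digest(s, c("XbaI", "BfaI"), registry = reg), "ambiguous")
})

test_that("three-prime overhang digestion mirrors the five-prime case", {
  s <- paste0(strrep("A", 100), "CTGCAG", strrep("G", 100))
  fr <- digest(s, "PstI", registry = reg)
  expect_equal(nrow(fr), 2L)
  expect_equal(fr$right_overhang[1], "TGCA")
  expect_equal(fr$right_polarity[1], "three_prime")
  expect_equal(fr$left_overhang[2], "TGCA")
  expect_equal(paste0(fr$top_seq, collapse = ""), s)
})
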