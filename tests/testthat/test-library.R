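sim_constructs <- function(n_loci = 10, seed = 8, ...) {
  g <- make_locus_genome(n_loci, seed = seed)
  frags <- digest(g$seq, c("XbaI", "EcoRI-HF", "NheI"), registry = reg)
  digestion_ligation_cycle(frags, adapter_for(1, "read1", "A"),
                           adapter_for(1, "read2", "1"), reg,
                           sim_config(seed = seed, ...),
                           enzymes = c("XbaI", "EcoRI-HF", "NheI"))
}

test_that("amplification maps amplifiable constructs 1:1 and reports skips", {
  cons <- sim_constructs()
  n_amp <- sum(vapply(cons, amplifiable, logical(1)))
  mols <- pcr_amplify(cons, "TACCGCTA", "ACTTATAG", sim_config(seed = 8))
  expect_equal(nrow(mols), n_amp)
  expect_equal(attr(mols, "n_skipped"), length(cons) - n_amp)
  expect_true(all(mols$i5 == "TACCGCTA"))
  expect_true(all(mols$i7 == "ACTTATAG"))
  # total length decomposes into fixed segments + tags + insert
  expect_equal(mols$total_length,
               136L + nchar(mols$r1_tag) + nchar(mols$r1_post) +
                 nchar(mols$insert) + nchar(mols$r2_post) +
                 nchar(mols$r2_tag))
  expect_error(pcr_amplify(cons, "SHORT", "ACTTATAG"), "non-IUPAC|8 nt")
})

test_that("molecular ID tags are distinct fresh draws from the 8N space", {
  cons <- sim_constructs(n_loci = 15, seed = 21)
  mols <- pcr_amplify(cons, "TACCGCTA", "ACTTATAG",
                      sim_config(seed = 21, umi_mode = TRUE))
  expect_true(all(nchar(mols$umi) == 8L))
  expect_true(all(grepl("^[ACGT]{8}$", mols$umi)))
  expect_equal(anyDuplicated(mols$umi), 0L)
  again <- pcr_amplify(cons, "TACCGCTA", "ACTTATAG",
                       sim_config(seed = 21, umi_mode = TRUE))
  expect_identical(mols$umi, again$umi)  # deterministic under seed
})

test_that("size selection keeps the inclusive window 495-605 at 550 +/- 10%", {
  mols <- tibble::tibble(molecule_id = 1:6, total_length = c(494, 495, 550,
                                                             605, 606, 150))
  kept <- size_select(mols, 550, 0.10)
  expect_equal(kept$total_length, c(495, 550, 605))
  expect_equal(nrow(size_select(mols[0, ], 550, 0.10)), 0L)
  expect_error(size_select(mols, 550, 1.2), "tol")
  one <- tibble::tibble(total_length = 550)
  expect_equal(nrow(size_select(one, 550, 0)), 1L)
})

test_that("expected locus count matches Monte-Carlo digestion", {
  E <- expected_locus_count(50000, 0.5, "XbaI", registry = reg)
  set.seed(31)
  mc <- replicate(40, {
    nrow(digest(random_dna(50000), "XbaI", registry = reg))
  })
  se <- stats::sd(mc) / sqrt(length(mc))
  expect_lt(abs(mean(mc) - E), max(3 * se, 0.05 * mean(mc)))

  E2 <- expected_locus_count(50000, 0.5, c("XbaI", "EcoRI-HF"),
                             size_window = c(200, 3000), registry = reg)
  mc2 <- replicate(40, {
    fr <- digest(random_dna(50000), c("XbaI", "EcoRI-HF"), registry = reg)
    het <- !is.na(fr$left_enzyme) & !is.na(fr$right_enzyme) &
      fr$left_enzyme != fr$right_enzyme
    sum(het & fr$length >= 200 & fr$length <= 3000)
  })
  se2 <- stats::sd(mc2) / sqrt(length(mc2))
  expect_lt(abs(mean(mc2) - E2), max(3 * se2, 0.05 * max(mean(mc2), 1)))
})

test_that("expected locus count is zero at length zero and linear in length", {
  expect_equal(expected_locus_count(0, 0.5, "XbaI", registry = reg), 0)
  e1 <- expected_locus_count(1e6, 0.5, c("XbaI", "EcoRI-HF"), registry = reg)
  e2 <- expected_locus_count(2e6, 0.5, c("XbaI", "EcoRI-HF"), registry = reg)
  expect_equal(e2 / e1, 2, tolerance = 1e-9)
  # GC weighting moves AT-rich motifs as expected
  at_rich <- expected_locus_count(1e6, 0.3, "XbaI", registry = reg)
  gc_rich <- expected_locus_count(1e6, 0.7, "XbaI", registry = reg)
  expect_gt(at_rich, gc_rich)
})
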