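# The published adapter stub table: adapter name, then top and bottom oligo
# strings (case-sensitive; /5phos/ marks Read-1 bottom phosphorylation).
published_oligos <- list(
  list(d = 1, side = "read1", v = "A",
       top = "ACGACGCTCTTCCGATCTCCGAATG",
       bottom = "/5phos/CTAGCATTCGGAGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT"),
  list(d = 1, side = "read2", v = "1",
       top = "AATTACGTTAGAGATCGGAAGAGCACACGTaatcc",
       bottom = "GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCTCTAACGT"),
  list(d = 2, side = "read1", v = "B",
       top = "ACGACGCTCTTCCGATCTTTAGGCAAT",
       bottom = "/5phos/CGATTGCCTAAAGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT"),
  list(d = 2, side = "read2", v = "2",
       top = "GATCGGTACCGAAGATCGGAAGAGCACACGTaatcc",
       bottom = "GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCTTCGGTACC"),
  list(d = 3, side = "read1", v = "C",
       top = "ACGACGCTCTTCCGATCTAACTCGTCCTGCA",
       bottom = "/5phos/GGACGAGTTAGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT"),
  list(d = 3, side = "read2", v = "3",
       top = "TNACCAACGATCAGATCGGAAGAGCACACGTaatcc",
       bottom = "GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCTGATCGTTGG"),
  list(d = 4, side = "read1", v = "D",
       top = "ACGACGCTCTTCCGATCTGGTCTACGTG",
       bottom = "/5phos/TACACGTAGACCAGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT"),
  list(d = 4, side = "read2", v = "4",
       top = "AGCTAAGTGTAGCTAGATCGGAAGAGCACACGTaatcc",
       bottom = "GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCTAGCTACACTT")
)

test_that("build_adapter regenerates the published oligo strings byte-exactly", {
  for (po in published_oligos) {
    pair <- adapter_for(po$d, po$side, po$v)
    expect_identical(pair$top, po$top)
    expect_identical(pair$bottom, po$bottom)
  }
})

test_that("oligo names follow the published naming scheme", {
  a <- adapter_for(1, "read1", "A")
  expect_equal(a$name_top, "iTru_NheI_R1_stub_A")
  expect_equal(a$name_bottom, "iTru_NheI_R1_RCp_A")
  b <- adapter_for(1, "read2", "1")
  expect_equal(b$name_top, "iTru_EcoRI_R2_RC_stub_1")
  expect_equal(b$name_bottom, "iTru_EcoRI_R2_1")
  expect_true(a$bottom_phosphorylated)
  expect_false(b$bottom_phosphorylated)
})

test_that("build_adapter validates its inputs", {
  d1 <- design_side(1, "read1")
  expect_error(build_adapter(d1, ""), "non-empty")
  expect_error(build_adapter(d1, "CCGNAT"), "non-IUPAC")
  tg2 <- load_index_tags()
  wrong <- tg2[tg2$side == "read2", ][1, ]
  expect_error(build_adapter(d1, wrong), "side")
})

test_that("cut-site remnants follow the adapter-fragment junction arithmetic", {
  d1r1 <- design_side(1, "read1")
  d1r2 <- design_side(1, "read2")
  expect_equal(cutsite_remnant(d1r1, get_enzyme(reg, "XbaI")), "GCTAGA")
  expect_equal(cutsite_remnant(d1r1, get_enzyme(reg, "SpeI")), "GCTAGT")
  expect_equal(cutsite_remnant(d1r1, get_enzyme(reg, "NheI")), "GCTAGC")
  expect_equal(cutsite_remnant(d1r2, get_enzyme(reg, "EcoRI-HF")), "TAATTC")
  d3r1 <- design_side(3, "read1")
  expect_equal(cutsite_remnant(d3r1, get_enzyme(reg, "NsiI")), "CTGCAT")
  expect_equal(cutsite_remnant(d3r1, get_enzyme(reg, "PstI")), "CTGCAG")
})

test_that("Read-1 self-ligation recreates the blocking site exactly once", {
  blockers <- c(`1` = "NheI", `2` = "ClaI", `3` = "PstI", `4` = "CviQI")
  printed_r1 <- c(`1` = "A", `2` = "B", `3` = "C", `4` = "D")
  for (d in 1:4) {
    pair <- adapter_for(d, "read1", printed_r1[[as.character(d)]])
    sl <- simulate_self_ligation(pair, reg)
    expect_true(sl$possible)
    motif <- get_enzyme(reg, blockers[[as.character(d)]])$recognition
    n_block <- sum(sl$sites$matched_seq == motif |
                     grepl(paste0("^", blockers[[as.character(d)]]),
                           sl$sites$enzyme))
    hits <- sl$sites[grepl(paste0("^", blockers[[as.character(d)]]),
                           sub("-HF$", "", sl$sites$enzyme)), ]
    expect_equal(nrow(dplyr::distinct(hits, position)), 1L)
    # the site sits at the junction between the two adapters
    expect_true(all(abs(hits$position - sl$junction_at) < 8))
  }
})

test_that("unphosphorylated and blunt adapters cannot form dimers", {
  r2 <- adapter_for(1, "read2", "1")
  sl <- simulate_self_ligation(r2, reg)
  expect_false(sl$possible)
  expect_match(sl$reason, "unphosphorylated")

  blunt <- adapter_for(1, "read1", "A")
  blunt$overhang <- ""
  blunt$polarity <- "blunt"
  sl2 <- simulate_self_ligation(blunt, reg)
  expect_false(sl2$possible)
  expect_match(sl2$reason, "no dimer possible")
})
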