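cfg_fast <- function(...) sim_config(seed = 5, read_length = 75, ...)

test_that("full recutting leaves no surviving adapter-dimers", {
  r1 <- adapter_for(1, "read1", "A")
  r2 <- adapter_for(1, "read2", "1")
  cons <- digestion_ligation_cycle(
    no_site_fragments(), r1, r2, reg,
    cfg_fast(recut_probability = 1, ligation_efficiency = 1,
             adapter_excess = 20),
    enzymes = c("XbaI", "EcoRI-HF", "NheI"))
  classes <- vapply(cons, function(x) x$construct_class, character(1))
  expect_equal(sum(classes == "adapter_dimer"), 0L)
})

test_that("without recutting, dimers match the analytic pairing count", {
  # 2n phosphorylated Read-1 adapters with ligation efficiency 1 pair into
  # exactly n dimers
  r1 <- adapter_for(1, "read1", "A")
  cons <- digestion_ligation_cycle(
    no_site_fragments(), r1, NULL, reg,
    cfg_fast(recut_probability = 0, ligation_efficiency = 1,
             adapter_excess = 20),
    enzymes = c("XbaI", "EcoRI-HF", "NheI"))
  classes <- vapply(cons, function(x) x$construct_class, character(1))
  expect_equal(sum(classes == "adapter_dimer"), 10L)
  expect_equal(length(cons), 10L)
})

test_that("Read-2 adapters never self-ligate in the cycle", {
  r2 <- adapter_for(1, "read2", "1")
  cons <- digestion_ligation_cycle(
    no_site_fragments(), NULL, r2, reg,
    cfg_fast(recut_probability = 0, ligation_efficiency = 1,
             adapter_excess = 20),
    enzymes = c("XbaI", "EcoRI-HF", "NheI"))
  classes <- vapply(cons, function(x) x$construct_class, character(1))
  expect_equal(sum(classes == "adapter_dimer"), 0L)
  expect_equal(length(cons), 20L)  # all stay free adapters
})

test_that("cycling is deterministic under a fixed seed", {
  g <- make_locus_genome(8, seed = 3)
  frags <- digest(g$seq, c("XbaI", "EcoRI-HF", "NheI"), registry = reg)
  r1 <- adapter_for(1, "read1", "A")
  r2 <- adapter_for(1, "read2", "1")
  run <- function() {
    cons <- digestion_ligation_cycle(frags, r1, r2, reg, cfg_fast(),
                                     enzymes = c("XbaI", "EcoRI-HF", "NheI"))
    vapply(cons, function(x) paste(x$construct_class,
                                   substr(mol_core_seq_test(x), 1, 40)),
           character(1))
  }
  mol_core_seq_test <- triplerad:::mol_core_seq
  expect_identical(run(), run())
})

test_that("construct classification follows the product rules", {
  g <- make_locus_genome(10, third_every = 5, seed = 4)
  frags <- digest(g$seq, c("XbaI", "EcoRI-HF", "NheI"), registry = reg)
  r1 <- adapter_for(1, "read1", "A")
  r2 <- adapter_for(1, "read2", "1")
  cons <- digestion_ligation_cycle(
    frags, r1, r2, reg,
    cfg_fast(recut_probability = 0, ligation_efficiency = 1),
    enzymes = c("XbaI", "EcoRI-HF", "NheI"))
  classes <- vapply(cons, function(x) x$construct_class, character(1))
  expect_true(all(classes %in% c("desired", "third_site_locus",
                                 "adapter_dimer", "chimera", "dead")))
  expect_gt(sum(classes == "desired"), 0)
  expect_gt(sum(classes == "third_site_locus"), 0)
  # desired molecules: XbaI junction on the Read-1 side
  for (m in cons[classes == "desired"]) {
    types <- vapply(m$units, function(e) e$u$type, character(1))
    expect_length(types, 3L)
    expect_setequal(types[c(1, 3)], c("r1", "r2"))
  }
  # third-site loci carry a blocking-enzyme end
  for (m in cons[classes == "third_site_locus"]) {
    enz <- c(vapply(m$units, function(e) {
      if (e$u$type == "fragment") {
        paste(e$u$end_l$enzyme, e$u$end_r$enzyme)
      } else ""
    }, character(1)))
    expect_true(any(grepl("NheI", enz)))
  }
})

test_that("amplifiability requires class and an intact bottom strand", {
  g <- make_locus_genome(6, seed = 6)
  frags <- digest(g$seq, c("XbaI", "EcoRI-HF", "NheI"), registry = reg)
  r1 <- adapter_for(1, "read1", "A")
  r2 <- adapter_for(1, "read2", "1")
  cons <- digestion_ligation_cycle(frags, r1, r2, reg, cfg_fast(),
                                   enzymes = c("XbaI", "EcoRI-HF", "NheI"))
  classes <- vapply(cons, function(x) x$construct_class, character(1))
  ok <- cons[classes == "desired"]
  expect_true(length(ok) > 0)
  expect_true(all(vapply(ok, amplifiable, logical(1))))
  nicked <- ok[[1]]
  nicked$bottom_ok <- FALSE
  expect_false(amplifiable(nicked))
  dimer <- cons[classes == "adapter_dimer"]
  if (length(dimer)) expect_false(amplifiable(dimer[[1]]))
  # an un-ligated nick everywhere -> nothing amplifies
  cons2 <- digestion_ligation_cycle(frags, r1, r2, reg,
                                    cfg_fast(nick_probability = 1),
                                    enzymes = c("XbaI", "EcoRI-HF", "NheI"))
  expect_false(any(vapply(cons2, amplifiable, logical(1))))
})
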