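small_library <- function(seed = 9, n_loci = 12, third_every = 0,
                          error_rate = 0, ...) {
  g <- make_locus_genome(n_loci, third_every = third_every, seed = seed)
  layout <- make_plate_layout(design = 1, rows = c("A", "B"), cols = 1:2,
                              i5 = "TACCGCTA", i7 = "ACTTATAG")
  cfg <- sim_config(seed = seed, error_rate = error_rate, ...)
  list(mols = simulate_library(g, layout, config = cfg), cfg = cfg,
       layout = layout)
}

test_that("error-free reads start with the well's tag and intended remnant", {
  lib <- small_library(read_length = 100, depth = 3,
                       recut_probability = 0.9)
  sim <- generate_reads(lib$mols, lib$cfg)
  expect_gt(nrow(sim$reads), 0)
  joined <- dplyr::left_join(sim$truth, lib$layout,
                             by = c(well = "well"))
  tag1 <- joined$r1_tag
  tag2 <- joined$r2_tag
  desired <- joined$construct_class == "desired"
  expect_true(all(startsWith(sim$reads$r1[desired],
                             paste0(tag1[desired], "GCTAGA"))))
  expect_true(all(startsWith(sim$reads$r2, paste0(tag2, "TAATTC"))))
  third <- joined$construct_class == "third_site_locus"
  if (any(third)) {
    expect_true(all(startsWith(sim$reads$r1[third],
                               paste0(tag1[third], "GCTAGC"))))
  }
  expect_true(all(nchar(sim$reads$r1) == 100L))
  expect_true(all(sim$reads$i1 == "ACTTATAG"))
  expect_true(all(sim$reads$i2 == "TACCGCTA"))
})

test_that("short inserts read through into the opposite adapter", {
  mols <- tibble::tibble(
    molecule_id = 1L, sample_id = "s", well = "A01",
    construct_class = "desired", i5 = "TACCGCTA", i7 = "ACTTATAG",
    umi = NA_character_, r1_tag = "CCGAAT", r1_post = "G",
    r2_tag = "CTAACG", r2_post = "T",
    insert = "CTAGACCCGG", total_length = 160L)
  cfg <- sim_config(seed = 1, read_length = 40, depth = 1,
                    depth_model = "fixed", error_rate = 0)
  sim <- generate_reads(mols, cfg)
  r1 <- sim$reads$r1
  # tag (6) + post+insert (11) then reverse complement of the Read-2 side
  expect_equal(substr(r1, 1, 17), "CCGAATGCTAGACCCGG")
  expect_equal(substr(r1, 18, 18 + 6), substr(
    paste0(triplerad:::revcomp("T"), triplerad:::revcomp("CTAACG"),
           triplerad:::revcomp(triplerad:::R2_STUB_BOTTOM)), 1, 7))
})

test_that("depth zero produces empty streams and seeds give identical FASTQ", {
  lib <- small_library(read_length = 75, depth = 0, depth_model = "fixed")
  sim0 <- generate_reads(lib$mols, lib$cfg)
  expect_equal(nrow(sim0$reads), 0L)

  lib2 <- small_library(read_length = 75, depth = 2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- generate_reads(lib2$mols, lib2$cfg)
  s2 <- generate_reads(lib2$mols, lib2$cfg)
  write_fastq_quads(s1$reads, d1)
  write_fastq_quads(s2$reads, d2)
  for (f in c("sim_R1.fastq", "sim_R2.fastq", "sim_I1.fastq",
              "sim_I2.fastq")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("fastq quad IO round-trips and detects desynchronised streams", {
  lib <- small_library(read_length = 75, depth = 2)
  sim <- generate_reads(lib$mols, lib$cfg)
  d <- withr::local_tempdir()
  paths <- write_fastq_quads(sim$reads, d)
  back <- read_fastq_quads(paths["r1"], paths["r2"], paths["i1"],
                           paths["i2"])
  expect_equal(back$r1, sim$reads$r1)
  expect_equal(back$i2, sim$reads$i2)
  # shuffle one stream -> hard error naming the offending record
  x <- readLines(paths[["i1"]])
  swapped <- c(x[5:8], x[1:4], x[-(1:8)])
  writeLines(swapped, paths[["i1"]])
  expect_error(read_fastq_quads(paths["r1"], paths["r2"], paths["i1"],
                                paths["i2"]),
               "desynchronised")
})

test_that("substitution errors appear at the configured rate", {
  lib <- small_library(read_length = 100, depth = 4, error_rate = 0.02)
  sim_err <- generate_reads(lib$mols, lib$cfg)
  cfg0 <- lib$cfg
  cfg0$error_rate <- 0
  sim_clean <- generate_reads(lib$mols, cfg0)
  mm <- mapply(function(a, b) {
    sum(strsplit(a, NULL)[[1]] != strsplit(b, NULL)[[1]])
  }, sim_err$reads$r1, sim_clean$reads$r1)
  rate <- sum(mm) / (100 * length(mm))
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.05)
})
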