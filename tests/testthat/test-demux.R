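plate_pairs <- tibble::tibble(plate_id = c("p1", "p2"),
                              i5 = c("TACCGCTA", "ACTTATAG"),
                              i7 = c("ACTTATAG", "GGCGCGAG"))

test_that("external index assignment tolerates mismatches and refuses ties", {
  expect_equal(assign_external("ACTTATAG", "TACCGCTA", plate_pairs, tol = 0),
               "p1")
  # one mismatch in i7, tol 1 -> still assigned (distance-3 code)
  expect_equal(assign_external("ACTTATAC", "TACCGCTA", plate_pairs, tol = 1),
               "p1")
  expect_true(is.na(assign_external("ACTTATAC", "TACCGCTA", plate_pairs,
                                    tol = 0)))
  # i5 matching disabled in molecular-ID-tag mode
  expect_equal(assign_external("ACTTATAG", "NNNNNNNN", plate_pairs, tol = 0,
                               match_i5 = FALSE), "p1")
  # equidistant candidates -> unassigned
  amb <- tibble::tibble(plate_id = c("a", "b"),
                        i5 = c("AAAAAAAA", "AAAAAAAA"),
                        i7 = c("AAACCCGG", "AAACCGGG"))
  expect_error(assign_external("AAACCCGG", "AAAAAAAA", amb, tol = 1),
               "distance 3")
  amb2 <- tibble::tibble(plate_id = c("a", "b"),
                         i5 = c("AAAAAAAA", "AAAAAAAA"),
                         i7 = c("CCCCAAAA", "CCCCTTTT"))
  # read equidistant from both candidates stays unassigned
  expect_true(is.na(assign_external("CCCCAATT", "AAAAAAAA", amb2, tol = 2)))
})

test_that("internal assignment resolves wells and reports failure reasons", {
  layout <- make_plate_layout(design = 1, rows = c("A", "B"), cols = 1:2,
                              i5 = "TACCGCTA", i7 = "ACTTATAG")
  tagA <- layout$r1_tag[layout$r1_version == "A"][1]
  tag1 <- layout$r2_tag[layout$r2_version == "1"][1]
  r1_ok <- paste0(tagA, "GCTAGA", strrep("ACGT", 20))
  r2_ok <- paste0(tag1, "TAATTC", strrep("TGCA", 20))
  res <- assign_internal(r1_ok, r2_ok, layout)
  expect_equal(res$well, "A01")
  expect_equal(res$classification, "intended")

  # valid tag but broken remnant -> no cut-site
  r1_bad <- paste0(tagA, "GCTGGA", strrep("ACGT", 20))
  res2 <- assign_internal(r1_bad, r2_ok, layout)
  expect_true(is.na(res2$well))
  expect_equal(res2$reason, "no_cutsite")

  # unknown tag -> no_tag
  res3 <- assign_internal(paste0("TTTTTT", "GCTAGA", strrep("A", 60)),
                          r2_ok, layout)
  expect_equal(res3$reason, "no_tag")

  # third-enzyme remnant still assigns, classified third_enzyme
  r1_third <- paste0(tagA, "GCTAGC", strrep("ACGT", 20))
  res4 <- assign_internal(r1_third, r2_ok, layout)
  expect_equal(res4$well, "A01")
  expect_equal(res4$classification, "third_enzyme")
})

test_that("prefix tags are disambiguated by the remnant position", {
  layout <- make_plate_layout(design = 1, rows = c("A", "B"), cols = 1:2,
                              i5 = "TACCGCTA", i7 = "ACTTATAG")
  # make tag B a one-base extension of tag A: only the remnant position
  # decides which version produced the read
  layout$r1_tag[layout$r1_version == "A"] <- "CCGAAT"
  layout$r1_tag[layout$r1_version == "B"] <- "CCGAATA"
  tag1 <- layout$r2_tag[layout$r2_version == "1"][1]
  r2_ok <- paste0(tag1, "TAATTC", strrep("TG", 40))
  shortread <- paste0("CCGAAT", "GCTAGA", "TTTT", strrep("C", 60))
  longread <- paste0("CCGAATA", "GCTAGA", "TTTT", strrep("C", 60))
  res_s <- assign_internal(shortread, r2_ok, layout)
  res_l <- assign_internal(longread, r2_ok, layout)
  expect_equal(res_s$well, "A01")
  expect_equal(res_l$well, "B01")
})

test_that("cut-site checking distinguishes intended, third and failures", {
  remn <- list(r1_intended = "GCTAGA", r1_third = "GCTAGC")
  expect_equal(check_cutsite(c("GCTAGA", "GCTAGC", "GCTGGA"), remn, "exact"),
               c("intended", "third_enzyme", "fail"))
  # rescue1 rescues one mismatch to intended, but exact third stays third
  expect_equal(check_cutsite(c("GCTGGA", "GCTAGC"), remn, "rescue1"),
               c("intended", "third_enzyme"))
  expect_equal(check_cutsite("GGTGGA", remn, "rescue1"), "fail")
  # disabled never fails; unrecognised remnants pass through flagged
  expect_equal(check_cutsite(c("GCTAGA", "GCTAGC", "TTTTTT"), remn,
                             "disabled"),
               c("intended", "third_enzyme", "passthrough"))
  # degenerate patterns (DdeI-style) match through IUPAC codes
  remn_deg <- list(r1_intended = "GTNAG", r1_third = NULL)
  expect_equal(check_cutsite(c("GTCAG", "GTTAG", "GACAG"), remn_deg,
                             "exact"),
               c("intended", "intended", "fail"))
})

test_that("clone filtering recovers planted molecule counts", {
  reads <- tibble::tibble(
    read_id = sprintf("r%02d", 1:9),
    r1 = rep(c(paste0("CCGAATGCTAGA", strrep("A", 30)),
               paste0("CCGAATGCTAGA", strrep("C", 30)),
               paste0("CCGAATGCTAGA", strrep("G", 30))), each = 3),
    r2 = rep(c(paste0("CTAACGTAATTC", strrep("T", 30)),
               paste0("CTAACGTAATTC", strrep("G", 30)),
               paste0("CTAACGTAATTC", strrep("A", 30))), each = 3),
    i1 = "ACTTATAG",
    i2 = rep(c("AAAACCCC", "CCCCAAAA", "GGGGTTTT"), each = 3)
  )
  res <- clone_filter(reads, demux_config(umi_mode = TRUE))
  expect_equal(res$n_unique, 3L)
  expect_equal(res$duplicate_fraction, 2 / 3)

  # all distinct -> nothing removed
  distinct_reads <- reads[c(1, 4, 7), ]
  res2 <- clone_filter(distinct_reads, demux_config(umi_mode = TRUE))
  expect_equal(res2$duplicate_fraction, 0)

  # same 8N tag, different inserts -> both retained
  shared <- reads[c(1, 4), ]
  shared$i2 <- "AAAACCCC"
  res3 <- clone_filter(shared, demux_config(umi_mode = TRUE))
  expect_equal(res3$n_unique, 2L)

  expect_error(clone_filter(reads[, c("read_id", "r1", "r2")],
                            demux_config(umi_mode = TRUE)),
               "I2")
})

test_that("demux_run partitions every read into exactly one bin", {
  g <- make_locus_genome(15, third_every = 5, seed = 12)
  layout <- make_plate_layout(design = 1, rows = c("A", "B"), cols = 1:3,
                              i5 = "TACCGCTA", i7 = "ACTTATAG")
  cfg <- sim_config(seed = 12, error_rate = 0, depth = 3,
                    recut_probability = 0)
  mols <- simulate_library(g, layout, config = cfg)
  sim <- generate_reads(mols, cfg)
  stats <- demux_run(sim$reads, layout, demux_config(radcheck_mode = "exact"))
  binned <- stats$reads
  expect_equal(nrow(binned), nrow(sim$reads))
  bins <- table(binned$bin)
  expect_equal(sum(bins), nrow(sim$reads))
  expect_equal(stats$n_input, nrow(sim$reads))
  expect_equal(sum(stats$per_sample$n_reads) +
                 sum(stats$unassigned$n), stats$n_input)

  # error-free exact mode: all desired reads to their true samples,
  # all third-site reads in the third_enzyme bin
  tr <- dplyr::left_join(binned, sim$truth, by = "read_id")
  desired <- tr[tr$construct_class == "desired", ]
  expect_true(all(desired$bin == desired$sample_id.y))
  third <- tr[tr$construct_class == "third_site_locus", ]
  expect_true(all(third$bin == "third_enzyme"))

  # disabled mode keeps third-site reads in their samples
  stats_d <- demux_run(sim$reads, layout,
                       demux_config(radcheck_mode = "disabled"))
  tr_d <- dplyr::left_join(stats_d$reads, sim$truth, by = "read_id")
  third_d <- tr_d[tr_d$construct_class == "third_site_locus", ]
  expect_true(all(third_d$bin == third_d$sample_id.y))
  expect_gt(stats_d$third_enzyme_fraction, 0)

  # empty input -> empty stats
  empty <- demux_run(sim$reads[0, ], layout, demux_config())
  expect_equal(empty$n_input, 0L)
  expect_equal(nrow(empty$per_sample), 0L)
})

test_that("tidy and glance summarise demux stats", {
  g <- make_locus_genome(8, seed = 14)
  layout <- make_plate_layout(design = 1, rows = "A", cols = 1:2,
                              i5 = "TACCGCTA", i7 = "ACTTATAG")
  cfg <- sim_config(seed = 14, error_rate = 0, depth = 2)
  mols <- simulate_library(g, layout, config = cfg)
  sim <- generate_reads(mols, cfg)
  stats <- demux_run(sim$reads, layout, demux_config())
  td <- tidy(stats)
  expect_true(all(c("sample_id", "n_reads", "third_fraction") %in% names(td)))
  gl <- glance(stats)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$n_input, nrow(sim$reads))
  tp <- third_enzyme_proportion(stats)
  expect_true(is.numeric(tp$pooled))
})

test_that("rescued assignment never misassigns at 1% error", {
  g <- make_locus_genome(20, seed = 15)
  layout <- make_plate_layout(design = 1, rows = c("A", "B"), cols = 1:2,
                              i5 = "TACCGCTA", i7 = "ACTTATAG")
  cfg <- sim_config(seed = 15, error_rate = 0.01, depth = 4)
  mols <- simulate_library(g, layout, config = cfg)
  sim <- generate_reads(mols, cfg)
  stats <- demux_run(sim$reads, layout,
                     demux_config(radcheck_mode = "rescue1",
                                  internal_mismatch_tol = 1))
  tr <- dplyr::left_join(stats$reads, sim$truth, by = "read_id")
  assigned <- tr[!startsWith(tr$bin, "unassigned") &
                   tr$bin != "third_enzyme", ]
  # errors may only push reads to unassigned, never to the wrong sample
  expect_true(all(assigned$sample_id.x == assigned$sample_id.y))
  expect_gte(nrow(assigned) / nrow(tr), 0.90)
})
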