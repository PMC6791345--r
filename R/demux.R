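#' Demultiplexing configuration
#'
#' @param external_mismatch_tol Mismatches tolerated per external (i5/i7)
#'   index, 0-2.
#' @param internal_mismatch_tol Mismatches tolerated in the internal tag,
#'   0-1.
#' @param radcheck_mode Cut-site remnant handling: `"exact"` (only the
#'   intended remnant passes; exact third-enzyme remnants are routed to a
#'   third-enzyme bin), `"rescue1"` (one mismatch to the intended remnant is
#'   rescued, but an exact third-enzyme remnant always classifies as
#'   third-enzyme), or `"disabled"` (no remnant filtering; remnants are
#'   still classified by exact match, everything else passes through
#'   flagged).
#' @param trim_tags Remove tag + remnant from emitted reads so output reads
#'   start at the first genomic base.
#' @param umi_mode Expect the I2 stream to carry 8N molecular ID tags.
#' @param umi_key_length Bases of R1/R2 prefix used in the duplicate key.
#' @param design Adapter design number in use.
#' @param enzymes Named character vector `c(read1=, read2=, blocking=)`
#'   giving the enzyme combination the library was built with.
#' @return List of class `demux_config`.
#' @export
demux_config <- function(external_mismatch_tol = 1L,
                         internal_mismatch_tol = 0L,
                         radcheck_mode = c("exact", "rescue1", "disabled"),
                         trim_tags = TRUE,
                         umi_mode = FALSE,
                         umi_key_length = 30L,
                         design = 1L,
                         enzymes = c(read1 = "XbaI", read2 = "EcoRI-HF",
                                     blocking = "NheI")) {
  radcheck_mode <- arg_match(radcheck_mode)
  if (external_mismatch_tol < 0 || external_mismatch_tol > 2) {
    abort("external_mismatch_tol must be 0-2")
  }
  if (internal_mismatch_tol < 0 || internal_mismatch_tol > 1) {
    abort("internal_mismatch_tol must be 0-1")
  }
  structure(list(external_mismatch_tol = as.integer(external_mismatch_tol),
                 internal_mismatch_tol = as.integer(internal_mismatch_tol),
                 radcheck_mode = radcheck_mode, trim_tags = trim_tags,
                 umi_mode = umi_mode,
                 umi_key_length = as.integer(umi_key_length),
                 design = as.integer(design), enzymes = enzymes),
            class = "demux_config")
}

# Hamming distances of fixed-length reads against one reference
hamming_to <- function(obs, ref) {
  k <- nchar(ref)
  obs <- substr(obs, 1L, k)
  short <- nchar(obs) < k
  rch <- strsplit(ref, NULL)[[1]]
  d <- integer(length(obs))
  for (p in seq_len(k)) {
    d <- d + (substr(obs, p, p) != rch[p])
  }
  d[short] <- k
  d
}

#' Assign reads to plates by external indexes
#'
#' Matches the two index reads against a table of expected (i5, i7) pairs.
#' A read is assigned when exactly one pair is within `tol` mismatches on
#' both indexes; ties and non-matches return `NA` (unassigned). The pair
#' table must itself be a distance-3 code per side, which is validated up
#' front.
#'
#' @param i1,i2 Character vectors: the I1 (= i7) and I2 (= i5) index reads.
#' @param pairs Tibble with columns `plate_id`, `i5`, `i7` (one row per
#'   expected pair).
#' @param tol Mismatches tolerated per index (0-2).
#' @param match_i5 When `FALSE` (molecular-ID-tag libraries, where the I2
#'   read carries the 8N tag instead of the i5 index) only the i7 index is
#'   matched.
#' @return Character vector of `plate_id` or `NA`.
#' @export
assign_external <- function(i1, i2, pairs, tol = 1L, match_i5 = TRUE) {
  pairs <- distinct(as_tibble(pairs), plate_id, i5, i7)
  for (side in c("i5", "i7")) {
    u <- unique(pairs[[side]])
    if (length(u) >= 2 && min_pairwise_edit_distance(u) < 3) {
      abort(sprintf("primer table validation error: %s indexes closer than edit distance 3", side))
    }
  }
  n <- length(i1)
  best <- rep(NA_character_, n)
  best_d <- rep(Inf, n)
  tie <- rep(FALSE, n)
  for (p in seq_len(nrow(pairs))) {
    d7 <- hamming_to(i1, pairs$i7[p])
    d5 <- if (match_i5) hamming_to(i2, pairs$i5[p]) else 0L
    d <- d7 + d5
    ok <- d7 <= tol & d5 <= tol
    better <- ok & d < best_d
    equal <- ok & d == best_d & !is.na(best) & best != pairs$plate_id[p]
    tie[equal] <- TRUE
    best[better] <- pairs$plate_id[p]
    best_d[better] <- d[better]
    tie[better] <- FALSE
  }
  best[tie] <- NA_character_
  best
}

# expected remnants for a design + enzyme combination
remnant_set <- function(config,
                        designs = load_adapter_designs(),
                        registry = load_enzyme_registry(quiet = TRUE)) {
  d1 <- designs[designs$design == config$design & designs$side == "read1", ]
  d2 <- designs[designs$design == config$design & designs$side == "read2", ]
  e1 <- get_enzyme(registry, config$enzymes[["read1"]])
  e2 <- get_enzyme(registry, config$enzymes[["read2"]])
  e3 <- if (!is.na(config$enzymes["blocking"]) &&
            nzchar(config$enzymes[["blocking"]])) {
    get_enzyme(registry, config$enzymes[["blocking"]])
  } else NULL
  list(
    r1_intended = cutsite_remnant(d1, e1),
    r1_third = if (!is.null(e3)) cutsite_remnant(d1, e3) else NULL,
    r2_intended = cutsite_remnant(d2, e2)
  )
}

# full-string IUPAC match of observed remnants against a pattern
rem_matches <- function(obs, pattern) {
  grepl(paste0("^", iupac_regex(pattern), "$"), obs)
}

# <= 1 mismatch against an IUPAC pattern, vectorised
rem_matches_1mm <- function(obs, pattern) {
  hit <- rem_matches(obs, pattern)
  k <- nchar(pattern)
  ch <- strsplit(pattern, NULL)[[1]]
  for (p in seq_len(k)) {
    alt <- ch
    alt[p] <- "N"
    hit <- hit | rem_matches(obs, paste(alt, collapse = ""))
  }
  hit
}

#' Classify the cut-site remnant of Read-1 sequences
#'
#' Inspects the bases following the internal tag and classifies each read:
#' `intended` (the first enzyme's remnant), `third_enzyme` (the blocking
#' enzyme's remnant, always by exact match so sequencing errors cannot
#' inflate the third-enzyme fraction), `fail`, or - in `disabled` mode -
#' `passthrough` for any other sequence.
#'
#' @param remnant_obs Character vector of observed remnant bases (already
#'   cut out of the read, tag removed).
#' @param remnants A [remnant_set()]-style list (`r1_intended`, `r1_third`).
#' @param mode `"exact"`, `"rescue1"` or `"disabled"`.
#' @return Character vector with levels `intended`, `third_enzyme`, `fail`,
#'   `passthrough`.
#' @export
check_cutsite <- function(remnant_obs, remnants,
                          mode = c("exact", "rescue1", "disabled")) {
  mode <- arg_match(mode)
  out <- rep("fail", length(remnant_obs))
  is_third <- if (!is.null(remnants$r1_third)) {
    rem_matches(remnant_obs, remnants$r1_third)
  } else rep(FALSE, length(remnant_obs))
  is_int <- rem_matches(remnant_obs, remnants$r1_intended)
  if (mode == "rescue1") {
    is_int <- is_int | (rem_matches_1mm(remnant_obs, remnants$r1_intended) &
                          !is_third)
  }
  out[is_int & !is_third] <- "intended"
  out[is_third] <- "third_enzyme"
  if (mode == "disabled") out[out == "fail"] <- "passthrough"
  out
}

# internal assignment engine: returns per-read version calls and remnant
# classes for one side
match_side <- function(reads, tags, remnant_patterns, tol, mode,
                       third_pattern = NULL) {
  n <- length(reads)
  n_hit <- integer(n)
  version <- rep(NA_character_, n)
  tag_len <- integer(n)
  rem_class <- rep(NA_character_, n)
  any_tag <- logical(n)
  for (v in names(tags)) {
    tg <- tags[[v]]
    lt <- nchar(tg)
    obs_tag <- substr(reads, 1L, lt)
    ok_tag <- obs_tag == tg
    if (tol > 0) {
      u <- unique(obs_tag[!ok_tag])
      if (length(u)) {
        du <- utils::adist(u, tg)
        near <- u[du <= tol]
        if (length(near)) ok_tag <- ok_tag | obs_tag %in% near
      }
    }
    any_tag <- any_tag | ok_tag
    rem_len <- nchar(remnant_patterns$intended)
    obs_rem <- substr(reads, lt + 1L, lt + rem_len)
    cls <- check_cutsite(obs_rem,
                         list(r1_intended = remnant_patterns$intended,
                              r1_third = third_pattern),
                         mode)
    ok <- ok_tag & (cls != "fail")
    n_hit <- n_hit + ok
    version[ok] <- v
    tag_len[ok] <- lt
    rem_class[ok] <- cls[ok]
  }
  list(n_hit = n_hit, version = version, tag_len = tag_len,
       rem_class = rem_class, any_tag = any_tag)
}

#' Assign reads to wells by internal indexes and cut-site remnants
#'
#' Resolves the variable-length internal tags by testing every candidate tag
#' and requiring a valid cut-site remnant immediately after it (tag within
#' `internal_mismatch_tol`; remnant per `radcheck_mode`). A read is assigned
#' to the unique well consistent with both mates; anything else is
#' unassigned with a reason.
#'
#' @param r1,r2 Character vectors of read sequences.
#' @param layout Plate layout (wells in the read's plate).
#' @param config [demux_config()].
#' @param designs,registry Bundled tables by default.
#' @return Tibble: `well`, `sample_id`, `classification` (remnant class of
#'   Read 1), `r1_trim_at`, `r2_trim_at` (1-based first genomic base),
#'   `reason` (`NA` when assigned).
#' @export
assign_internal <- function(r1, r2, layout, config = demux_config(),
                            designs = load_adapter_designs(),
                            registry = load_enzyme_registry(quiet = TRUE)) {
  rem <- remnant_set(config, designs, registry)
  t1 <- setNames(unique(layout$r1_tag), unique(layout$r1_tag))
  names(t1) <- layout$r1_version[match(t1, layout$r1_tag)]
  t2 <- setNames(unique(layout$r2_tag), unique(layout$r2_tag))
  names(t2) <- layout$r2_version[match(t2, layout$r2_tag)]

  m1 <- match_side(r1, t1, list(intended = rem$r1_intended),
                   config$internal_mismatch_tol, config$radcheck_mode,
                   third_pattern = rem$r1_third)
  m2 <- match_side(r2, t2, list(intended = rem$r2_intended),
                   config$internal_mismatch_tol, config$radcheck_mode,
                   third_pattern = NULL)

  n <- length(r1)
  well <- rep(NA_character_, n)
  sample_id <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  key <- paste(m1$version, m2$version)
  lk <- setNames(seq_len(nrow(layout)),
                 paste(layout$r1_version, layout$r2_version))
  ok <- m1$n_hit == 1L & m2$n_hit == 1L & key %in% names(lk)
  idx <- lk[key[ok]]
  well[ok] <- layout$well[idx]
  sample_id[ok] <- layout$sample_id[idx]
  reason[!ok & (m1$n_hit > 1L | m2$n_hit > 1L)] <- "ambiguous_tag"
  reason[!ok & is.na(reason) & (!m1$any_tag | !m2$any_tag)] <- "no_tag"
  reason[!ok & is.na(reason) &
           ((m1$any_tag & m1$n_hit == 0L) |
              (m2$any_tag & m2$n_hit == 0L))] <- "no_cutsite"
  reason[!ok & is.na(reason)] <- "no_well"

  rem_len1 <- nchar(rem$r1_intended)
  rem_len2 <- nchar(rem$r2_intended)
  tibble(
    well = well, sample_id = sample_id,
    classification = m1$rem_class,
    r1_trim_at = if_else(ok, m1$tag_len + rem_len1 + 1L, NA_integer_),
    r2_trim_at = if_else(ok, m2$tag_len + rem_len2 + 1L, NA_integer_),
    reason = reason
  )
}

#' Demultiplex a four-stream read set
#'
#' Runs external (plate) and internal (well) assignment, classifies
#' cut-site remnants, optionally trims tags/remnants and writes per-sample
#' FASTQ, and accumulates [demux_stats]. Every input read lands in exactly
#' one bin: a sample, the third-enzyme bin (in `exact`/`rescue1` modes), or
#' the unassigned bin with a reason.
#'
#' @param reads Read-quad tibble (`read_id`, `r1`, `r2`, `i1`, `i2`) or a
#'   named list/vector of four FASTQ paths (`r1`, `r2`, `i1`, `i2`).
#' @param layout Plate layout ([make_plate_layout()]); `i5`/`i7` columns
#'   define the expected external pairs per plate.
#' @param config [demux_config()].
#' @param out_dir Optional directory for per-sample FASTQ output.
#' @param designs,registry Bundled tables by default.
#' @return A `demux_stats` object; the binned reads are attached as
#'   `$reads` (tibble with `bin`, `sample_id`, `classification`, trimmed
#'   `r1`/`r2`).
#' @export
demux_run <- function(reads, layout, config = demux_config(),
                      out_dir = NULL,
                      designs = load_adapter_designs(),
                      registry = load_enzyme_registry(quiet = TRUE)) {
  if (!is.data.frame(reads)) {
    reads <- read_fastq_quads(reads[["r1"]], reads[["r2"]], reads[["i1"]],
                              reads[["i2"]])
  }
  layout <- validate_plate_layout(layout)
  n <- nrow(reads)
  if (n == 0) {
    return(new_demux_stats(tibble(), layout, config, 0L))
  }

  pairs <- distinct(as_tibble(layout), plate_id, i5, i7)
  plate <- assign_external(reads$i1, reads$i2, pairs,
                           tol = config$external_mismatch_tol,
                           match_i5 = !isTRUE(config$umi_mode))

  res <- tibble(plate_id = plate, well = NA_character_,
                sample_id = NA_character_, classification = NA_character_,
                reason = NA_character_, r1_out = reads$r1, r2_out = reads$r2)
  for (p in unique(stats::na.omit(plate))) {
    sel <- which(!is.na(plate) & plate == p)
    sub <- assign_internal(reads$r1[sel], reads$r2[sel],
                           layout[layout$plate_id == p, ], config,
                           designs, registry)
    res$well[sel] <- sub$well
    res$sample_id[sel] <- sub$sample_id
    res$classification[sel] <- sub$classification
    res$reason[sel] <- sub$reason
    if (isTRUE(config$trim_tags)) {
      ok <- sel[!is.na(sub$well)]
      res$r1_out[ok] <- substr(reads$r1[ok], sub$r1_trim_at[!is.na(sub$well)],
                               nchar(reads$r1[ok]))
      res$r2_out[ok] <- substr(reads$r2[ok], sub$r2_trim_at[!is.na(sub$well)],
                               nchar(reads$r2[ok]))
    }
  }
  res$reason[is.na(plate)] <- "external_mismatch"

  route_third <- config$radcheck_mode %in% c("exact", "rescue1")
  res$bin <- dplyr::case_when(
    !is.na(res$reason) ~ paste0("unassigned:", res$reason),
    route_third & res$classification == "third_enzyme" ~ "third_enzyme",
    TRUE ~ res$sample_id
  )

  out <- bind_cols(reads["read_id"], res)
  stats <- new_demux_stats(out, layout, config, n)
  if (!is.null(out_dir)) {
    write_demux_output(out, reads, stats, out_dir, config)
  }
  stats
}

# writes per-bin FASTQ pairs, the unassigned catch-all and stats files
write_demux_output <- function(out, reads, stats, out_dir, config) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(seqs, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(
                                  strrep("I", nchar(seqs))))
  }
  for (b in unique(out$bin)) {
    sel <- out$bin == b
    safe <- gsub("[^A-Za-z0-9_.-]", "_", b)
    ids <- out$read_id[sel]
    if (startsWith(b, "unassigned:")) {
      ids <- paste(ids, sub("^unassigned:", "reason=", b))
      safe <- "unassigned"
    }
    wr(out$r1_out[sel], ids, file.path(out_dir, paste0(safe, "_R1.fastq")))
    wr(out$r2_out[sel], ids, file.path(out_dir, paste0(safe, "_R2.fastq")))
  }
  readr::write_tsv(tidy(stats), file.path(out_dir, "demux_stats.tsv"),
                   progress = FALSE)
  jsonlite::write_json(render_report(stats, format = "json"),
                       file.path(out_dir, "demux_stats.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
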