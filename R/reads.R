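# Read generation: each library molecule yields a number of sequenced
# clusters (PCR duplicates share the template, hence the same molecular ID
# tag), and each cluster yields the four reads of a quadruple-indexed run:
# R1 (internal Read-1 tag + cut-site remnant + insert), R2 (same from the
# other end), I1 = i7, I2 = i5 (or the 8N molecular ID tag in umi_mode).

apply_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(stats::runif(n) < rate)
    if (!length(hit)) return(s)
    ch <- strsplit(s, NULL)[[1]]
    ch[hit] <- vapply(ch[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Generate quadruple-indexed reads from library molecules
#'
#' Samples sequencing clusters per molecule (`depth`), assembles the four
#' reads of each cluster from the molecule layout, applies uniform
#' substitution errors, and returns the reads with a truth table for
#' round-trip checks. Reads extend into the opposite adapter when the
#' insert is shorter than the read length, exactly as on an instrument.
#'
#' @param molecules [pcr_amplify()] / [simulate_library()] tibble.
#' @param config [sim_config()]; uses `read_length`, `depth`, `depth_model`,
#'   `error_rate`, `umi_mode`, `seed`.
#' @return List with `reads` (tibble `read_id`, `r1`, `r2`, `i1`, `i2`) and
#'   `truth` (tibble `read_id`, `sample_id`, `well`, `construct_class`,
#'   `molecule_id`, `dup_group`).
#' @export
generate_reads <- function(molecules, config = sim_config()) {
  rl <- config$read_length
  need <- max(nchar(molecules$r1_tag %||% ""), 0) + 10L
  if (rl < need) abort("read_length too short to cover tag plus remnant")
  with_seed(config$seed + 2L, {
    if (nrow(molecules) == 0) {
      return(list(
        reads = tibble(read_id = character(), r1 = character(),
                       r2 = character(), i1 = character(), i2 = character()),
        truth = tibble(read_id = character(), sample_id = character(),
                       well = character(), construct_class = character(),
                       molecule_id = integer(), dup_group = integer())
      ))
    }
    n_clusters <- switch(config$depth_model,
      fixed = rep(round(config$depth), nrow(molecules)),
      poisson = stats::rpois(nrow(molecules), config$depth)
    )
    pad <- strrep("A", rl)
    r1_tmpl <- paste0(molecules$r1_tag, molecules$r1_post, molecules$insert,
                      revcomp(molecules$r2_post), revcomp(molecules$r2_tag),
                      revcomp(R2_STUB_BOTTOM), molecules$i7, P7_FLOWCELL, pad)
    r2_tmpl <- paste0(molecules$r2_tag, molecules$r2_post,
                      revcomp(molecules$insert), revcomp(molecules$r1_post),
                      revcomp(molecules$r1_tag), R1_BOTTOM_TAIL,
                      revcomp(molecules$i5), revcomp(P5_FLOWCELL), pad)
    idx <- rep(seq_len(nrow(molecules)), n_clusters)
    if (length(idx) == 0) {
      return(list(
        reads = tibble(read_id = character(), r1 = character(),
                       r2 = character(), i1 = character(), i2 = character()),
        truth = tibble(read_id = character(), sample_id = character(),
                       well = character(), construct_class = character(),
                       molecule_id = integer(), dup_group = integer())
      ))
    }
    cluster <- sequence(n_clusters)
    read_id <- sprintf("SIM:%06d:%03d", molecules$molecule_id[idx], cluster)
    i2_seq <- if (isTRUE(config$umi_mode)) molecules$umi[idx] else
      molecules$i5[idx]
    reads <- tibble(
      read_id = read_id,
      r1 = apply_errors(substr(r1_tmpl[idx], 1L, rl), config$error_rate),
      r2 = apply_errors(substr(r2_tmpl[idx], 1L, rl), config$error_rate),
      i1 = apply_errors(molecules$i7[idx], config$error_rate),
      i2 = apply_errors(i2_seq, config$error_rate)
    )
    truth <- tibble(
      read_id = read_id,
      sample_id = molecules$sample_id[idx],
      well = molecules$well[idx],
      construct_class = molecules$construct_class[idx],
      molecule_id = molecules$molecule_id[idx],
      dup_group = molecules$molecule_id[idx]
    )
    list(reads = reads, truth = truth)
  })
}

#' Write / read four-stream FASTQ
#'
#' `write_fastq_quads()` writes R1/R2/I1/I2 FASTQ files (constant quality);
#' `read_fastq_quads()` reads four record-synchronised streams back into a
#' read-quad tibble, raising an error at the first record whose ids
#' disagree across streams.
#'
#' @param reads Read-quad tibble (`read_id`, `r1`, `r2`, `i1`, `i2`).
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return `write_fastq_quads()` returns the four paths invisibly;
#'   `read_fastq_quads()` returns the read-quad tibble.
#' @rdname fastq_quads
#' @export
write_fastq_quads <- function(reads, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, "_", c("R1", "R2", "I1", "I2"),
                                 ".fastq"))
  streams <- list(reads$r1, reads$r2, reads$i1, reads$i2)
  for (i in seq_along(paths)) {
    x <- Biostrings::DNAStringSet(streams[[i]])
    names(x) <- reads$read_id
    qual <- Biostrings::BStringSet(strrep("I", nchar(streams[[i]])))
    Biostrings::writeXStringSet(x, paths[i], format = "fastq",
                                qualities = qual)
  }
  invisible(setNames(paths, c("r1", "r2", "i1", "i2")))
}

#' @param r1,r2,i1,i2 FASTQ paths of the four streams.
#' @rdname fastq_quads
#' @export
read_fastq_quads <- function(r1, r2, i1, i2) {
  rd <- function(p) {
    x <- Biostrings::readDNAStringSet(p, format = "fastq")
    tibble(read_id = vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1),
           seq = as.character(unname(x)))
  }
  a <- rd(r1); b <- rd(r2); c_ <- rd(i1); d <- rd(i2)
  ns <- c(nrow(a), nrow(b), nrow(c_), nrow(d))
  if (length(unique(ns)) != 1) {
    abort(sprintf("desynchronised FASTQ streams: record counts %s",
                  paste(ns, collapse = "/")))
  }
  bad <- which(a$read_id != b$read_id | a$read_id != c_$read_id |
                 a$read_id != d$read_id)
  if (length(bad)) {
    abort(sprintf("desynchronised FASTQ streams at record %d: ids %s / %s / %s / %s",
                  bad[1], a$read_id[bad[1]], b$read_id[bad[1]],
                  c_$read_id[bad[1]], d$read_id[bad[1]]))
  }
  tibble(read_id = a$read_id, r1 = a$seq, r2 = b$seq, i1 = c_$seq,
         i2 = d$seq)
}

#' Write a truth table alongside simulated reads
#'
#' @param truth Truth tibble from [generate_reads()].
#' @param path TSV path.
#' @export
write_truth_table <- function(truth, path) {
  readr::write_tsv(truth, path, progress = FALSE)
  invisible(path)
}
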