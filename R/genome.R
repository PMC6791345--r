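# run code under a local RNG state seeded from `seed` (global stream restored
# on exit); seed = NULL leaves the current stream in place
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# resolve IUPAC codes in a motif to concrete bases (random choice per code)
resolve_motif <- function(motif) {
  paste(vapply(strsplit(motif, NULL)[[1]], function(ch) {
    b <- IUPAC_SETS[[ch]]
    if (length(b) == 1) b else sample(b, 1)
  }, character(1)), collapse = "")
}

#' Generate a synthetic genome with planted restriction sites
#'
#' Draws a random DNA sequence of the requested length and GC content and
#' plants recognition sites for the given enzymes at recorded positions.
#' Planted motifs never overlap each other; sites of the same enzymes that
#' arise by chance in the random background are detected and reported (not
#' removed). Deterministic for a given seed.
#'
#' @param length Sequence length in bp (>= 1000).
#' @param gc GC fraction in `[0, 1]`.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param planted Data frame with columns `enzyme` and `count`, and/or an
#'   `at` list-column of explicit motif-start positions (overrides `count`).
#' @param registry Enzyme registry used to resolve motifs.
#' @param id Record id.
#' @param topology `"linear"` or `"circular"`.
#' @return Object of class `synthetic_genome`: list with `id`, `seq`,
#'   `topology`, `gc`, `planted` (tibble `enzyme`, `motif_start`) and
#'   `chance` (tibble of unplanned motif occurrences).
#' @examples
#' g <- make_synthetic_genome(10000, 0.5, seed = 7,
#'                            planted = data.frame(enzyme = "XbaI", count = 5))
#' g$planted
#' @export
make_synthetic_genome <- function(length, gc = 0.5, seed = NULL,
                                  planted = NULL,
                                  registry = load_enzyme_registry(quiet = TRUE),
                                  id = "synthetic_genome",
                                  topology = c("linear", "circular")) {
  topology <- arg_match(topology)
  if (length < 1000) abort("genome length must be at least 1 kb")
  if (gc < 0 || gc > 1) abort("gc must be in [0, 1]")
  with_seed(seed, {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    s <- sample(names(probs), length, replace = TRUE, prob = probs)
    planted_tbl <- tibble(enzyme = character(), motif_start = integer())
    if (!is.null(planted) && nrow(planted) > 0) {
      planted <- as_tibble(planted)
      motifs <- vapply(planted$enzyme, function(e) {
        get_enzyme(registry, e)$recognition
      }, character(1))
      n_explicit <- if ("at" %in% names(planted)) {
        sum(lengths(planted$at))
      } else 0L
      n_random <- if ("count" %in% names(planted)) {
        sum(planted$count[!vapply(seq_len(nrow(planted)), function(i) {
          "at" %in% names(planted) && length(planted$at[[i]]) > 0
        }, logical(1))])
      } else 0L
      need <- (n_explicit + n_random) * (max(nchar(motifs)) * 3L)
      if (need > length) abort("infeasible planting density for this length")
      taken <- integer(0)
      place <- function(enz, motif, at = NULL) {
        k <- nchar(motif)
        pos <- if (!is.null(at)) at else {
          repeat {
            p <- sample.int(length - k + 1L, 1L)
            if (!any(abs(p - taken) < k + 2L)) break
          }
          p
        }
        for (p in pos) {
          if (p < 1 || p + k - 1L > length) {
            abort(sprintf("planted position %d out of range", p))
          }
          s[p:(p + k - 1L)] <<- strsplit(resolve_motif(motif), NULL)[[1]]
          taken <<- c(taken, p)
          planted_tbl <<- bind_rows(planted_tbl,
                                    tibble(enzyme = enz, motif_start = as.integer(p)))
        }
      }
      for (i in seq_len(nrow(planted))) {
        at_i <- if ("at" %in% names(planted)) planted$at[[i]] else NULL
        if (!is.null(at_i) && length(at_i) > 0) {
          place(planted$enzyme[i], motifs[i], at = at_i)
        } else {
          cnt <- if ("count" %in% names(planted)) planted$count[i] else 0L
          if (is.na(cnt)) cnt <- 0L
          for (j in seq_len(cnt)) place(planted$enzyme[i], motifs[i])
        }
      }
    }
    seq <- paste(s, collapse = "")
    chance <- tibble(enzyme = character(), motif_start = integer())
    for (e in unique(planted_tbl$enzyme)) {
      hits <- find_sites(seq, get_enzyme(registry, e), topology)
      extra <- setdiff(hits$motif_start,
                       planted_tbl$motif_start[planted_tbl$enzyme == e])
      if (length(extra)) {
        chance <- bind_rows(chance, tibble(enzyme = e,
                                           motif_start = as.integer(extra)))
      }
    }
    structure(list(id = id, seq = seq, topology = topology, gc = gc,
                   planted = planted_tbl %>% arrange(motif_start),
                   chance = chance),
              class = "synthetic_genome")
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("<synthetic_genome> %s: %d bp (%s), GC %.2f, %d planted site(s), %d chance site(s)\n",
              x$id, nchar(x$seq), x$topology, x$gc, nrow(x$planted),
              nrow(x$chance)))
  invisible(x)
}

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings. Records whose header contains the word
#' `circular` are flagged as circular on read.
#'
#' @param path FASTA file.
#' @return `read_fasta()` returns a tibble with columns `id`, `seq`,
#'   `circular`.
#' @rdname fasta_io
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  headers <- names(x)
  tibble(
    id = vapply(strsplit(headers, "\\s+"), `[`, character(1), 1),
    seq = unname(as.character(x)),
    circular = grepl("circular", headers, ignore.case = TRUE)
  )
}

#' @param x A `synthetic_genome`, a tibble with `id` and `seq` columns, or a
#'   named character vector.
#' @rdname fasta_io
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "synthetic_genome")) {
    hdr <- paste0(x$id, if (x$topology == "circular") " circular" else "")
    x <- setNames(x$seq, hdr)
  } else if (is.data.frame(x)) {
    x <- setNames(x$seq, x$id)
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path)
  invisible(path)
}

#' Generate a genome of evenly spaced RAD loci
#'
#' Convenience generator for end-to-end tests and demonstrations: plants
#' Read-1-enzyme sites a fixed distance upstream of Read-2-enzyme sites so
#' that every locus yields a library molecule of predictable size. With the
#' defaults (420 bp between the XbaI and EcoRI motif starts) a Design-1
#' molecule totals 574 bp and falls inside the default 550 bp +/- 10
#' percent size window. Every `third_every`-th locus carries the blocking
#' enzyme's site instead of the first enzyme's, producing third-enzyme loci
#' at a known rate.
#'
#' @param n_loci Number of planted loci.
#' @param third_every Every n-th locus gets the blocking enzyme's site
#'   (0 = none).
#' @param seed Integer seed.
#' @param spacing Distance between locus starts in bp.
#' @param insert_gap Distance from first-enzyme to second-enzyme motif
#'   start, in bp.
#' @param enzymes Character vector `c(read1, read2, blocking)`.
#' @param registry Enzyme registry.
#' @return A `synthetic_genome` (see [make_synthetic_genome()]).
#' @export
plant_locus_genome <- function(n_loci, third_every = 0, seed = 1,
                               spacing = 1300L, insert_gap = 420L,
                               enzymes = c("XbaI", "EcoRI-HF", "NheI"),
                               registry = load_enzyme_registry(quiet = TRUE)) {
  first <- rep(enzymes[1], n_loci)
  if (third_every > 0 && length(enzymes) > 2) {
    first[seq(third_every, n_loci, by = third_every)] <- enzymes[3]
  }
  starts <- 500L + (seq_len(n_loci) - 1L) * as.integer(spacing)
  make_synthetic_genome(
    length = max(starts) + as.integer(insert_gap) + 1000L, gc = 0.5,
    seed = seed,
    planted = tibble(
      enzyme = c(enzymes[1], if (length(enzymes) > 2) enzymes[3] else NULL,
                 enzymes[2]),
      at = c(list(starts[first == enzymes[1]]),
             if (length(enzymes) > 2) list(starts[first == enzymes[3]]),
             list(starts + as.integer(insert_gap)))),
    registry = registry, id = sprintf("locus_genome_%d", n_loci))
}
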