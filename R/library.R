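#' Amplify constructs into full-length library molecules
#'
#' Converts each amplifiable construct into one full-length quadruple-indexed
#' library molecule (copy-number amplification is not modelled here;
#' PCR-duplicate multiplicity is introduced at read generation). The
#' molecule layout is flowcell-P5 / i5 / Read-1 primer region / internal
#' Read-1 tag / cut-site remnant / insert / remnant / internal Read-2 tag /
#' Read-2 primer region / i7 / flowcell-P7. In `umi_mode` a fresh random
#' 8-base molecular ID tag replaces the i5 index on each template molecule.
#'
#' @param constructs List of classified constructs
#'   ([digestion_ligation_cycle()]).
#' @param i5,i7 External 8-nt index sequences for this pool/plate.
#' @param config A [sim_config()] (supplies `umi_mode` and the seed for UMI
#'   draws).
#' @param sample_id,well Bookkeeping labels stored per molecule.
#' @return Tibble of library molecules: `molecule_id`, `sample_id`, `well`,
#'   `construct_class`, `i5`, `i7`, `umi`, `r1_tag`, `r2_tag`, `insert`,
#'   `total_length`, plus `n_skipped` (non-amplifiable inputs) as an
#'   attribute.
#' @export
pcr_amplify <- function(constructs, i5, i7, config = sim_config(),
                        sample_id = "sample1", well = NA_character_) {
  i5 <- check_dna(i5, "i5 index")
  i7 <- check_dna(i7, "i7 index")
  if (nchar(i5) != 8 || nchar(i7) != 8) {
    abort("external indexes must be 8 nt")
  }
  keep <- vapply(constructs, amplifiable, logical(1))
  skipped <- sum(!keep)
  mols <- constructs[keep]
  with_seed(config$seed + 1L, {
    rows <- purrr::map_dfr(seq_along(mols), function(i) {
      m <- mols[[i]]
      types <- vapply(m$units, function(e) e$u$type, character(1))
      if (types[1] == "r2") m <- mol_flip(m)
      r1u <- m$units[[1]]$u
      r2u <- m$units[[3]]$u
      jmap <- list()
      for (j in m$junctions) jmap[[as.character(j$after)]] <- j
      ov <- junction_ov_ins(m$units[[3]], jmap[["2"]]$left_end)
      insert <- paste0(unit_contrib(m$units[[2]]), ov)
      umi <- if (isTRUE(config$umi_mode)) {
        paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE), collapse = "")
      } else NA_character_
      tibble(
        molecule_id = i,
        sample_id = sample_id, well = well,
        construct_class = m$construct_class,
        i5 = i5, i7 = i7, umi = umi,
        r1_tag = r1u$tag, r1_post = r1u$post,
        r2_tag = r2u$tag, r2_post = r2u$post,
        insert = insert,
        total_length = nchar(P5_FLOWCELL) + 8L + nchar(R1_BOTTOM_TAIL) +
          nchar(r1u$tag) + nchar(r1u$post) + nchar(insert) +
          nchar(r2u$post) + nchar(r2u$tag) + nchar(R2_STUB_BOTTOM) +
          8L + nchar(P7_FLOWCELL)
      )
    })
    if (nrow(rows) == 0) {
      rows <- tibble(molecule_id = integer(), sample_id = character(),
                     well = character(), construct_class = character(),
                     i5 = character(), i7 = character(), umi = character(),
                     r1_tag = character(), r1_post = character(),
                     r2_tag = character(), r2_post = character(),
                     insert = character(), total_length = integer())
    }
    attr(rows, "n_skipped") <- skipped
    rows
  })
}

#' Size-select library molecules
#'
#' Retains molecules whose total length lies within
#' `[center * (1 - tol), center * (1 + tol)]`, bounds inclusive - e.g.
#' center 550 bp with tol 0.10 retains 495-605 bp.
#'
#' @param molecules [pcr_amplify()] tibble (needs `total_length`).
#' @param center Window centre in bp.
#' @param tol Fractional half-width in `[0, 1)`.
#' @return The retained subset.
#' @export
size_select <- function(molecules, center = 550, tol = 0.10) {
  if (tol < 0 || tol >= 1) abort("tol must lie in [0, 1)")
  lo <- center * (1 - tol)
  hi <- center * (1 + tol)
  molecules %>% filter(total_length >= lo, total_length <= hi)
}

#' Expected number of loci under an independent-bases genome model
#'
#' Closed-form expectation of the number of sequenceable fragments for a
#' genome of given length and GC content: recognition sites occur as a
#' Poisson process with per-base probability given by the motif's base
#' composition (GC-weighted, degeneracy-expanded), inter-cut distances are
#' approximately exponential, and a fragment is a locus when its two ends
#' come from the Read-1 and Read-2 enzymes respectively (any fragment, for a
#' single-enzyme digest) and its insert length falls inside the size window.
#'
#' @param genome_length Genome size in bp.
#' @param gc GC fraction.
#' @param enzymes One or two enzyme names (or registry rows): a single
#'   enzyme counts all fragments; a pair counts hetero-ended fragments.
#' @param size_window Optional `c(min, max)` insert-length window in bp.
#' @param registry Enzyme registry.
#' @return Expected locus count (numeric).
#' @export
expected_locus_count <- function(genome_length, gc = 0.5, enzymes,
                                 size_window = NULL,
                                 registry = load_enzyme_registry(quiet = TRUE)) {
  if (genome_length <= 0) return(0)
  if (is.character(enzymes)) {
    enzymes <- bind_rows(lapply(enzymes, get_enzyme, registry = registry))
  }
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  p_site <- vapply(enzymes$recognition, function(motif) {
    prod(vapply(strsplit(motif, NULL)[[1]], function(ch) {
      sum(base_p[IUPAC_SETS[[ch]]])
    }, numeric(1)))
  }, numeric(1), USE.NAMES = FALSE)
  lam <- sum(p_site)
  if (lam <= 0) return(0)
  p_win <- if (is.null(size_window)) 1 else {
    exp(-lam * max(0, size_window[1])) - exp(-lam * size_window[2])
  }
  if (nrow(enzymes) == 1) {
    # k cut sites yield k+1 fragments on a linear molecule
    (genome_length * lam + 1) * p_win
  } else if (nrow(enzymes) == 2) {
    2 * genome_length * p_site[1] * p_site[2] / lam * p_win
  } else {
    abort("supply one or two enzymes")
  }
}

#' Simulate a full 3RAD library for a plate of samples
#'
#' End-to-end wrapper: digests the genome with the chosen enzyme
#' combination, runs digestion-ligation cycling per well with that well's
#' indexed adapters, amplifies, size-selects, and pools the library
#' molecules of all wells.
#'
#' @param genome A [make_synthetic_genome()] object, or a list/tibble row
#'   with `seq` and `topology`.
#' @param layout [make_plate_layout()] tibble (wells to simulate).
#' @param enzymes Character vector `c(read1, read2)` or
#'   `c(read1, read2, blocking)` naming the digest enzymes.
#' @param config [sim_config()].
#' @param designs,registry Bundled tables by default.
#' @param apply_size_selection Apply the configured size window (default
#'   `TRUE`).
#' @return Tibble of library molecules across wells (see [pcr_amplify()]).
#' @export
simulate_library <- function(genome, layout,
                             enzymes = c("XbaI", "EcoRI-HF", "NheI"),
                             config = sim_config(),
                             designs = load_adapter_designs(),
                             registry = load_enzyme_registry(quiet = TRUE),
                             apply_size_selection = TRUE) {
  seq <- if (inherits(genome, "synthetic_genome")) genome$seq else genome$seq
  topo <- if (inherits(genome, "synthetic_genome")) genome$topology else
    (genome$topology %||% "linear")
  frags <- digest(seq, enzymes, topology = topo, registry = registry)
  design_id <- unique(layout$design)
  if (length(design_id) != 1) abort("layout must use a single design")
  d1 <- designs[designs$design == design_id & designs$side == "read1", ]
  d2 <- designs[designs$design == design_id & designs$side == "read2", ]
  out <- purrr::map_dfr(seq_len(nrow(layout)), function(w) {
    row <- layout[w, ]
    cfg <- config
    cfg$seed <- config$seed + w * 101L
    r1 <- build_adapter(d1, row$r1_tag, version = row$r1_version)
    r2 <- build_adapter(d2, row$r2_tag, version = row$r2_version)
    constructs <- digestion_ligation_cycle(frags, r1, r2, registry, cfg,
                                           enzymes = enzymes)
    mols <- pcr_amplify(constructs, row$i5, row$i7, cfg,
                        sample_id = row$sample_id, well = row$well)
    mols
  })
  if (nrow(out) > 0) {
    out$molecule_id <- seq_len(nrow(out))
    if (apply_size_selection) {
      out <- size_select(out, config$size_center, config$size_tol)
    }
  }
  out
}
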