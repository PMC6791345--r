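# Adapter stub architecture shared by all four designs (TruSeq-derived):
# the Read-1 stub top / tail and Read-2 stub bottom / tail are fixed; each
# design contributes its cohesive-end bases (`overhang`) and the duplex bases
# between the index slot and the overhang (`post`).
R1_STUB_TOP <- "ACGACGCTCTTCCGATCT"
R1_BOTTOM_TAIL <- "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT"
R2_STUB_BOTTOM <- "GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT"
R2_TOP_TAIL <- "AGATCGGAAGAGCACACGT"
R2_TOP_NC <- "aatcc"  # 5-base non-complementary tail, printed lowercase
PHOS <- "/5phos/"

#' Load the adapter design table
#'
#' Eight adapter stub designs: four Read-1 (named for the set's blocking
#' enzyme) and four Read-2. Each row records the design's cohesive-end
#' overhang, the duplex bases between index slot and overhang (`post`) and
#' the overhang polarity.
#'
#' @param path CSV path; defaults to the bundled table.
#' @return Tibble with columns `design`, `set`, `side`, `adapter_enzyme`,
#'   `overhang`, `post`, `polarity`.
#' @export
load_adapter_designs <- function(path = triplerad_file("adapter_designs.csv")) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE) %>%
    mutate(design = as.integer(design))
}

#' Load the internal index (in-line barcode) sets
#'
#' The universal Read-1 (versions A-H) and Read-2 (versions 1-12) internal
#' index sets. Tag lengths vary from 6 to 9 nt in balanced groups of four so
#' that pooled libraries stay base-diverse across the restriction remnant.
#' The four Read-1 and four Read-2 tags printed in the published design table
#' are included verbatim; the remaining tags are synthetic stand-ins
#' (generated under the published constraints: minimum pairwise Levenshtein
#' distance 3 within a set, no recognition site introduced into any
#' assembled adapter), since the full published sets live in a supplementary
#' workbook that is not redistributed here.
#'
#' When `design` is given, per-design overrides are applied (Design 2
#' replaces Read-2 index 5, whose universal sequence would create a BamHI
#' recognition site inside the assembled adapter).
#'
#' @param design Optional design number (1-4) whose overrides to apply.
#' @param path,overrides_path CSV paths; default to the bundled tables.
#' @return Tibble with columns `side` (`read1`/`read2`), `version`, `tag`,
#'   `source`, and `overridden` (logical) when `design` is given.
#' @export
load_index_tags <- function(design = NULL,
                            path = triplerad_file("index_tags_synthetic.csv"),
                            overrides_path = triplerad_file("index_overrides.csv")) {
  tags <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = "c"))
  if (!is.null(design)) {
    ov <- readr::read_csv(overrides_path, show_col_types = FALSE,
                          progress = FALSE,
                          col_types = readr::cols(.default = "c"))
    ov <- ov[ov$design == as.character(design), ]
    tags$overridden <- FALSE
    for (i in seq_len(nrow(ov))) {
      hit <- tags$side == ov$side[i] & tags$version == ov$version[i]
      tags$tag[hit] <- ov$tag[i]
      tags$source[hit] <- "override"
      tags$overridden[hit] <- TRUE
    }
  }
  tags
}

#' Load the external (i5/i7) primer index table
#'
#' Synthetic stand-ins for the indexed PCR primer sets: 8-nt indexes with
#' minimum pairwise Levenshtein distance 3 within each side.
#'
#' @param path CSV path; defaults to the bundled synthetic table.
#' @return Tibble with columns `name`, `side` (`i5`/`i7`), `sequence`.
#' @export
load_primer_table <- function(path = triplerad_file("itru_primers_synthetic.csv")) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(.default = "c"))
}

# oligo strings plus the character span occupied by the spliced tag (top
# strand) and its reverse complement (partner strand)
adapter_oligo_parts <- function(design_row, tag) {
  oh <- design_row$overhang
  post <- design_row$post
  if (design_row$side == "read1") {
    top <- paste0(R1_STUB_TOP, tag, post)
    lead <- if (design_row$polarity == "five_prime") {
      paste0(oh, revcomp(post))
    } else {
      revcomp(substr(post, 1, nchar(post) - nchar(oh)))
    }
    bottom_core <- paste0(lead, revcomp(tag), R1_BOTTOM_TAIL)
    list(top = top, bottom_core = bottom_core, lead = lead,
         span_top = nchar(R1_STUB_TOP) + c(1L, nchar(tag)),
         span_bottom = nchar(lead) + c(1L, nchar(tag)))
  } else {
    bottom_core <- paste0(R2_STUB_BOTTOM, tag, post)
    top <- paste0(oh, revcomp(post), revcomp(tag), R2_TOP_TAIL, R2_TOP_NC)
    list(top = top, bottom_core = bottom_core,
         lead = paste0(oh, revcomp(post)),
         span_top = nchar(oh) + nchar(post) + c(1L, nchar(tag)),
         span_bottom = nchar(R2_STUB_BOTTOM) + c(1L, nchar(tag)))
  }
}

#' Build an adapter oligonucleotide pair
#'
#' Splices an internal index tag into an adapter stub design, reproducing
#' the published oligo strings byte-exactly (including the `/5phos/`
#' phosphorylation marker on Read-1 bottom strands and the lowercase
#' non-complementary `aatcc` tail on Read-2 top strands).
#'
#' @param design One-row slice of [load_adapter_designs()] (one design, one
#'   side).
#' @param tag Index tag: a character scalar or a one-row slice of
#'   [load_index_tags()] (its `side` must then match the design's).
#' @param version Version label used in the oligo names (taken from `tag`
#'   when it is a tag row).
#' @return An object of class `oligo_pair`: a list with `name_top`,
#'   `name_bottom`, `top`, `bottom` (5'->3' strings), and bookkeeping fields
#'   (`side`, `design`, `overhang`, `polarity`, `tag`, `version`,
#'   `bottom_phosphorylated`).
#' @examples
#' designs <- load_adapter_designs()
#' tags <- load_index_tags()
#' d1 <- dplyr::filter(designs, design == 1, side == "read1")
#' build_adapter(d1, dplyr::filter(tags, side == "read1", version == "A"))
#' @export
build_adapter <- function(design, tag, version = NULL) {
  design <- as_tibble(design)
  if (nrow(design) != 1) abort("`design` must be a single design/side row")
  if (is.data.frame(tag)) {
    if (nrow(tag) != 1) abort("`tag` must be a single tag row")
    if (!identical(tag$side, design$side)) {
      abort(sprintf("tag side '%s' does not match design side '%s'",
                    tag$side, design$side))
    }
    version <- version %||% tag$version
    tag <- tag$tag
  }
  if (!is.character(tag) || length(tag) != 1 || is.na(tag) || !nzchar(tag)) {
    abort("index tag must be a non-empty DNA string")
  }
  tag <- check_dna(tag, "index tag", allow_iupac = FALSE)
  version <- version %||% "x"
  parts <- adapter_oligo_parts(design, tag)
  enz <- design$adapter_enzyme
  if (design$side == "read1") {
    structure(list(
      name_top = sprintf("iTru_%s_R1_stub_%s", enz, version),
      name_bottom = sprintf("iTru_%s_R1_RCp_%s", enz, version),
      top = parts$top,
      bottom = paste0(PHOS, parts$bottom_core),
      bottom_phosphorylated = TRUE,
      side = "read1", design = design$design, overhang = design$overhang,
      polarity = design$polarity, post = design$post,
      tag = tag, version = version
    ), class = "oligo_pair")
  } else {
    structure(list(
      name_top = sprintf("iTru_%s_R2_RC_stub_%s", enz, version),
      name_bottom = sprintf("iTru_%s_R2_%s", enz, version),
      top = parts$top,
      bottom = parts$bottom_core,
      bottom_phosphorylated = FALSE,
      side = "read2", design = design$design, overhang = design$overhang,
      polarity = design$polarity, post = design$post,
      tag = tag, version = version
    ), class = "oligo_pair")
  }
}

#' @export
print.oligo_pair <- function(x, ...) {
  cat(sprintf("<oligo_pair> design %s, %s (index %s: %s)\n",
              x$design, x$side, x$version, x$tag))
  cat(sprintf("  %-24s 5'-%s-3'\n", x$name_top, x$top))
  cat(sprintf("  %-24s 5'-%s-3'\n", x$name_bottom, x$bottom))
  invisible(x)
}

#' Expected cut-site remnant of a read
#'
#' The fixed bases observed in a read between the internal index tag and the
#' first genomic base, for a fragment end cut by `enzyme` and ligated to the
#' given adapter design. On Read 1 this is the adapter's duplex bases plus
#' the motif suffix downstream of the top-strand cut; on Read 2 the motif
#' contribution is read on the bottom strand. Degenerate motif positions
#' (e.g. DdeI) stay as IUPAC codes.
#'
#' @param design One-row design slice (the side determines the arithmetic).
#' @param enzyme One-row registry slice for the cutting enzyme.
#' @return Character scalar (IUPAC pattern).
#' @examples
#' designs <- load_adapter_designs()
#' reg <- load_enzyme_registry(quiet = TRUE)
#' d1r1 <- dplyr::filter(designs, design == 1, side == "read1")
#' cutsite_remnant(d1r1, get_enzyme(reg, "XbaI"))  # "GCTAGA"
#' cutsite_remnant(d1r1, get_enzyme(reg, "NheI"))  # "GCTAGC"
#' @export
cutsite_remnant <- function(design, enzyme) {
  motif <- enzyme$recognition
  if (design$side == "read1") {
    paste0(design$post, substr(motif, enzyme$cut_top + 1L, nchar(motif)))
  } else {
    paste0(design$post, revcomp(substr(motif, 1L, enzyme$cut_bottom)))
  }
}

#' Simulate self-ligation of an adapter
#'
#' Forms the adapter-dimer that results when two copies of the same adapter
#' ligate at their cohesive ends, and scans the dimer junction strand for
#' restriction recognition sites. For the Read-1 designs the junction
#' re-creates the set's blocking (third) enzyme site - the mechanism that
#' lets the third enzyme cleave adapter-dimers during ligation-digestion
#' cycling. Read-2 adapters are unphosphorylated and cannot self-ligate;
#' blunt or non-self-complementary ends cannot form dimers.
#'
#' @param pair An [build_adapter()] `oligo_pair`.
#' @param registry Enzyme registry to scan the junction with.
#' @return A list of class `self_ligation`: `possible` (logical), `reason`
#'   (when not possible), `junction_seq` (the ligated strand), `junction_at`
#'   (1-based offset where the second adapter begins) and `sites` (tibble of
#'   `enzyme`, `position`, `matched_seq` hits in the junction strand).
#' @export
simulate_self_ligation <- function(pair, registry = load_enzyme_registry(quiet = TRUE)) {
  stopifnot(inherits(pair, "oligo_pair"))
  empty <- tibble(enzyme = character(), position = integer(),
                  matched_seq = character())
  fail <- function(reason) {
    structure(list(possible = FALSE, reason = reason, junction_seq = NA_character_,
                   junction_at = NA_integer_, sites = empty),
              class = "self_ligation")
  }
  if (!isTRUE(pair$bottom_phosphorylated)) {
    return(fail("adapter is unphosphorylated on the 5' end and will not self-ligate"))
  }
  if (identical(pair$polarity, "blunt") || !nzchar(pair$overhang)) {
    return(fail("no dimer possible: blunt end"))
  }
  end <- list(kind = "cut", polarity = pair$polarity, overhang = pair$overhang)
  if (!ends_compatible(end, end)) {
    return(fail("no dimer possible: overhang is not self-complementary"))
  }
  # ligated strand: top of one adapter joined to the partner's phosphorylated
  # bottom strand across the annealed overhangs
  junction_seq <- paste0(pair$top, sub(PHOS, "", pair$bottom, fixed = TRUE))
  sites <- purrr::map_dfr(seq_len(nrow(registry)), function(i) {
    st <- motif_starts(junction_seq, registry$recognition[i])
    if (!length(st)) return(tibble())
    tibble(enzyme = registry$name[i], position = st,
           matched_seq = substring(junction_seq, st,
                                   st + nchar(registry$recognition[i]) - 1L))
  })
  if (nrow(sites) == 0) sites <- empty
  structure(list(possible = TRUE, reason = NA_character_,
                 junction_seq = junction_seq,
                 junction_at = nchar(pair$top) + 1L, sites = sites),
            class = "self_ligation")
}
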