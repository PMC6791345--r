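#' Find restriction recognition sites in a sequence
#'
#' Scans the top strand of `seq` for the enzyme's (possibly degenerate,
#' IUPAC-coded) recognition motif. All bundled motifs are palindromic under
#' IUPAC resolution, so a top-strand scan finds every cut site.
#'
#' Reported `position` follows the plasmid-map convention: the 1-based
#' coordinate of the first base 3' of the top-strand cut, i.e.
#' `motif_start + cut_top`. On the pUC19 map this convention reports the
#' XbaI site at 423 and the EcoRI site at 396; the `motif_start` column
#' retains the raw 1-based motif coordinate.
#'
#' @param seq DNA sequence (character scalar, IUPAC letters allowed) or a
#'   `Biostrings::DNAString`.
#' @param enzyme A one-row slice of an [load_enzyme_registry()] tibble, or an
#'   enzyme name (then `registry` must be supplied).
#' @param topology `"linear"` or `"circular"`. Circular topology also finds
#'   motifs spanning the origin; their `position` wraps modulo the sequence
#'   length.
#' @param registry Registry used to resolve `enzyme` when it is a name.
#' @return Tibble with columns `enzyme`, `motif_start`, `position`,
#'   `matched_seq`, sorted by `motif_start`.
#' @examples
#' reg <- load_enzyme_registry(quiet = TRUE)
#' find_sites("AATCTAGAGG", get_enzyme(reg, "XbaI"))
#' @export
find_sites <- function(seq, enzyme, topology = c("linear", "circular"),
                       registry = NULL) {
  topology <- arg_match(topology)
  if (inherits(seq, "DNAString")) seq <- as.character(seq)
  seq <- check_dna(seq)
  if (is.character(enzyme) && length(enzyme) == 1) {
    if (is.null(registry)) registry <- load_enzyme_registry(quiet = TRUE)
    enzyme <- get_enzyme(registry, enzyme)
  }
  motif <- enzyme$recognition
  k <- nchar(motif)
  L <- nchar(seq)
  subject <- if (topology == "circular" && L > 1) {
    paste0(seq, substr(seq, 1, min(k - 1L, L)))
  } else {
    seq
  }
  hits <- Biostrings::matchPattern(
    Biostrings::DNAString(motif), Biostrings::DNAString(subject),
    fixed = FALSE
  )
  st <- Biostrings::start(hits)
  st <- st[st <= L]
  if (length(st) == 0) {
    return(tibble(enzyme = character(), motif_start = integer(),
                  position = integer(), matched_seq = character()))
  }
  pos <- st + enzyme$cut_top
  if (topology == "circular") pos <- ((pos - 1L) %% L) + 1L
  tibble(
    enzyme = enzyme$name,
    motif_start = as.integer(st),
    position = as.integer(pos),
    matched_seq = substring(subject, st, st + k - 1L)
  ) %>% arrange(motif_start)
}

#' Test whether two fragment ends can ligate
#'
#' Two cohesive ends are compatible when they have the same polarity
#' (both 5' extensions or both 3' extensions) and their single-stranded
#' overhangs are reverse-complementary after IUPAC resolution (each overhang
#' read 5'->3' on its own strand). Two blunt ends are considered compatible.
#'
#' @param a,b Fragment ends: lists or one-row data frames with elements
#'   `polarity` (`"five_prime"`, `"three_prime"` or `"blunt"`) and
#'   `overhang` (character; `""` for blunt). A `kind` of `"terminal"`
#'   is never compatible with anything (unligated molecule extremities).
#' @return `TRUE` or `FALSE`.
#' @examples
#' xba <- list(polarity = "five_prime", overhang = "CTAG", kind = "cut")
#' nhe <- list(polarity = "five_prime", overhang = "CTAG", kind = "cut")
#' eco <- list(polarity = "five_prime", overhang = "AATT", kind = "cut")
#' ends_compatible(xba, nhe)
#' ends_compatible(xba, eco)
#' @export
ends_compatible <- function(a, b) {
  a <- as.list(a)
  b <- as.list(b)
  if (identical(a$kind, "terminal") || identical(b$kind, "terminal")) {
    return(FALSE)
  }
  if (!identical(a$polarity, b$polarity)) return(FALSE)
  if (identical(a$polarity, "blunt")) return(TRUE)
  oa <- a$overhang %||% ""
  ob <- b$overhang %||% ""
  if (nchar(oa) != nchar(ob) || nchar(oa) == 0) return(FALSE)
  is.finite(iupac_mismatches(oa, revcomp(ob))) &&
    iupac_mismatches(oa, revcomp(ob)) == 0
}

#' Enumerate usable enzyme combinations
#'
#' Crosses every Read-1 primary enzyme with every Read-2 enzyme whose
#' cohesive end matches its design set's adapter overhang, attaching the
#' Read-1 set's blocking enzyme (the third enzyme of a 3RAD reaction).
#' High-fidelity (-HF) variants collapse onto their parent enzyme, and
#' enzymes whose overhang cannot mate with their set's adapter (e.g. a blunt
#' cutter listed in a sticky-end set) are dropped.
#'
#' @param registry An [load_enzyme_registry()] tibble.
#' @param designs Adapter design table ([load_adapter_designs()]); used for
#'   the per-set adapter overhangs.
#' @return Tibble with columns `read1`, `read2`, `blocking`, `r1_set`,
#'   `r2_set`, one row per combination.
#' @export
enumerate_enzyme_combinations <- function(registry,
                                          designs = load_adapter_designs()) {
  if (nrow(registry) == 0) {
    return(tibble(read1 = character(), read2 = character(),
                  blocking = character(), r1_set = character(),
                  r2_set = character()))
  }
  reg <- registry %>%
    mutate(base_name = sub("-HF$", "", name)) %>%
    distinct(base_name, role, design_set, .keep_all = TRUE)

  set_overhang <- setNames(designs$overhang, designs$set)
  set_polarity <- setNames(designs$polarity, designs$set)
  mates_adapter <- function(i) {
    oh <- set_overhang[[reg$design_set[i]]]
    if (is.null(oh)) return(FALSE)
    ends_compatible(
      list(polarity = reg$overhang_kind[i], overhang = reg$overhang_seq[i],
           kind = "cut"),
      list(polarity = set_polarity[[reg$design_set[i]]], overhang = oh,
           kind = "cut")
    )
  }
  usable <- vapply(seq_len(nrow(reg)), mates_adapter, logical(1))
  reg <- reg[usable, ]

  r1 <- reg %>% filter(role == "read1_primary")
  r2 <- reg %>% filter(role == "read2")
  blockers <- reg %>% filter(role == "read1_blocking") %>%
    distinct(design_set, .keep_all = TRUE)
  block_of <- setNames(blockers$base_name, blockers$design_set)
  if (nrow(r1) == 0 || nrow(r2) == 0) {
    return(tibble(read1 = character(), read2 = character(),
                  blocking = character(), r1_set = character(),
                  r2_set = character()))
  }
  tidyr::crossing(
    r1 %>% select(read1 = base_name, r1_set = design_set),
    r2 %>% select(read2 = base_name, r2_set = design_set)
  ) %>%
    mutate(blocking = unname(block_of[r1_set])) %>%
    select(read1, read2, blocking, r1_set, r2_set)
}
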