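#' Minimum pairwise edit distance of an index set
#'
#' Minimum Levenshtein distance over all unordered pairs of tags. Index sets
#' are designed to a minimum edit distance of 3 so that a single sequencing
#' error can never convert one valid tag into another. Variable-length tags
#' require an indel-aware metric; Hamming distance is available for
#' equal-length pairs.
#'
#' @param tags Character vector of tags, or a data frame with a `tag` column.
#' @param method `"levenshtein"` (default) or `"hamming"` (equal-length
#'   pairs only; errors if no two tags share a length).
#' @return Integer scalar.
#' @examples
#' min_pairwise_edit_distance(c("CCGAAT", "TTAGGCA", "AACTCGTC"))
#' @export
min_pairwise_edit_distance <- function(tags,
                                       method = c("levenshtein", "hamming")) {
  method <- arg_match(method)
  if (is.data.frame(tags)) tags <- tags$tag
  if (length(tags) < 2) abort("at least 2 tags are required")
  if (method == "levenshtein") {
    d <- utils::adist(tags)
    return(as.integer(min(d[upper.tri(d)])))
  }
  best <- Inf
  for (i in seq_along(tags)[-length(tags)]) {
    for (j in (i + 1L):length(tags)) {
      if (nchar(tags[i]) == nchar(tags[j])) {
        h <- sum(strsplit(tags[i], NULL)[[1]] != strsplit(tags[j], NULL)[[1]])
        best <- min(best, h)
      }
    }
  }
  if (!is.finite(best)) abort("no equal-length tag pairs for Hamming distance")
  as.integer(best)
}

#' Multiplexing capacity of an index scheme
#'
#' Number of distinguishable libraries given the counts of Read-1 internal
#' indexes, Read-2 internal indexes, i5 primers and i7 primers:
#' `n_r1 * n_r2 * n_i5 * n_i7`. With the 8 x 12 internal sets this gives the
#' 96 within-plate combinations; with two sets of 384 indexed primers the
#' external indexes alone distinguish 147,456 dual-indexed samples, and all
#' four tiers together exceed 14 million.
#'
#' @param n_r1,n_r2,n_i5,n_i7 Positive counts.
#' @return Numeric scalar (the product; may exceed integer range).
#' @examples
#' multiplex_capacity(8, 12, 1, 1)      # 96
#' multiplex_capacity(8, 12, 384, 384)  # 14,155,776
#' @export
multiplex_capacity <- function(n_r1, n_r2, n_i5, n_i7) {
  counts <- c(n_r1 = n_r1, n_r2 = n_r2, n_i5 = n_i5, n_i7 = n_i7)
  if (any(!is.finite(counts)) || any(counts < 1) ||
      any(counts != floor(counts))) {
    abort("all index counts must be positive integers")
  }
  prod(as.numeric(counts))
}

# sites introduced into an assembled adapter by its index tag: motif matches
# overlapping the spliced tag (or its reverse complement) span
introduced_sites <- function(design_row, tag, inset) {
  parts <- adapter_oligo_parts(design_row, tag)
  out <- list()
  for (i in seq_len(nrow(inset))) {
    motif <- inset$recognition[i]
    for (strand in c("top", "bottom")) {
      s <- if (strand == "top") parts$top else parts$bottom_core
      sp <- parts[[paste0("span_", strand)]]
      st <- motif_starts(toupper(s), motif)
      st <- st[st <= sp[2] & (st + nchar(motif) - 1L) >= sp[1]]
      if (length(st)) {
        out[[length(out) + 1L]] <- tibble(
          enzyme = inset$name[i], motif = motif,
          specificity = motif_specificity(motif),
          strand = strand, position = st
        )
      }
    }
  }
  if (length(out)) bind_rows(out) else
    tibble(enzyme = character(), motif = character(),
           specificity = integer(), strand = character(),
           position = integer())
}

#' Validate adapter designs and index sets
#'
#' Runs the design rules the 2RAD/3RAD adapters are built to satisfy and
#' returns a named check report (failures are report rows, not errors):
#'
#' * `dimer_junction` - each Read-1 design's self-ligation junction contains
#'   its set's blocking-enzyme recognition site exactly once.
#' * `index_no_site` - no index tag introduces a recognition site for an
#'   in-set enzyme into its assembled adapter. Sites for motifs with at
#'   least 5 non-degenerate positions fail the check; introduced 4-cutter
#'   sites are reported as warnings only, since such motifs occur in the
#'   published adapters themselves and matter only for specific enzyme
#'   choices.
#' * `edit_distance` - minimum pairwise Levenshtein distance within each
#'   side's index set is at least 3.
#' * `tag_length` - tag lengths lie in 5-9 nt (lengths above 8 are noted:
#'   the published material describes 5-8 nt indexes yet prints 9-nt tags).
#' * `read2_tail` - the Read-2 top (dummy) strand ends in exactly 5 bases
#'   non-complementary to its partner strand.
#' * `overhang_match` - each adapter's overhang mates with the cohesive end
#'   of its assigned enzyme.
#'
#' @param designs Adapter design table ([load_adapter_designs()]), possibly
#'   filtered.
#' @param tags Index tag table ([load_index_tags()]). When `NULL` (default)
#'   the bundled sets are loaded per design with that design's overrides
#'   applied; a supplied table is used verbatim for every design.
#' @param registry Enzyme registry.
#' @return Tibble of class `design_validation` with columns `design`,
#'   `check`, `pass`, `warning`, `detail`.
#' @export
validate_design <- function(designs = load_adapter_designs(),
                            tags = NULL,
                            registry = load_enzyme_registry(quiet = TRUE)) {
  rows <- list()
  add <- function(design, check, pass, detail = "", warning = FALSE) {
    rows[[length(rows) + 1L]] <<- tibble(design = design, check = check,
                                         pass = pass, warning = warning,
                                         detail = detail)
  }
  for (d in sort(unique(designs$design))) {
    dd <- designs[designs$design == d, ]
    r1 <- dd[dd$side == "read1", ]
    r2 <- dd[dd$side == "read2", ]
    sets <- c(r1$set, r2$set)
    inset <- registry[registry$design_set %in% sets, ]
    tag_d <- if (is.null(tags)) load_index_tags(design = d) else tags
    t1 <- tag_d[tag_d$side == "read1", ]
    t2 <- tag_d[tag_d$side == "read2", ]

    # (a) dimer junction carries the blocking site exactly once
    if (nrow(r1) == 1) {
      blocker <- inset[inset$role == "read1_blocking", ]
      blocker <- blocker[!duplicated(sub("-HF$", "", blocker$name)), ]
      ok <- TRUE; det <- character(0)
      for (i in seq_len(nrow(t1))) {
        sl <- simulate_self_ligation(build_adapter(r1, t1[i, ]), registry)
        n_block <- sum(sl$sites$enzyme %in% blocker$name)
        if (!sl$possible || n_block != 1) {
          ok <- FALSE
          det <- c(det, sprintf("index %s: %d blocking site(s)",
                                t1$version[i], n_block))
        }
      }
      add(d, "dimer_junction", ok, paste(det, collapse = "; "))
    }

    # (b) indexes introduce no in-set recognition site
    ok <- TRUE; wrn <- FALSE; det <- character(0)
    for (side_tags in list(list(r1, t1), list(r2, t2))) {
      drow <- side_tags[[1]]
      if (nrow(drow) != 1) next
      tt <- side_tags[[2]]
      for (i in seq_len(nrow(tt))) {
        hits <- introduced_sites(drow, tt$tag[i], inset)
        strong <- hits[hits$specificity >= 5, ]
        weak <- hits[hits$specificity < 5, ]
        if (nrow(strong)) {
          ok <- FALSE
          det <- c(det, sprintf("%s index %s introduces %s site",
                                drow$side, tt$version[i],
                                paste(unique(strong$enzyme), collapse = "/")))
        }
        if (nrow(weak)) {
          wrn <- TRUE
          det <- c(det, sprintf("note: %s index %s introduces 4-cutter %s site",
                                drow$side, tt$version[i],
                                paste(unique(weak$enzyme), collapse = "/")))
        }
      }
    }
    add(d, "index_no_site", ok, paste(det, collapse = "; "), warning = wrn)

    # (c) minimum pairwise edit distance within each side's set
    med1 <- if (nrow(t1) >= 2) min_pairwise_edit_distance(t1$tag) else NA
    med2 <- if (nrow(t2) >= 2) min_pairwise_edit_distance(t2$tag) else NA
    add(d, "edit_distance",
        isTRUE(med1 >= 3) && isTRUE(med2 >= 3),
        sprintf("read1 min %s, read2 min %s", med1, med2))

    # (d) tag lengths within the declared 5-9 nt range
    lens <- nchar(c(t1$tag, t2$tag))
    long <- lens > 8
    add(d, "tag_length", all(lens >= 5 & lens <= 9),
        if (any(long)) sprintf("%d tag(s) of 9 nt (declared range 5-8 in text)",
                               sum(long)) else "",
        warning = any(long))

    # (e) Read-2 dummy-strand tail: exactly 5 terminal non-complementary bases
    if (nrow(r2) == 1) {
      ok <- TRUE; det <- ""
      for (i in seq_len(nrow(t2))) {
        p <- adapter_oligo_parts(r2, t2$tag[i])
        paired <- revcomp(p$bottom_core)  # what a complementary top would be
        top_dup <- substr(p$top, nchar(r2$overhang) + 1L, nchar(p$top))
        ref <- substr(paired, 1L, nchar(top_dup))
        n <- nchar(top_dup)
        tail_obs <- toupper(substr(top_dup, n - 4L, n))
        tail_ref <- substr(ref, n - 4L, n)
        mism <- iupac_mismatches(tail_obs, tail_ref)
        before_ok <- toupper(substr(top_dup, 1, n - 5L)) ==
          substr(ref, 1, n - 5L)
        if (!(mism == 5 && before_ok)) {
          ok <- FALSE
          det <- sprintf("index %s: tail not 5 non-complementary bases",
                         t2$version[i])
        }
      }
      add(d, "read2_tail", ok, det)
    }

    # (f) adapter overhang mates with the assigned enzyme's cohesive end
    for (drow in list(r1, r2)) {
      if (nrow(drow) != 1) next
      enz <- registry[sub("-HF$", "", registry$name) == drow$adapter_enzyme, ]
      if (nrow(enz) == 0) {
        add(d, "overhang_match", FALSE,
            sprintf("%s: enzyme %s not in registry", drow$side,
                    drow$adapter_enzyme))
        next
      }
      enz <- enz[1, ]
      frag_end <- list(kind = "cut", polarity = enz$overhang_kind,
                       overhang = enz$overhang_seq)
      adp_end <- list(kind = "cut", polarity = drow$polarity,
                      overhang = drow$overhang)
      add(d, "overhang_match", ends_compatible(adp_end, frag_end),
          sprintf("%s adapter (%s) vs %s", drow$side, drow$overhang,
                  enz$name))
    }
  }
  out <- if (length(rows)) bind_rows(rows) else
    tibble(design = integer(), check = character(), pass = logical(),
           warning = logical(), detail = character())
  class(out) <- c("design_validation", class(out))
  out
}
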