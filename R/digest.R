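#' Digest a sequence with one or more restriction enzymes
#'
#' Performs a complete double or triple digest of a linear or circular DNA
#' sequence, returning one row per fragment with the cut-end geometry needed
#' downstream: which enzyme produced each end, the single-stranded overhang
#' (read 5'->3' on its own strand) and its polarity.
#'
#' Fragment top strands partition the input at the top-strand cut
#' coordinates, so concatenating `top_seq` over the fragments (counting each
#' overhang once) reconstructs the input exactly. A linear molecule with k
#' cut positions yields k+1 fragments; a circular one yields k fragments (or
#' the uncut circle).
#'
#' Cuts whose top/bottom cleavage intervals intersect (two enzymes cutting at
#' overlapping positions) cannot be resolved into well-formed ends; this is
#' reported as an ambiguity error listing the offending positions rather than
#' guessed at.
#'
#' @inheritParams find_sites
#' @param enzymes Registry slice (rows of an `enzyme_registry`) or character
#'   vector of enzyme names resolved against `registry`.
#' @param record Record id stored with each fragment.
#' @return Tibble of class `rad_fragments`: columns `record`, `frag_id`,
#'   `start`, `length`, `top_seq`, and `left_*` / `right_*` end descriptors
#'   (`kind`, `enzyme`, `overhang`, `polarity`). The input length and
#'   topology are kept as attributes.
#' @examples
#' reg <- load_enzyme_registry(quiet = TRUE)
#' digest("AAATCTAGAAACCCGAATTCCC", c("XbaI", "EcoRI-HF"), registry = reg)
#' @export
digest <- function(seq, enzymes, topology = c("linear", "circular"),
                   registry = NULL, record = "seq") {
  topology <- arg_match(topology)
  if (inherits(seq, "DNAString")) seq <- as.character(seq)
  seq <- check_dna(seq)
  L <- nchar(seq)
  if (is.character(enzymes)) {
    if (is.null(registry)) registry <- load_enzyme_registry(quiet = TRUE)
    enzymes <- dplyr::bind_rows(lapply(enzymes, get_enzyme, registry = registry))
  }
  if (nrow(enzymes) == 0) abort("at least one enzyme is required")

  cuts <- purrr::map_dfr(seq_len(nrow(enzymes)), function(i) {
    e <- enzymes[i, ]
    hits <- find_sites(seq, e, topology)
    if (nrow(hits) == 0) return(tibble())
    t_cut <- hits$motif_start + e$cut_top
    b_cut <- hits$motif_start + e$cut_bottom
    tibble(
      enzyme = e$name,
      motif_start = hits$motif_start,
      t = as.integer(t_cut), b = as.integer(b_cut),
      polarity = e$overhang_kind
    )
  })
  if (nrow(cuts) > 0) {
    # identical geometry from isoschizomers/HF pairs collapses to one cut
    cuts <- cuts %>% distinct(t, b, .keep_all = TRUE) %>% arrange(t)
    iv_lo <- pmin(cuts$t, cuts$b)
    iv_hi <- pmax(cuts$t, cuts$b) - 1L
    if (nrow(cuts) > 1) {
      ovl <- which(iv_lo[-1] <= iv_hi[-nrow(cuts)])
      if (length(ovl)) {
        abort(sprintf(
          "ambiguous digest: intersecting cut intervals at positions %s",
          paste(unique(c(cuts$t[ovl], cuts$t[ovl + 1])), collapse = ", ")))
      }
    }
  }

  blunt_terminal <- list(kind = "terminal", enzyme = NA_character_,
                         overhang = "", polarity = "blunt")
  # end descriptors created by a cut: `left` end of the downstream fragment,
  # `right` end of the upstream fragment
  cut_ends <- function(i) {
    ov_lo <- min(cuts$t[i], cuts$b[i])
    ov_hi <- max(cuts$t[i], cuts$b[i]) - 1L
    region <- if (ov_hi >= ov_lo) {
      substring(paste0(seq, seq), ov_lo, ov_hi)  # may wrap on circles
    } else ""
    pol <- cuts$polarity[i]
    down_ov <- if (pol == "five_prime") region else
      if (pol == "three_prime") revcomp(region) else ""
    up_ov <- if (pol == "five_prime") revcomp(region) else
      if (pol == "three_prime") region else ""
    list(
      down = list(kind = "cut", enzyme = cuts$enzyme[i], overhang = down_ov,
                  polarity = pol),
      up = list(kind = "cut", enzyme = cuts$enzyme[i], overhang = up_ov,
                polarity = pol)
    )
  }

  bshift <- function(end) {
    l <- nchar(end$overhang %||% "")
    switch(end$polarity, five_prime = l, three_prime = -l, 0L)
  }
  frag_row <- function(start, len, left, right, id) {
    s0 <- ((start - 1L) %% L) + 1L
    dbl <- paste0(seq, seq)
    s1 <- bshift(left)
    s2 <- bshift(right)
    # bottom strand of the fragment, read 5'->3' (used when a fragment is
    # flipped inside a ligation product)
    b_lo <- max(1L, s0 + s1)
    b_hi <- min(nchar(dbl), s0 + len - 1L + s2)
    tibble(
      record = record, frag_id = id,
      start = s0, length = as.integer(len),
      top_seq = substring(dbl, s0, s0 + len - 1L),
      bottom_seq = if (b_hi >= b_lo) revcomp(substring(dbl, b_lo, b_hi)) else "",
      left_kind = left$kind, left_enzyme = left$enzyme,
      left_overhang = left$overhang, left_polarity = left$polarity,
      right_kind = right$kind, right_enzyme = right$enzyme,
      right_overhang = right$overhang, right_polarity = right$polarity
    )
  }

  k <- nrow(cuts)
  out <- if (topology == "linear") {
    if (k == 0) {
      frag_row(1L, L, blunt_terminal, blunt_terminal, 1L)
    } else {
      ends <- lapply(seq_len(k), cut_ends)
      bounds <- c(1L, cuts$t)
      lens <- c(cuts$t, L + 1L) - bounds
      purrr::map_dfr(seq_len(k + 1L), function(i) {
        left <- if (i == 1) blunt_terminal else ends[[i - 1]]$down
        right <- if (i == k + 1) blunt_terminal else ends[[i]]$up
        frag_row(bounds[i], lens[i], left, right, i)
      })
    }
  } else {
    if (k == 0) {
      frag_row(1L, L, blunt_terminal, blunt_terminal, 1L)
    } else {
      ends <- lapply(seq_len(k), cut_ends)
      ts <- ((cuts$t - 1L) %% L) + 1L
      ord <- order(ts)
      ts <- ts[ord]
      ends <- ends[ord]
      purrr::map_dfr(seq_len(k), function(i) {
        nxt <- if (i == k) 1L else i + 1L
        len <- if (i == k) (L - ts[i] + ts[1]) else (ts[nxt] - ts[i])
        frag_row(ts[i], len, ends[[i]]$down, ends[[nxt]]$up, i)
      })
    }
  }
  structure(out,
            class = c("rad_fragments", class(out)),
            input_length = L, topology = topology)
}
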