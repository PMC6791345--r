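# Internal sequence helpers. All user-facing sequences are plain uppercase
# character vectors; Biostrings objects are used at the file-format boundary.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), K = c("G", "T"), M = c("A", "C"),
  S = c("C", "G"), W = c("A", "T"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_CHARS <- paste0(names(IUPAC_SETS), collapse = "")

revcomp <- function(x) {
  out <- chartr("ACGTRYKMSWBDHVNacgtrykmswbdhvn",
                "TGCAYRMKSWVHDBNtgcayrmkswvhdbn", x)
  vapply(strsplit(out, NULL), function(s) paste(rev(s), collapse = ""),
         character(1))
}

check_dna <- function(seq, what = "sequence", allow_iupac = TRUE) {
  if (!is.character(seq) || length(seq) != 1 || is.na(seq) || !nzchar(seq)) {
    abort(sprintf("%s must be a non-empty character scalar", what))
  }
  ok_chars <- if (allow_iupac) IUPAC_CHARS else "ACGT"
  bad <- gsub(sprintf("[%s]", ok_chars), "", toupper(seq))
  if (nzchar(bad)) {
    abort(sprintf("%s contains non-IUPAC characters: '%s'", what,
                  paste(unique(strsplit(bad, NULL)[[1]]), collapse = "")))
  }
  toupper(seq)
}

# do two IUPAC letters share at least one concrete base?
iupac_overlap <- function(a, b) {
  sa <- IUPAC_SETS[[a]]
  sb <- IUPAC_SETS[[b]]
  if (is.null(sa) || is.null(sb)) return(FALSE)
  length(intersect(sa, sb)) > 0
}

# number of positions of `obs` incompatible with IUPAC pattern `pat`
# (length mismatch counts as incomparable -> Inf)
iupac_mismatches <- function(obs, pat) {
  if (nchar(obs) != nchar(pat)) return(Inf)
  so <- strsplit(obs, NULL)[[1]]
  sp <- strsplit(pat, NULL)[[1]]
  sum(!mapply(iupac_overlap, so, sp))
}

# regex matching a (possibly degenerate) motif against subjects that may
# themselves contain N (N in the subject matches anything)
iupac_regex <- function(motif) {
  cls <- vapply(strsplit(motif, NULL)[[1]], function(ch) {
    bases <- IUPAC_SETS[[ch]]
    if (length(bases) == 4) "." else paste0("[", paste0(bases, collapse = ""), "N]")
  }, character(1))
  paste0(cls, collapse = "")
}

# all (possibly overlapping) start positions of `motif` in string `s`
motif_starts <- function(s, motif) {
  re <- paste0("(?=", iupac_regex(motif), ")")
  m <- gregexpr(re, s, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

# count of non-fully-degenerate positions (effective specificity of a motif)
motif_specificity <- function(motif) {
  sum(vapply(strsplit(motif, NULL)[[1]],
             function(ch) length(IUPAC_SETS[[ch]]) < 4, logical(1)))
}

# path to a bundled data file
triplerad_file <- function(...) {
  p <- system.file("extdata", ..., package = "triplerad", mustWork = FALSE)
  if (!nzchar(p)) abort(sprintf("bundled file not found: %s", file.path(...)))
  p
}

`%||%` <- rlang::`%||%`
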