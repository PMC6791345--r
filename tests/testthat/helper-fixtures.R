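# Shared fixtures and independent oracles for the test suite.

reg <- load_enzyme_registry(quiet = TRUE)
designs <- load_adapter_designs()
tags_universal <- load_index_tags()

# ---- independent oracles ----------------------------------------------------

# brute-force sliding-window IUPAC matcher (oracle for find_sites)
iupac_sets_oracle <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), K = c("G", "T"), M = c("A", "C"),
  S = c("C", "G"), W = c("A", "T"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

brute_force_sites <- function(seq, motif) {
  k <- nchar(motif)
  mo <- strsplit(motif, NULL)[[1]]
  s <- strsplit(seq, NULL)[[1]]
  hits <- integer(0)
  for (i in seq_len(nchar(seq) - k + 1L)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!(s[i + j - 1L] %in% iupac_sets_oracle[[mo[j]]])) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

# full dynamic-programming Levenshtein matrix (oracle for edit distances)
lev_dp <- function(a, b) {
  sa <- strsplit(a, NULL)[[1]]
  sb <- strsplit(b, NULL)[[1]]
  m <- length(sa)
  n <- length(sb)
  d <- matrix(0L, m + 1L, n + 1L)
  d[, 1] <- 0:m
  d[1, ] <- 0:n
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L,
                               d[i, j] + (sa[i] != sb[j]))
    }
  }
  d[m + 1L, n + 1L]
}

# random DNA string (test-local, independent of the package generator)
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# engineered genome whose XbaI/NheI-to-EcoRI loci fall inside the default
# size window (total molecule length 574 bp for Design 1 tags A/1)
make_locus_genome <- function(n_loci, third_every = 0, seed = 1,
                              spacing = 1300L, insert_gap = 420L) {
  plant_locus_genome(n_loci, third_every = third_every, seed = seed,
                     spacing = spacing, insert_gap = insert_gap,
                     registry = reg)
}

design_side <- function(d, s) designs[designs$design == d & designs$side == s, ]

adapter_for <- function(d, side, version) {
  tg <- load_index_tags(design = d)
  build_adapter(design_side(d, side),
                tg[tg$side == side & tg$version == version, ])
}

no_site_fragments <- function() {
  digest(strrep("A", 1000), "XbaI", registry = reg)[0, ]
}
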