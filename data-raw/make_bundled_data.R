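# Generates the synthetic bundled data under inst/extdata:
#   - index_tags_synthetic.csv   (universal internal index sets; the four
#     published Read-1 and four published Read-2 tags plus synthetic tags
#     completing the 8 x 12 sets under the published constraints)
#   - index_overrides.csv        (per-design tag override table; Design 2 /
#     BamHI replacement for Read-2 index 5)
#   - itru_primers_synthetic.csv (synthetic 8-nt i5/i7 external index sets)
#   - pUC19_synthetic.fasta      (synthetic stand-in for the pUC19 plasmid
#     carrying the documented anchor sites)
# Run from the package root: Rscript data-raw/make_bundled_data.R
# Base R only, independent of the package code.

set.seed(20191011L)

rc <- function(x) chartr("ACGTRYKMBDHVN", "TGCAYRMKVHDBN",
                         sapply(strsplit(x, NULL), function(s) paste(rev(s), collapse = "")))

iupac_regex <- function(motif) {
  map <- c(A = "A", C = "C", G = "G", T = "T",
           R = "[AGN]", Y = "[CTN]", K = "[GTN]", M = "[ACN]",
           B = "[CGTN]", D = "[AGTN]", H = "[ACTN]", V = "[ACGN]", N = ".")
  cls <- map[strsplit(motif, NULL)[[1]]]
  cls <- ifelse(cls %in% c("A", "C", "G", "T"), paste0("[", cls, "N]"), cls)
  paste0(cls, collapse = "")
}

count_motif <- function(seqs, motif) {
  re <- iupac_regex(motif)
  sum(vapply(seqs, function(s) {
    n <- 0L; from <- 1L
    while ((m <- regexpr(re, substr(s, from, nchar(s)))) > 0) {
      n <- n + 1L; from <- from + m
    }
    n
  }, integer(1)))
}

lev <- function(a, b) drop(utils::adist(a, b))

# ---- design constants (Table 2 architecture) --------------------------------
R1_STUB  <- "ACGACGCTCTTCCGATCT"
R1_TAIL  <- "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT"
R2_STUB  <- "GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT"
R2_TAIL  <- "AGATCGGAAGAGCACACGT"
R2_NC    <- "aatcc"

designs <- data.frame(
  design = 1:4,
  r1_overhang = c("CTAG", "CG", "TGCA", "TA"),
  r1_post     = c("G", "AT", "CTGCA", "G"),
  r1_polarity = c("five_prime", "five_prime", "three_prime", "five_prime"),
  r2_overhang = c("AATT", "GATC", "TNA", "AGCT"),
  r2_post     = c("T", "C", "G", "T"),
  stringsAsFactors = FALSE
)

# in-set recognition motifs per design (R1 set + blocking + R2 set)
inset <- list(
  `1` = c("GCTAGC", "TCTAGA", "ACTAGT", "GAATTC", "CAATTG", "RAATTY"),
  `2` = c("ATCGAT", "CCGG", "TCGA", "GGATCC", "TGATCA", "RGATCY"),
  `3` = c("CTGCAG", "ATGCAT", "CTNAG"),
  `4` = c("GTAC", "CATATG", "TTAA", "ATTAAT", "CTAG", "AAGCTT")
)
blocking <- c(`1` = "GCTAGC", `2` = "ATCGAT", `3` = "CTGCAG", `4` = "GTAC")

# assemble oligo strings and the character interval occupied by the tag (top)
# and its reverse complement (bottom for read1, top for read2)
assemble <- function(d, side, tag) {
  row <- designs[designs$design == d, ]
  if (side == "read1") {
    oh <- row$r1_overhang; post <- row$r1_post
    top <- paste0(R1_STUB, tag, post)
    lead <- if (row$r1_polarity == "five_prime") {
      paste0(oh, rc(post))
    } else {
      rc(substr(post, 1, nchar(post) - nchar(oh)))
    }
    bottom <- paste0(lead, rc(tag), R1_TAIL)
    list(top = top, bottom = bottom,
         span_top = nchar(R1_STUB) + c(1L, nchar(tag)),
         span_bottom = nchar(lead) + c(1L, nchar(tag)))
  } else {
    oh <- row$r2_overhang; post <- row$r2_post
    bottom <- paste0(R2_STUB, tag, post)
    top <- paste0(oh, rc(post), rc(tag), R2_TAIL, toupper(R2_NC))
    list(top = top, bottom = bottom,
         span_top = nchar(oh) + nchar(post) + c(1L, nchar(tag)),
         span_bottom = nchar(R2_STUB) + c(1L, nchar(tag)))
  }
}

motif_hits <- function(s, motif) {
  re <- iupac_regex(motif); hits <- integer(0); from <- 1L
  while ((m <- regexpr(re, substr(s, from, nchar(s)))) > 0) {
    hits <- c(hits, from + m - 1L); from <- from + m
  }
  hits
}

# motif matches overlapping the spliced tag region = sites introduced by the
# index; strict rule (any specificity) used for synthetic-tag generation
introduced <- function(d, side, tag, min_spec = 0L) {
  ol <- assemble(d, side, tag)
  out <- character(0)
  for (m in inset[[as.character(d)]]) {
    spec <- sum(strsplit(m, NULL)[[1]] != "N")
    if (spec < min_spec) next
    for (str in c("top", "bottom")) {
      sp <- ol[[paste0("span_", str)]]
      for (h in motif_hits(ol[[str]], m)) {
        if (h <= sp[2] && (h + nchar(m) - 1L) >= sp[1]) out <- c(out, m)
      }
    }
  }
  out
}

tag_ok <- function(tag, side, skip_design = integer(0), min_spec = 0L) {
  for (d in setdiff(1:4, skip_design)) {
    if (length(introduced(d, side, tag, min_spec)) > 0) return(FALSE)
    if (side == "read1") {
      ol <- assemble(d, side, tag)
      dimer <- paste0(ol$top, ol$bottom)   # self-ligation junction strand
      if (length(motif_hits(dimer, blocking[[as.character(d)]])) != 1) return(FALSE)
    }
  }
  TRUE
}

rand_tag <- function(len) paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")

grow_set <- function(published, lengths, side) {
  tags <- published
  for (len in lengths) {
    repeat {
      cand <- rand_tag(len)
      if (all(lev(cand, tags) >= 3) && tag_ok(cand, side)) { tags <- c(tags, cand); break }
    }
  }
  tags
}

# Read-1 universal set: published A-D, synthetic E-H (lengths 6,7,8,9)
r1_pub <- c(A = "CCGAAT", B = "TTAGGCA", C = "AACTCGTC", D = "GGTCTACGT")
stopifnot(all(vapply(r1_pub, tag_ok, TRUE, side = "read1", min_spec = 5L)))
cat("growing R1 set...\n")
r1_tags <- grow_set(r1_pub, c(6, 7, 8, 9), "read1")
cat("R1 set done\n")
names(r1_tags) <- LETTERS[1:8]

# Read-2 universal set: published 1-4; index 5 deliberately recreates GGATCC
# inside the assembled BamHI adapter (Design 2) and is overridden there.
r2_pub <- c(`1` = "CTAACG", `2` = "TCGGTAC", `3` = "GATCGTTG", `4` = "AGCTACACT")
stopifnot(all(vapply(r2_pub, tag_ok, TRUE, side = "read2", min_spec = 5L)))
tag5 <- NULL
for (x in c("A", "C", "G", "T")) {
  cand <- paste0(x, "GGATC")
  if (all(lev(cand, r2_pub) >= 3) && tag_ok(cand, "read2", skip_design = 2L, min_spec = 5L)) { tag5 <- cand; break }
}
stopifnot(!is.null(tag5))
r2_tags <- c(r2_pub, `5` = tag5)
cat("growing R2 set...\n")
for (len in c(7, 8, 9, 6, 7, 8, 9)) {
  repeat {
    cand <- rand_tag(len)
    if (all(lev(cand, r2_tags) >= 3) && tag_ok(cand, "read2")) { r2_tags <- c(r2_tags, cand); break }
  }
}
names(r2_tags) <- as.character(1:12)

cat("R2 set done\n")
# Design-2 override for index 5 (the BamHI exception)
repeat {
  ov5 <- rand_tag(6)
  if (all(lev(ov5, c(r2_tags[names(r2_tags) != "5"], r1_tags)) >= 3) &&
      tag_ok(ov5, "read2")) break
}

src1 <- ifelse(names(r1_tags) %in% names(r1_pub), "published", "synthetic")
src2 <- ifelse(names(r2_tags) %in% names(r2_pub), "published", "synthetic")
tags <- rbind(
  data.frame(side = "read1", version = names(r1_tags), tag = unname(r1_tags), source = src1),
  data.frame(side = "read2", version = names(r2_tags), tag = unname(r2_tags), source = src2)
)
write.csv(tags, "inst/extdata/index_tags_synthetic.csv", row.names = FALSE, quote = FALSE)

overrides <- data.frame(
  design = 2L, side = "read2", version = "5", tag = ov5,
  reason = "universal index 5 creates a BamHI recognition site in the assembled Design 2 Read 2 adapter"
)
write.csv(overrides, "inst/extdata/index_overrides.csv", row.names = FALSE, quote = FALSE)

# ---- synthetic iTru i5/i7 external indexes (8 nt, pairwise Levenshtein >= 3) --
grow_simple <- function(n, len) {
  out <- character(0)
  while (length(out) < n) {
    cand <- rand_tag(len)
    if (length(out) == 0 || all(lev(cand, out) >= 3)) out <- c(out, cand)
  }
  out
}
cat("primers...\n")
i5 <- grow_simple(16, 8)
i7 <- grow_simple(16, 8)
primers <- rbind(
  data.frame(name = sprintf("iTru5_%02d_synth", 1:16), side = "i5", sequence = i5),
  data.frame(name = sprintf("iTru7_%02d_synth", 1:16), side = "i7", sequence = i7)
)
write.csv(primers, "inst/extdata/itru_primers_synthetic.csv", row.names = FALSE, quote = FALSE)

# ---- synthetic pUC19 stand-in ------------------------------------------------
# 2,686 bp circular sequence with the documented anchors:
#   EcoRI GAATTC motif start 395 (reported cut position 396)
#   XbaI  TCTAGA motif start 422 (reported cut position 423)
#   forward primer site (215F) at 215-236, reverse primer site (774R) at 753-774
# and no other Design-1 in-set recognition site anywhere (circularly).
L <- 2686L
plant <- list(
  list(pos = 215L, seq = "AAGGAGAAAATACCGCATCAGG"),
  list(pos = 753L, seq = rc("TAACCGTATTACCGCCTTTGAG")),
  list(pos = 395L, seq = "GAATTC"),
  list(pos = 422L, seq = "TCTAGA")
)
planted_idx <- sort(unique(unlist(lapply(plant, function(p) p$pos:(p$pos + nchar(p$seq) - 1L)))))
cat("pUC19 stand-in...\n")
# the planted GAATTC anchor legitimately matches both EcoRI and degenerate
# ApoI (RAATTY); any match whose window lies inside an anchor span is expected
anchor_ok <- function(st, len) (st >= 395L && st + len - 1L <= 400L) ||
                               (st >= 422L && st + len - 1L <= 427L)
repeat {
  s <- sample(c("A", "C", "G", "T"), L, TRUE)
  for (p in plant) s[p$pos:(p$pos + nchar(p$seq) - 1L)] <- strsplit(p$seq, NULL)[[1]]
  # repair stray in-set sites (scan circularly), never touching planted bases
  for (iter in 1:200) {
    ext <- paste(c(s, s[1:8]), collapse = "")
    bad <- integer(0)
    for (m in inset[["1"]]) {
      for (st in motif_hits(ext, m)) {
        if (st <= L && !anchor_ok(st, nchar(m)))
          bad <- c(bad, st + nchar(m) %/% 2L)
      }
    }
    bad <- ((bad - 1L) %% L) + 1L
    bad <- setdiff(bad, planted_idx)
    if (length(bad) == 0) break
    for (b in bad) s[b] <- sample(setdiff(c("A", "C", "G", "T"), s[b]), 1)
  }
  ext <- paste(c(s, s[1:8]), collapse = "")
  stray <- 0L
  for (m in inset[["1"]]) for (st in motif_hits(ext, m))
    if (st <= L && !anchor_ok(st, nchar(m))) stray <- stray + 1L
  if (stray == 0L) break
}
seq <- paste(s, collapse = "")
stopifnot(substr(seq, 395, 400) == "GAATTC", substr(seq, 422, 427) == "TCTAGA")
lines <- c(
  ">pUC19_synthetic circular synthetic stand-in for pUC19 (L09137): anchor sites EcoRI@396 XbaI@423, primer sites 215F/774R; random elsewhere",
  substring(seq, seq(1, L, 70), pmin(seq(1, L, 70) + 69, L))
)
writeLines(lines, "inst/extdata/pUC19_synthetic.fasta")
cat("done\n")
print(tags); print(overrides); print(head(primers))
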