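---
title: "Models and methods behind triplerad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind triplerad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triplerad)
```

This vignette documents the scientific model the package implements, the
choices made where the protocol description leaves the design open, and
what the synthetic-data tests do and do not demonstrate.

## The molecular model

### Digestion

A restriction enzyme is modelled by its IUPAC recognition motif and two
cut offsets, `cut_top` and `cut_bottom`, measured in bases from the motif
start on the top strand. `cut_top < cut_bottom` yields a 5′ overhang (the
bases between the two cuts, e.g. `CTAG` for XbaI `T^CTAGA`),
`cut_top > cut_bottom` a 3′ overhang (PstI, NsiI), equality a blunt end.
All motifs in the bundled panel are palindromic under IUPAC resolution, so
scanning the top strand finds every site. Reported site positions follow
the plasmid-map convention — the first base 3′ of the top-strand cut
(`motif_start + cut_top`) — which is the convention under which the pUC19
map places XbaI at 423 and EcoRI at 396; the raw motif start is also
returned.

Digestion partitions the top strand at the top-cut coordinates. This makes
sequence conservation exact (concatenating fragment top strands
reconstructs the input, every overhang counted once) and is asserted as a
property over seeded random sequences. Each fragment carries explicit end
descriptors: producing enzyme, overhang sequence *read 5′→3′ on its own
strand*, and polarity. Two ends are ligatable when polarities match and
the overhangs are reverse-complementary after IUPAC resolution; this
orientation-free formulation makes compatibility symmetric and handles the
degenerate DdeI overhang (`TNA`), where a concrete `TCA` end pairs with
`TGA` but not with itself. Circular topology is handled by scanning the
sequence extended by motif length − 1 bases; overlapping cut intervals
from different enzymes (e.g. BfaI inside an XbaI site) are refused with an
ambiguity error rather than resolved arbitrarily.

### Adapters

All four designs share one architecture: a fixed TruSeq-derived stub, an
index slot, and design-specific duplex bases (`post`) plus cohesive-end
overhang. Read-1 adapters are phosphorylated on the bottom strand and can
self-ligate; the junction sequence `post + overhang + rc(post)` is exactly
the blocking enzyme's recognition site (for Design 1, `G + CTAG + C` =
NheI's `GCTAGC`). Read-2 adapters are unphosphorylated and end in five
non-complementary bases (printed lowercase, `aatcc`) so the dummy strand
cannot prime. These facts are not hard-coded: the oligo builder splices
tags into templates and the published oligo strings are regenerated
byte-exactly as a test.

The cut-site remnant — the fixed bases between the internal index and the
first genomic base of a read — follows from junction arithmetic:
`post + motif[cut_top+1 ..]` on Read 1 and
`post + rc(motif[.. cut_bottom])` on Read 2. For Design 1 this yields
`GCTAGA` (XbaI), `GCTAGC` (NheI) and `TAATTC` (EcoRI), the patterns the
demultiplexer checks.

### Ligation–digestion cycling

The reaction is simulated as alternating phases. In a ligation phase all
free sticky ends are randomly matched, and each matched compatible pair
joins with probability `ligation_efficiency` (default 0.9). Matching is
subject to two physical constraints: two Read-2 ends cannot join (no 5′
phosphate on either side) and circularisation is not modelled. In a
digestion phase each junction whose sequence re-creates a recognition site
of an enzyme in the reaction is cleaved with probability
`recut_probability` (default 0.9); the process always ends on a digestion
phase, and the default is two cycles. The protocol literature gives no
kinetics for either step, so both knobs are single per-event probabilities — the
simplest model that reproduces the qualitative behaviour:
adapter-dimers and re-ligated genomic joints are suppressed, while
first-enzyme/adapter junctions (which do not re-create a site) survive.
`recut_probability` is also the stand-in for the open question of the
third enzyme's optimal concentration: at 1.0 no dimer survives, at 0.0
third-enzyme loci are never removed.

Constructs are classified from their unit chain: `desired` (Read-1
adapter, one fragment cut by a primary enzyme on the Read-1 side and a
Read-2 enzyme on the other, Read-2 adapter), `third_site_locus` (the
Read-1 side was cut by the blocking enzyme), `adapter_dimer` (any
adapter–adapter junction), `chimera` (more than one fragment), `dead`
(everything else). Only `desired` and `third_site_locus` constructs with
an intact bottom strand amplify; `nick_probability` (default 0) lets one
model failed bottom-strand sealing.

### PCR, size selection, reads

PCR produces one full-length molecule per amplifiable construct; copy
number is deliberately not modelled at this stage — duplicate multiplicity
is introduced at read generation (`depth`, Poisson or fixed per molecule),
which is where duplicates matter for the data. Molecule length is the
insert plus 136 bp of fixed flowcell/primer segments plus tags; size
selection keeps totals inside `center × (1 ± tol)` inclusive (default
550 bp ± 10 %, i.e. 495–605). Reads are assembled from the molecule
layout, read through into the opposite adapter when the insert is short,
and carry uniform substitution errors only (no indels, constant quality
strings) — sufficient for index/remnant robustness questions, not a
platform error model. In `umi_mode` the i5 index read is replaced by a
fresh random 8-base tag per template molecule, drawn from the 65,536-tag
space.

### Demultiplexing

External indexes use Hamming matching within a tolerance against the
expected (i5, i7) pairs; any tie leaves the read unassigned — with
distance-3 index codes a tie requires at least two errors, so accuracy is
never traded for yield. Internal, variable-length tags are resolved by
testing every candidate tag and requiring a valid remnant immediately
after it; this also disambiguates tags that are prefixes of one another.
Remnant modes mirror two-pass practice: `exact` accepts only the intended
remnant (exact third-enzyme remnants are routed to a third-enzyme bin),
`rescue1` additionally rescues one mismatch to the intended remnant — but
an exact third-enzyme remnant always classifies as third-enzyme, so
sequencing errors can only deflate, never inflate, the third-enzyme
fraction (a deliberate conservative bias) — and `disabled` passes
everything through, flagged. Duplicate removal keys on the 8N tag plus the
first 30 bases of each mate (configurable); the first read per key is
kept.

## Synthetic data and what the tests show

The generator draws i.i.d. bases at a given GC content and plants motif
instances at recorded (or random non-overlapping) positions; chance
occurrences of the same motifs are reported, not removed. The
locus-genome builder places first-enzyme sites 420 bp upstream of
second-enzyme sites so each Design-1 molecule totals 574 bp — inside the
default window — giving deterministic ground truth for round-trip tests.
The default end-to-end check uses 60 loci (every 5th a third-enzyme
locus, i.e. a planted 20 % mixture), a full 96-well plate, fixed depth 4
and zero error rate: about 13,000 read quads, chosen to keep the whole
suite a few minutes on one CPU while leaving the planted-fraction check
enough molecules that three binomial standard errors is a ±2 % band.
With fixed depth the read-level fraction equals the molecule-level
fraction, so the binomial unit for that check is the molecule.

What passing these tests shows: the index/remnant arithmetic, the
dimer-suppression mechanism, partitioning, and duplicate accounting are
internally consistent and deterministic under seeds. What they do not
show: performance on real data — real genomes have repeat structure,
methylation, biased base composition, enzyme-efficiency differences and
platform error spectra that the i.i.d. model and uniform substitution
model do not emulate, and the published retained-read percentages or the
~20 % third-enzyme average observed across real datasets are properties
of those datasets, not targets this simulator can reproduce.

## Numerical and data choices

* **Edit distance** is Levenshtein (indel-aware, as variable-length tags
  require), via base `adist`; Hamming is available for equal-length pairs.
  The test oracle is an independent DP implementation.
* **Index-site validation** counts a recognition site against a tag only
  when the motif match overlaps the spliced tag and the motif has ≥ 5
  non-degenerate positions; introduced 4-cutter sites are warnings. The
  published adapters themselves contain 4-cutter motifs (e.g. `CTAG`
  across the Design-4 tag/stub boundary), so a stricter rule would reject
  the published designs; the BamHI index-5 exception is a 6-cutter and
  fails the check as it should.
* **The registry records the R2.4 entry "HindII-HF" verbatim** with a
  caveat note (it is presumably a typo for HindIII-HF); being blunt it
  cannot mate the set's `AGCT` adapter and is excluded from combination
  enumeration, which then counts 9 × 8 = 72 combinations with HF variants
  collapsed.
* **Bundled index sets and i5/i7 primers** beyond the eight printed
  adapter tags are synthetic stand-ins, generated by seeded search under
  the published constraints (balanced lengths 6/7/8/9, pairwise
  Levenshtein ≥ 3, no introduced sites of any specificity); the
  generation script is `data-raw/make_bundled_data.R`. The Read-2 index 5
  deliberately re-creates `GGATCC` in the BamHI adapter and is overridden
  for Design 2 via the bundled override table, reproducing the published
  exception mechanistically.
* **The pUC19 stand-in** is a random 2,686 bp circular sequence carrying
  the documented anchors (XbaI 423, EcoRI 396, the 215F/774R primer
  sites) and no other Design-1 sites; it is labelled synthetic everywhere
  it appears. On the real GenBank record the same code reports the same
  anchor positions, since the reporting convention was calibrated to the
  plasmid map.
* **Degenerate positions**: `N` in adapter oligos (DdeI designs) is
  treated as matching any base during validation and compatibility
  checks; observed read bases are matched against IUPAC patterns, and an
  observed `N` matches only a fully degenerate pattern position.
* **Determinism**: every stochastic step runs under a locally scoped RNG
  seeded from the configuration; per-well seeds are derived by fixed
  offsets, and rerunning any seeded simulation is byte-identical down to
  the FASTQ files.

## Known limitations

Partial digestion, star activity, methylation blocking and buffer
kinetics are not modelled (activities and flags are data only). Ligation
is single-parameter random matching, not concentration-dependent kinetics;
chimera rates are therefore qualitative. Blunt-end ligation is not
modelled, so the verbatim HindII-HF entry is inert in simulation. Quality
scores are constant, and indel errors are absent, so the demultiplexer's
indel robustness is untested. Copy-number bias across PCR cycles (and its
interaction with size selection near the window edges) is out of scope.
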