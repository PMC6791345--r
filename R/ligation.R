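# Construct model for digestion-ligation cycling.
#
# A construct ("molecule") is an ordered chain of units - genomic fragments
# and adapters - with explicit sticky ends and junction records. The
# molecule's amplified ("top") strand is the concatenation of per-unit
# contributions; fragment contributions are the fragment top strand (or its
# bottom strand when the fragment sits flipped), adapter contributions are
# the strand that survives PCR (the Read-1 and Read-2 functional bottom
# strands, in molecule orientation). Junction records keep the two ligated
# end descriptors plus any recognition motifs spanning the joint, so the
# digestion phase can re-cleave re-created sites (adapter-dimers,
# third-enzyme loci, re-ligated genomic joints).

P5_FLOWCELL <- "AATGATACGGCGACCACCGAGATCTACAC"
P7_FLOWCELL <- "ATCTCGTATGCCGTCTTCTGCTTG"

# ---- unit constructors ------------------------------------------------------

unit_fragment <- function(frag, uid = 0L) {
  list(type = "fragment", uid = uid, frag_id = frag$frag_id,
       fwd = frag$top_seq, rev = frag$bottom_seq,
       end_l = list(kind = frag$left_kind, enzyme = frag$left_enzyme,
                    overhang = frag$left_overhang,
                    polarity = frag$left_polarity, owner = "fragment"),
       end_r = list(kind = frag$right_kind, enzyme = frag$right_enzyme,
                    overhang = frag$right_overhang,
                    polarity = frag$right_polarity, owner = "fragment"))
}

unit_adapter <- function(pair, uid = 0L) {
  bottom_core <- sub(PHOS, "", pair$bottom, fixed = TRUE)
  owner <- if (pair$side == "read1") "adapter_r1" else "adapter_r2"
  sticky <- list(kind = "cut", enzyme = NA_character_,
                 overhang = pair$overhang, polarity = pair$polarity,
                 owner = owner)
  closed <- list(kind = "terminal", enzyme = NA_character_, overhang = "",
                 polarity = "blunt", owner = owner)
  if (pair$side == "read1") {
    # forward = adapter at the molecule's left end; amplified strand is
    # rc(bottom tail) + tag + post, sticky end on the right
    list(type = "r1", uid = uid, tag = pair$tag, version = pair$version,
         post = pair$post,
         fwd = paste0(revcomp(R1_BOTTOM_TAIL), pair$tag, pair$post),
         rev = bottom_core,
         end_l = closed, end_r = sticky)
  } else {
    # forward = adapter at the molecule's right end (contributes the reverse
    # complement of its functional bottom strand); sticky end on the left.
    # The cohesive overhang lives on the dummy top strand, so the forward
    # contribution does not contain it (it is inserted at the junction).
    list(type = "r2", uid = uid, tag = pair$tag, version = pair$version,
         post = pair$post,
         fwd = revcomp(bottom_core),
         rev = bottom_core,
         end_l = sticky, end_r = closed)
  }
}

# ---- molecule helpers -------------------------------------------------------

new_molecule <- function(unit) {
  list(units = list(list(u = unit, orient = 1L)),
       junctions = list(), bottom_ok = TRUE)
}

unit_contrib <- function(entry) if (entry$orient == 1L) entry$u$fwd else entry$u$rev

unit_left_end <- function(entry) if (entry$orient == 1L) entry$u$end_l else entry$u$end_r
unit_right_end <- function(entry) if (entry$orient == 1L) entry$u$end_r else entry$u$end_l

mol_left_end <- function(m) unit_left_end(m$units[[1]])
mol_right_end <- function(m) unit_right_end(m$units[[length(m$units)]])

mol_flip <- function(m) {
  n <- length(m$units)
  m$units <- lapply(rev(m$units), function(e) {
    e$orient <- -e$orient
    e
  })
  m$junctions <- lapply(m$junctions, function(j) {
    list(after = n - j$after, left_end = j$right_end, right_end = j$left_end,
         site_enzymes = j$site_enzymes)
  })
  m
}

# an R2 unit in forward orientation does not carry its cohesive overhang in
# its contribution (the overhang lives on the dummy strand); the duplexed
# overhang bases are inserted at the junction once
junction_ov_ins <- function(right_entry, left_end) {
  if (right_entry$u$type == "r2" && right_entry$orient == 1L) {
    revcomp(left_end$overhang)
  } else ""
}

# recognition motifs whose match spans the junction between two contributions
junction_site_enzymes <- function(left_seq, ov_ins, right_seq, motifs) {
  if (nrow(motifs) == 0) return(character(0))
  w <- max(nchar(motifs$recognition))
  lt <- substr(left_seq, max(1L, nchar(left_seq) - w + 1L), nchar(left_seq))
  rt <- substr(right_seq, 1L, min(w, nchar(right_seq)))
  window <- paste0(lt, ov_ins, rt)
  lo <- nchar(lt)                       # last index on the left side
  hi <- nchar(lt) + nchar(ov_ins) + 1L  # first index on the right side
  hits <- character(0)
  for (i in seq_len(nrow(motifs))) {
    k <- nchar(motifs$recognition[i])
    st <- motif_starts(window, motifs$recognition[i])
    crossing <- st[st <= lo & (st + k - 1L) >= hi]
    if (length(crossing)) hits <- c(hits, motifs$name[i])
  }
  unique(hits)
}

mol_join <- function(a, b, motifs, nick_probability = 0) {
  left_entry <- a$units[[length(a$units)]]
  right_entry <- b$units[[1]]
  le <- mol_right_end(a)
  re <- mol_left_end(b)
  ov_ins <- junction_ov_ins(right_entry, le)
  sites <- junction_site_enzymes(unit_contrib(left_entry), ov_ins,
                                 unit_contrib(right_entry), motifs)
  # ov_ins is not stored: it depends on orientation and is recomputed from
  # the junction's current left end wherever the sequence is assembled
  j <- list(after = length(a$units), left_end = le, right_end = re,
            site_enzymes = sites)
  list(units = c(a$units, b$units),
       junctions = c(a$junctions,
                     list(j),
                     lapply(b$junctions, function(x) {
                       x$after <- x$after + length(a$units)
                       x
                     })),
       bottom_ok = a$bottom_ok && b$bottom_ok &&
         (nick_probability <= 0 || stats::runif(1) >= nick_probability))
}

# split molecule at junction index ji, restoring the stored ends
mol_split <- function(m, ji) {
  j <- m$junctions[[ji]]
  k <- j$after
  left_units <- m$units[seq_len(k)]
  right_units <- m$units[(k + 1L):length(m$units)]
  lj <- purrr::keep(m$junctions, function(x) x$after < k)
  rj <- purrr::keep(m$junctions, function(x) x$after > k)
  rj <- lapply(rj, function(x) {
    x$after <- x$after - k
    x
  })
  list(
    list(units = left_units, junctions = lj, bottom_ok = m$bottom_ok),
    list(units = right_units, junctions = rj, bottom_ok = m$bottom_ok)
  )
}

# full amplified-strand sequence of a molecule chain (tags/posts inclusive)
mol_core_seq <- function(m) {
  jmap <- list()
  for (j in m$junctions) jmap[[as.character(j$after)]] <- j
  out <- unit_contrib(m$units[[1]])
  if (length(m$units) > 1) {
    for (i in 2:length(m$units)) {
      j <- jmap[[as.character(i - 1L)]]
      ov <- if (!is.null(j)) junction_ov_ins(m$units[[i]], j$left_end) else ""
      out <- paste0(out, ov, unit_contrib(m$units[[i]]))
    }
  }
  out
}

# ---- configuration ----------------------------------------------------------

#' Simulation configuration
#'
#' Collects the tunable parameters of the library-construction simulator.
#'
#' @param seed Integer seed driving every stochastic step.
#' @param ligation_efficiency Probability that a matched compatible free end
#'   pair ligates within one ligation phase.
#' @param recut_probability Probability that a re-created recognition site at
#'   a junction is cleaved during one digestion phase (the knob standing in
#'   for the third enzyme's concentration/activity).
#' @param n_cycles Number of alternating ligation-digestion cycles; the
#'   process always ends on a digestion phase. Default 2.
#' @param adapter_excess Adapter copies supplied per genomic fragment.
#' @param nick_probability Probability that a junction's bottom strand fails
#'   to seal (molecules carrying such a nick are not amplifiable).
#' @param size_center,size_tol Size-selection window: total molecule length
#'   within `size_center * (1 +/- size_tol)`, bounds inclusive. Default
#'   550 bp +/- 10 percent.
#' @param read_length Read length in bases.
#' @param depth Expected sequenced clusters per library molecule
#'   (PCR-duplicate multiplicity).
#' @param depth_model `"poisson"` (default) or `"fixed"`.
#' @param error_rate Per-base substitution probability applied to all four
#'   reads.
#' @param umi_mode When `TRUE` the i5 index read is replaced by a random
#'   8-base molecular ID tag drawn per template molecule.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, ligation_efficiency = 0.9,
                       recut_probability = 0.9, n_cycles = 2L,
                       adapter_excess = 3, nick_probability = 0,
                       size_center = 550, size_tol = 0.10,
                       read_length = 150L, depth = 3, depth_model = "poisson",
                       error_rate = 0, umi_mode = FALSE) {
  probs <- c(ligation_efficiency = ligation_efficiency,
             recut_probability = recut_probability,
             nick_probability = nick_probability, error_rate = error_rate)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (n_cycles < 1) abort("n_cycles must be >= 1")
  if (read_length < 20) abort("read_length too short")
  if (!depth_model %in% c("poisson", "fixed")) {
    abort("depth_model must be 'poisson' or 'fixed'")
  }
  structure(list(seed = as.integer(seed),
                 ligation_efficiency = ligation_efficiency,
                 recut_probability = recut_probability,
                 n_cycles = as.integer(n_cycles),
                 adapter_excess = adapter_excess,
                 nick_probability = nick_probability,
                 size_center = size_center, size_tol = size_tol,
                 read_length = as.integer(read_length),
                 depth = depth, depth_model = depth_model,
                 error_rate = error_rate, umi_mode = umi_mode),
            class = "sim_config")
}

# ---- the cycle --------------------------------------------------------------

# fast ligatable test on precollected end records
lig_ok <- function(ea, eb) {
  if (ea$pol != eb$pol || ea$len != eb$len) return(FALSE)
  if (ea$owner == "adapter_r2" && eb$owner == "adapter_r2") return(FALSE)
  if (ea$ov == eb$rc_ov) return(TRUE)
  if (grepl("N", ea$ov, fixed = TRUE) || grepl("N", eb$ov, fixed = TRUE)) {
    return(iupac_mismatches(ea$ov, eb$rc_ov) == 0)
  }
  FALSE
}

#' Run digestion-ligation cycling
#'
#' Simulates the simultaneous digestion/ligation reaction: per cycle, free
#' compatible sticky ends are randomly matched and each matched pair ligates
#' with probability `ligation_efficiency`; then every junction whose
#' sequence re-creates a recognition site of an enzyme in the reaction is
#' cleaved with probability `recut_probability`. The process always ends
#' with a digestion phase - that final digestion is what suppresses
#' adapter-dimers, whose Read-1/Read-1 junction re-creates the blocking
#' enzyme's site. Blunt ends are never joined, Read-2/Read-2 joints are
#' impossible (no 5' phosphate on either side), and circularisation is not
#' modelled.
#'
#' @param fragments A [digest()] result (genomic fragments in the reaction).
#' @param r1_adapter,r2_adapter [build_adapter()] pairs for this well
#'   (either may be `NULL`).
#' @param registry Enzyme registry (roles and motifs).
#' @param config A [sim_config()].
#' @param enzymes Character vector naming the enzymes present in the
#'   reaction; junction re-cutting is restricted to these. Defaults to the
#'   enzymes annotated on the fragments' ends plus, for 3RAD, any blocking
#'   enzyme of the adapters' design sets should be listed explicitly when
#'   the genome carries no site for it.
#' @return A list of classified construct objects (class `rad_construct`).
#' @export
digestion_ligation_cycle <- function(fragments, r1_adapter, r2_adapter,
                                     registry = load_enzyme_registry(quiet = TRUE),
                                     config = sim_config(),
                                     enzymes = NULL) {
  if (is.null(enzymes)) {
    enzymes <- unique(stats::na.omit(c(fragments$left_enzyme,
                                       fragments$right_enzyme)))
  }
  motifs <- registry[registry$name %in% enzymes, c("name", "recognition")]
  with_seed(config$seed, {
    mols <- list()
    uid <- 0L
    add_mol <- function(unit) {
      mols[[length(mols) + 1L]] <<- new_molecule(unit)
    }
    for (i in seq_len(nrow(fragments))) {
      uid <- uid + 1L
      add_mol(unit_fragment(fragments[i, ], uid))
    }
    n_frag <- max(1L, nrow(fragments))
    n_ad <- ceiling(config$adapter_excess * n_frag)
    for (pair in list(r1_adapter, r2_adapter)) {
      if (is.null(pair)) next
      for (i in seq_len(n_ad)) {
        uid <- uid + 1L
        add_mol(unit_adapter(pair, uid))
      }
    }

    collect_ends <- function(mols) {
      out <- list()
      for (mi in seq_along(mols)) {
        m <- mols[[mi]]
        if (is.null(m)) next
        for (side in c("left", "right")) {
          entry <- if (side == "left") m$units[[1]] else
            m$units[[length(m$units)]]
          e <- if (side == "left") mol_left_end(m) else mol_right_end(m)
          if (e$kind != "cut" || e$polarity == "blunt") next
          slot <- if (side == "left") {
            if (entry$orient == 1L) "l" else "r"
          } else {
            if (entry$orient == 1L) "r" else "l"
          }
          out[[length(out) + 1L]] <- list(
            uid = entry$u$uid, slot = slot, mi = mi,
            pol = e$polarity, ov = e$overhang, rc_ov = revcomp(e$overhang),
            len = nchar(e$overhang), owner = e$owner)
        }
      }
      out
    }

    # current location of an end identified by (unit uid, end slot)
    locate <- function(mols, uid, slot) {
      for (mi in seq_along(mols)) {
        m <- mols[[mi]]
        if (is.null(m)) next
        f <- m$units[[1]]
        if (f$u$uid == uid &&
            identical(if (f$orient == 1L) "l" else "r", slot)) {
          return(list(mi = mi, side = "left"))
        }
        l <- m$units[[length(m$units)]]
        if (l$u$uid == uid &&
            identical(if (l$orient == 1L) "r" else "l", slot)) {
          return(list(mi = mi, side = "right"))
        }
      }
      NULL
    }

    ligation_phase <- function(mols) {
      ends <- collect_ends(mols)
      if (length(ends) < 2) return(mols)
      ord <- sample.int(length(ends))
      used <- logical(length(ends))
      for (ii in seq_along(ord)) {
        i <- ord[ii]
        if (used[i]) next
        for (jj in seq_along(ord)) {
          if (jj <= ii) next
          j <- ord[jj]
          if (used[j]) next
          if (!lig_ok(ends[[i]], ends[[j]])) next
          used[c(i, j)] <- TRUE
          if (stats::runif(1) > config$ligation_efficiency) break
          la <- locate(mols, ends[[i]]$uid, ends[[i]]$slot)
          lb <- locate(mols, ends[[j]]$uid, ends[[j]]$slot)
          if (is.null(la) || is.null(lb) || la$mi == lb$mi) break
          a <- mols[[la$mi]]
          b <- mols[[lb$mi]]
          if (la$side == "left") a <- mol_flip(a)
          if (lb$side == "right") b <- mol_flip(b)
          mols[[la$mi]] <- mol_join(a, b, motifs, config$nick_probability)
          mols[lb$mi] <- list(NULL)
          break
        }
      }
      purrr::discard(mols, is.null)
    }

    digestion_phase <- function(mols) {
      out <- list()
      for (m in mols) {
        pieces <- list(m)
        repeat {
          cut_made <- FALSE
          nxt <- list()
          for (p in pieces) {
            ji <- which(vapply(p$junctions,
                               function(j) length(j$site_enzymes) > 0,
                               logical(1)))
            ji <- ji[stats::runif(length(ji)) < config$recut_probability]
            if (length(ji)) {
              nxt <- c(nxt, mol_split(p, ji[1]))
              cut_made <- TRUE
            } else {
              nxt <- c(nxt, list(p))
            }
          }
          pieces <- nxt
          if (!cut_made) break
        }
        out <- c(out, pieces)
      }
      out
    }

    for (cy in seq_len(config$n_cycles)) {
      mols <- ligation_phase(mols)
      mols <- digestion_phase(mols)
    }

    lapply(mols, function(m) {
      m$construct_class <- classify_construct(m, registry)
      class(m) <- "rad_construct"
      m
    })
  })
}

#' Classify a ligation construct
#'
#' Assigns the product class of a construct formed during ligation cycling:
#'
#' * `desired` - Read-1 adapter / primary-enzyme junction / one genomic
#'   fragment / Read-2-enzyme junction / Read-2 adapter;
#' * `third_site_locus` - as desired, but the Read-1-side fragment end was
#'   cut by the blocking (third) enzyme, so the junction re-creates its
#'   recognition site (these survive only when the re-cut misses them);
#' * `adapter_dimer` - any adapter-adapter junction;
#' * `chimera` - more than one genomic fragment in the chain;
#' * `dead` - everything else (missing an adapter, same adapter type at both
#'   ends, bare fragments, lone adapters).
#'
#' @param construct A construct from [digestion_ligation_cycle()].
#' @param registry Enzyme registry (for enzyme roles).
#' @return Character scalar, one of the classes above.
#' @export
classify_construct <- function(construct, registry) {
  m <- construct
  types <- vapply(m$units, function(e) e$u$type, character(1))
  for (j in m$junctions) {
    if (startsWith(j$left_end$owner, "adapter") &&
        startsWith(j$right_end$owner, "adapter")) {
      return("adapter_dimer")
    }
  }
  n_frag <- sum(types == "fragment")
  if (n_frag > 1) return("chimera")
  if (n_frag == 0) return("dead")
  if (length(types) != 3) return("dead")
  if (types[1] == "r2" && types[3] == "r1") {
    m <- mol_flip(m)
    types <- rev(types)
  }
  if (!(types[1] == "r1" && types[2] == "fragment" && types[3] == "r2")) {
    return("dead")
  }
  role_of <- function(enz) {
    if (is.na(enz)) return(NA_character_)
    r <- registry$role[registry$name == enz]
    if (length(r)) r[1] else NA_character_
  }
  r1_role <- role_of(unit_left_end(m$units[[2]])$enzyme)
  r2_role <- role_of(unit_right_end(m$units[[2]])$enzyme)
  if (identical(r2_role, "read2")) {
    if (identical(r1_role, "read1_primary")) return("desired")
    if (identical(r1_role, "read1_blocking")) return("third_site_locus")
  }
  "dead"
}

#' Is a construct amplifiable by PCR?
#'
#' Only constructs whose continuous bottom strand carries both adapter
#' sequences amplify: the class must be `desired` or `third_site_locus` and
#' every junction's bottom strand must have sealed (no nick).
#'
#' @param construct A classified construct.
#' @return `TRUE` or `FALSE`.
#' @export
amplifiable <- function(construct) {
  isTRUE(construct$bottom_ok) &&
    construct$construct_class %in% c("desired", "third_site_locus")
}
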