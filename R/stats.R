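# demux_stats: the accounting object produced by demux_run(). Per-sample
# counts, unassigned counts by failure reason, and pooled fractions.

new_demux_stats <- function(binned, layout, config, n_input,
                            duplicate_fraction = NA_real_) {
  if (nrow(binned) == 0) {
    per_sample <- tibble(sample_id = character(), well = character(),
                         n_reads = integer(), n_intended = integer(),
                         n_third = integer(), n_passthrough = integer(),
                         n_fail = integer(), n_loci = integer(),
                         normalized_coverage = numeric())
    unassigned <- tibble(reason = character(), n = integer())
  } else {
    assigned <- binned %>% filter(is.na(reason))
    per_sample <- assigned %>%
      group_by(sample_id, well) %>%
      summarise(
        n_reads = n(),
        n_intended = sum(classification == "intended", na.rm = TRUE),
        n_third = sum(classification == "third_enzyme", na.rm = TRUE),
        n_passthrough = sum(classification == "passthrough", na.rm = TRUE),
        n_fail = sum(classification == "fail", na.rm = TRUE),
        # locus proxy: distinct 30-base prefixes of the trimmed forward read;
        # normalized coverage = mean per-locus coverage / retained reads
        n_loci = dplyr::n_distinct(substr(r1_out, 1, 30)),
        normalized_coverage = (n_reads / n_loci) / n_reads,
        .groups = "drop"
      )
    unassigned <- binned %>%
      filter(!is.na(reason)) %>%
      count(reason, name = "n")
  }
  n_assigned <- sum(per_sample$n_reads)
  n_third_total <- sum(per_sample$n_third)
  n_retained <- if (nrow(binned)) {
    sum(!startsWith(binned$bin, "unassigned") & binned$bin != "third_enzyme")
  } else 0L
  structure(list(
    per_sample = per_sample,
    unassigned = unassigned,
    n_input = n_input,
    n_assigned = n_assigned,
    retained_fraction = if (n_input > 0) n_retained / n_input else NA_real_,
    third_enzyme_fraction = if (n_assigned > 0) {
      s <- sum(per_sample$n_intended) + n_third_total
      if (s > 0) n_third_total / s else NA_real_
    } else NA_real_,
    duplicate_fraction = duplicate_fraction,
    mode = config$radcheck_mode,
    reads = binned
  ), class = "demux_stats")
}

#' @export
print.demux_stats <- function(x, ...) {
  cat(sprintf("<demux_stats> %d reads: %d assigned (%.1f%% retained), %d sample bins\n",
              x$n_input, x$n_assigned,
              100 * (x$retained_fraction %||% NA), nrow(x$per_sample)))
  if (!is.na(x$third_enzyme_fraction)) {
    cat(sprintf("  third-enzyme fraction: %.3f\n", x$third_enzyme_fraction))
  }
  if (!is.na(x$duplicate_fraction)) {
    cat(sprintf("  duplicate fraction: %.3f\n", x$duplicate_fraction))
  }
  if (nrow(x$unassigned)) {
    cat("  unassigned:",
        paste(sprintf("%s=%d", x$unassigned$reason, x$unassigned$n),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a demux_stats object
#'
#' One row per sample with read counts and per-sample third-enzyme
#' fraction (broom-style).
#'
#' @param x A `demux_stats` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.demux_stats <- function(x, ...) {
  x$per_sample %>%
    mutate(third_fraction = if_else(n_intended + n_third > 0,
                                    n_third / (n_intended + n_third),
                                    NA_real_))
}

#' One-row summary of a demux run
#'
#' @param x A `demux_stats` object.
#' @param ... Unused.
#' @return A one-row tibble: input/assigned counts, retained fraction,
#'   pooled third-enzyme fraction, duplicate fraction.
#' @export
glance.demux_stats <- function(x, ...) {
  tibble(
    n_input = x$n_input,
    n_assigned = x$n_assigned,
    n_samples = nrow(x$per_sample),
    retained_fraction = x$retained_fraction,
    third_enzyme_fraction = x$third_enzyme_fraction,
    duplicate_fraction = x$duplicate_fraction
  )
}

#' Third-enzyme locus proportion
#'
#' Per-sample and pooled proportion of reads whose Read-1 cut-site remnant
#' came from the blocking (third) enzyme rather than the intended first
#' enzyme: `n_third / (n_intended + n_third)`. Samples with no classified
#' reads are reported as missing.
#'
#' @param stats A `demux_stats` object.
#' @return List with `per_sample` (tibble `sample_id`, `proportion`),
#'   `pooled` (all samples pooled), `mean` and `sd` (across samples).
#' @export
third_enzyme_proportion <- function(stats) {
  ps <- stats$per_sample %>%
    mutate(proportion = if_else(n_intended + n_third > 0,
                                n_third / (n_intended + n_third),
                                NA_real_)) %>%
    select(sample_id, well, n_intended, n_third, proportion)
  tot <- sum(ps$n_intended) + sum(ps$n_third)
  list(
    per_sample = ps,
    pooled = if (tot > 0) sum(ps$n_third) / tot else NA_real_,
    mean = mean(ps$proportion, na.rm = TRUE),
    sd = stats::sd(ps$proportion, na.rm = TRUE)
  )
}
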