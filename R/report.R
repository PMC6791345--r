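#' Render a report object as text or JSON-ready structure
#'
#' Stable rendering for the package's report objects (demultiplexing stats
#' and design-validation reports): `"text"` gives a human-readable character
#' vector, `"json"` a list ready for `jsonlite::write_json()` with a stable
#' schema.
#'
#' @param x A `demux_stats` or `design_validation` object (or a bare list,
#'   passed through for JSON).
#' @param format `"text"` or `"json"`.
#' @return Character vector (`"text"`) or list (`"json"`).
#' @export
render_report <- function(x, format = c("text", "json")) {
  UseMethod("render_report")
}

#' @export
render_report.default <- function(x, format = c("text", "json")) {
  format <- arg_match(format)
  if (format == "json") return(x)
  utils::capture.output(print(x))
}

#' @export
render_report.demux_stats <- function(x, format = c("text", "json")) {
  format <- arg_match(format)
  if (format == "json") {
    return(list(
      n_input = x$n_input,
      n_assigned = x$n_assigned,
      retained_fraction = round(x$retained_fraction, 6),
      third_enzyme_fraction = if (is.na(x$third_enzyme_fraction)) NULL else
        round(x$third_enzyme_fraction, 6),
      duplicate_fraction = if (is.na(x$duplicate_fraction)) NULL else
        round(x$duplicate_fraction, 6),
      mode = x$mode,
      per_sample = as.data.frame(tidy(x)),
      unassigned = as.data.frame(x$unassigned)
    ))
  }
  ps <- tidy(x)
  c(sprintf("demultiplexing report (%s mode)", x$mode),
    sprintf("  input reads:      %d", x$n_input),
    sprintf("  assigned reads:   %d (retained %.2f%%)", x$n_assigned,
            100 * x$retained_fraction),
    if (!is.na(x$third_enzyme_fraction)) {
      sprintf("  third-enzyme:     %.2f%% of classified reads",
              100 * x$third_enzyme_fraction)
    },
    sprintf("  samples:          %d", nrow(ps)),
    vapply(seq_len(nrow(ps)), function(i) {
      sprintf("    %-14s %6d reads (intended %d, third %d)",
              ps$sample_id[i], ps$n_reads[i], ps$n_intended[i], ps$n_third[i])
    }, character(1)),
    if (nrow(x$unassigned)) {
      c("  unassigned:",
        sprintf("    %-18s %d", x$unassigned$reason, x$unassigned$n))
    })
}

#' @export
render_report.design_validation <- function(x, format = c("text", "json")) {
  format <- arg_match(format)
  if (format == "json") {
    return(list(all_pass = all(x$pass),
                checks = as.data.frame(as_tibble(x))))
  }
  c("adapter design validation",
    vapply(seq_len(nrow(x)), function(i) {
      sprintf("  design %d %-16s %s%s%s",
              x$design[i], x$check[i],
              if (x$pass[i]) "PASS" else "FAIL",
              if (x$warning[i]) " (warning)" else "",
              if (nzchar(x$detail[i])) paste0("  [", x$detail[i], "]") else "")
    }, character(1)),
    sprintf("  overall: %s", if (all(x$pass)) "all checks pass" else
      "FAILURES present"))
}

# run manifest: one per CLI output directory
write_manifest <- function(dir, subcommand, config, inputs = character(0),
                           seed = NULL) {
  digests <- if (length(inputs)) {
    files <- inputs[file.exists(inputs)]
    as.list(tools::md5sum(files))
  } else list()
  manifest <- list(
    tool = "triplerad",
    version = as.character(utils::packageVersion("triplerad")),
    subcommand = subcommand,
    seed = seed,
    config = config,
    input_digests = digests,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}
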