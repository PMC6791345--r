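#' Build a 96-well (or sub-) plate layout
#'
#' Assigns internal index pairs across a plate: Read-1 adapter versions by
#' row (A-H) and Read-2 versions by column (1-12), so the full plate yields
#' 96 distinct internal index combinations and samples can be pooled right
#' after ligation. External (i5, i7) primer indexes are recorded per plate
#' (or per well, if vectors are supplied).
#'
#' @param design Adapter design number (1-4); selects the bundled tag sets
#'   with that design's overrides applied.
#' @param rows,cols Row letters (Read-1 versions) and column numbers
#'   (Read-2 versions) to use; defaults give the full 8 x 12 plate.
#' @param i5,i7 External index sequences (length 1, recycled, or one per
#'   well).
#' @param plate_id Plate identifier stored with each well.
#' @param tags Index tag table; defaults to the bundled sets for `design`.
#' @return Tibble of class `plate_layout` with columns `plate_id`, `well`,
#'   `row`, `col`, `r1_version`, `r2_version`, `r1_tag`, `r2_tag`, `i5`,
#'   `i7`, `sample_id`, `design`.
#' @examples
#' layout <- make_plate_layout(design = 1, i5 = "TACCGCTA", i7 = "AGTCGCTT")
#' nrow(layout)  # 96
#' @export
make_plate_layout <- function(design = 1, rows = LETTERS[1:8], cols = 1:12,
                              i5 = "NNNNNNNN", i7 = "NNNNNNNN",
                              plate_id = "plate1",
                              tags = load_index_tags(design = design)) {
  t1 <- setNames(tags$tag[tags$side == "read1"],
                 tags$version[tags$side == "read1"])
  t2 <- setNames(tags$tag[tags$side == "read2"],
                 tags$version[tags$side == "read2"])
  if (!all(rows %in% names(t1))) {
    abort(sprintf("no Read-1 tag for version(s): %s",
                  paste(setdiff(rows, names(t1)), collapse = ", ")))
  }
  if (!all(as.character(cols) %in% names(t2))) {
    abort(sprintf("no Read-2 tag for version(s): %s",
                  paste(setdiff(as.character(cols), names(t2)), collapse = ", ")))
  }
  grid <- tidyr::crossing(row = rows, col = as.integer(cols)) %>%
    arrange(match(row, rows), col)
  n <- nrow(grid)
  layout <- grid %>%
    mutate(
      plate_id = plate_id,
      well = sprintf("%s%02d", row, col),
      r1_version = row,
      r2_version = as.character(col),
      r1_tag = unname(t1[r1_version]),
      r2_tag = unname(t2[r2_version]),
      i5 = rep_len(toupper(i5), n),
      i7 = rep_len(toupper(i7), n),
      sample_id = paste0(plate_id, "_", well),
      design = as.integer(design)
    ) %>%
    select(plate_id, well, row, col, r1_version, r2_version, r1_tag, r2_tag,
           i5, i7, sample_id, design)
  validate_plate_layout(layout)
}

#' Validate a plate layout
#'
#' Checks that every sample is distinguishable: no two wells may share the
#' same internal (Read-1, Read-2) tag pair together with the same external
#' (i5, i7) pair, and sample ids must be unique.
#'
#' @param layout A plate-layout tibble (see [make_plate_layout()]).
#' @return The layout, invisibly classed `plate_layout`; errors on duplicate
#'   assignments.
#' @export
validate_plate_layout <- function(layout) {
  needed <- c("well", "r1_version", "r2_version", "r1_tag", "r2_tag",
              "i5", "i7", "sample_id")
  missing_cols <- setdiff(needed, names(layout))
  if (length(missing_cols)) {
    abort(sprintf("plate layout missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  key <- paste(layout$r1_tag, layout$r2_tag, layout$i5, layout$i7)
  if (anyDuplicated(key)) {
    dups <- layout$well[duplicated(key) | duplicated(key, fromLast = TRUE)]
    abort(sprintf(
      "plate layout validation error: wells %s share identical internal and external index pairs",
      paste(unique(dups), collapse = ", ")))
  }
  if (anyDuplicated(layout$sample_id)) {
    abort("plate layout validation error: duplicate sample_id")
  }
  if (!inherits(layout, "plate_layout")) {
    class(layout) <- c("plate_layout", class(layout))
  }
  layout
}

#' Read / write plate layouts as CSV
#'
#' @param path CSV file path.
#' @rdname plate_layout_io
#' @return `read_plate_layout()` returns a validated `plate_layout` tibble.
#' @export
read_plate_layout <- function(path) {
  layout <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                            col_types = readr::cols(.default = "c"))
  for (cl in intersect(c("design", "col"), names(layout))) {
    layout[[cl]] <- as.integer(layout[[cl]])
  }
  validate_plate_layout(layout)
}

#' @param layout Plate layout tibble.
#' @rdname plate_layout_io
#' @export
write_plate_layout <- function(layout, path) {
  readr::write_csv(as_tibble(layout), path, progress = FALSE)
  invisible(path)
}
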