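#' Remove PCR duplicates using molecular ID tags
#'
#' Implements clone filtering for molecular-ID-tagged (8N) libraries: the
#' duplicate key is the 8N tag carried by the I2 read combined with the
#' first `umi_key_length` bases of each mate, so two template molecules
#' that happen to share a tag are kept apart by their inserts. The first
#' read encountered per key is retained.
#'
#' @param reads Read-quad tibble (`read_id`, `r1`, `r2`, `i2`, ...); the
#'   `i2` column must carry the molecular ID tag.
#' @param config [demux_config()] (uses `umi_key_length`).
#' @return List: `reads` (deduplicated tibble), `n_total`, `n_unique`,
#'   `duplicate_fraction` (`1 - unique/total`).
#' @export
clone_filter <- function(reads, config = demux_config(umi_mode = TRUE)) {
  if (!"i2" %in% names(reads) || all(is.na(reads$i2))) {
    abort("clone_filter requires an I2 stream carrying the molecular ID tag")
  }
  k <- config$umi_key_length
  key <- paste(reads$i2, substr(reads$r1, 1L, k), substr(reads$r2, 1L, k),
               sep = "|")
  keep <- !duplicated(key)
  list(
    reads = reads[keep, , drop = FALSE],
    n_total = nrow(reads),
    n_unique = sum(keep),
    duplicate_fraction = if (nrow(reads) > 0) 1 - sum(keep) / nrow(reads)
    else NA_real_
  )
}
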