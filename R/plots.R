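#' Fragment length distribution plot
#'
#' Histogram of digest fragment lengths, optionally with the size-selection
#' window marked - the standard first look when choosing an enzyme
#' combination for a genome.
#'
#' @param fragments A [digest()] result.
#' @param size_center,size_tol Optional size window to mark (total library
#'   length is the insert plus ~136 bp of fixed adapter/primer sequence,
#'   plus tags; the marked window here is on fragment length as plotted).
#' @param binwidth Histogram bin width in bp.
#' @return A ggplot object.
#' @export
plot_fragment_lengths <- function(fragments, size_center = NULL,
                                  size_tol = 0.10, binwidth = 100) {
  p <- ggplot2::ggplot(as_tibble(fragments),
                       ggplot2::aes(x = length)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey35") +
    ggplot2::labs(x = "fragment length (bp)", y = "fragments") +
    ggplot2::theme_minimal()
  if (!is.null(size_center)) {
    p <- p + ggplot2::geom_vline(
      xintercept = size_center * c(1 - size_tol, 1 + size_tol),
      linetype = "dashed", colour = "firebrick")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-sample demultiplexing results
#'
#' Stacked per-sample read counts split by cut-site classification.
#'
#' @param object A `demux_stats` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.demux_stats <- function(object, ...) {
  ps <- tidy(object) %>%
    tidyr::pivot_longer(c(n_intended, n_third, n_passthrough, n_fail),
                        names_to = "classification", values_to = "n") %>%
    mutate(classification = sub("^n_", "", classification)) %>%
    filter(n > 0)
  ggplot2::ggplot(ps, ggplot2::aes(x = sample_id, y = n,
                                   fill = classification)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "reads", fill = "cut-site") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}
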