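#' Plot the cross-sequence overlap of reproducible features
#'
#' Bar chart of the exact-subset intersection counts from
#' [overlap_summary()], filled by feature family, with subsets ordered by
#' the number of sequences they span.
#'
#' @param overlap output of [overlap_summary()].
#' @return A ggplot object.
#' @export
plot_overlap <- function(overlap) {
  if (nrow(overlap) == 0L) {
    abort("plot_overlap: no reproducible features to plot")
  }
  lev <- unique(overlap$subset)
  overlap$subset <- factor(overlap$subset, levels = lev)
  ggplot2::ggplot(overlap,
                  ggplot2::aes(x = .data$subset, y = .data$n_features,
                               fill = .data$family)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "sequences sharing the feature",
                  y = "reproducible features", fill = "family") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a threshold sensitivity sweep
#'
#' Line plot of reproducible-feature and cluster counts against the CCC
#' threshold, one curve per ICC threshold, facetted by metric (and by
#' sequence when more than one is present).
#'
#' @param sweep output of [threshold_sweep()].
#' @param sequence optional single sequence to display.
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep, sequence = NULL) {
  d <- sweep
  if (!is.null(sequence)) d <- d[d$sequence %in% sequence, , drop = FALSE]
  if (nrow(d) == 0L) abort("plot_sweep: empty sweep grid")
  long <- tidyr::pivot_longer(d, c("n_reproducible", "n_clusters"),
                              names_to = "metric", values_to = "n")
  long$metric <- factor(long$metric, levels = c("n_reproducible",
                                                "n_clusters"),
                        labels = c("reproducible features",
                                   "redundancy clusters"))
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = .data$ccc_threshold, y = .data$n,
                                    colour = factor(.data$icc_threshold))) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "CCC threshold", y = "count",
                  colour = "ICC threshold") +
    ggplot2::theme_minimal()
  if (length(unique(long$sequence)) > 1L) {
    p + ggplot2::facet_grid(metric ~ sequence, scales = "free_y")
  } else {
    p + ggplot2::facet_wrap(~metric, scales = "free_y")
  }
}
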