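#' Bar chart of classification categories
#'
#' @param object A `hilcis_classification`.
#' @param which `"inheritance"` or `"regulatory"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hilcis_classification <- function(object,
                                           which = c("inheritance", "regulatory"),
                                           ...) {
  which <- match.arg(which)
  dat <- filter(tidy(object), .data$which == !!which)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(
      x = NULL, y = "genes",
      title = sprintf(
        "%s categories%s", which,
        if (!is.null(attr(object, "hil"))) paste0(" (", attr(object, "hil"), ")") else ""
      )
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Tile heatmap of a cross-HIL concordance matrix
#'
#' @param object A `hilcis_concordance`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hilcis_concordance <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$category_a, y = .data$category_b, fill = .data$n)
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(
      ggplot2::aes(label = .data$n),
      colour = "white", size = 3
    ) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = "HIL A category", y = "HIL B category",
      title = sprintf(
        "%s concordance: %s%% on the diagonal", object$which,
        format(round_half_up(100 * object$diagonal_fraction))
      )
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Mapping-delta scatter along a chromosome
#'
#' Plots per-gene dual-reference mapping deltas against position, with called
#' introgression segments shaded - the diagnostic view used to read off
#' introgression boundaries.
#'
#' @param deltas Output of [mapping_deltas()].
#' @param segments Optional output of [segment_introgression()].
#' @param chrom Chromosome to show (default `"X"`).
#' @param threshold Delta threshold drawn as a horizontal line.
#' @return A ggplot.
#' @export
plot_deltas <- function(deltas, segments = NULL, chrom = "X", threshold = 1) {
  dat <- filter(as_tibble(deltas), .data$chrom == !!chrom)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$position, y = .data$delta)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2, colour = "red") +
    ggplot2::labs(
      x = sprintf("position on %s (bp)", chrom),
      y = "log2(mean+0.1) refB - refN"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(segments) && nrow(segments) > 0) {
    seg <- filter(as_tibble(segments), .data$chrom == !!chrom)
    if (nrow(seg) > 0) {
      p <- p + ggplot2::annotate(
        "rect",
        xmin = seg$start, xmax = seg$end, ymin = -Inf, ymax = Inf,
        alpha = 0.15, fill = "steelblue"
      )
    }
  }
  p
}
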