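# ggplot2 visualisations.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot intra/inter distance distributions and the barcoding gap
#'
#' @param object A [distance_summary()] result.
#' @param binwidth Histogram bin width (distance units).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.distance_summary <- function(object, binwidth = 0.005, ...) {
  gap <- tryCatch(barcoding_gap(object), error = function(e) NULL)
  p <- ggplot2::ggplot(object$pairs,
                       ggplot2::aes(x = .data$distance, fill = .data$class)) +
    ggplot2::geom_histogram(binwidth = binwidth, position = "identity",
                            alpha = 0.6, boundary = 0) +
    ggplot2::labs(
      x = paste0("pairwise ", toupper(object$model), " (Ts) distance"),
      y = "sequence pairs", fill = NULL,
      title = "Intra- vs interspecific distance distributions"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(gap)) {
    p <- p +
      ggplot2::geom_vline(xintercept = c(gap$upper_intra, gap$lower_inter),
                          linetype = "dashed")
  }
  p
}

#' Tile plot of the panel haplotypes at their variable positions
#'
#' @param object A `reference_panel`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reference_panel <- function(object, ...) {
  haps <- object$haplotypes
  pos <- object$sites$rcrs
  long <- purrr::map_dfr(pos, function(p) {
    i <- rcrs_to_fragment_index(p) + 1L
    tibble::tibble(
      haplotype_id = haps$haplotype_id,
      group = haps$group,
      rcrs = factor(p, levels = pos),
      base = substr(haps$sequence, i, i)
    )
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rcrs, y = .data$haplotype_id,
                                     fill = .data$base)) +
    ggplot2::geom_tile(colour = "grey85") +
    ggplot2::geom_text(ggplot2::aes(label = .data$base), size = 2.5) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$group), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = "rCRS position", y = NULL, fill = "base",
                  title = "Reference haplotypes at the 14 variable positions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Bar chart of primer-region mismatch totals per species
#'
#' @param data Output of [tabulate_primer_mismatches()].
#' @return A ggplot object.
#' @export
plot_mismatch_profile <- function(data = tabulate_primer_mismatches()) {
  long <- tidyr::pivot_longer(
    data, c("forward_mismatches", "reverse_mismatches"),
    names_to = "region", values_to = "mismatches"
  )
  ggplot2::ggplot(long,
                  ggplot2::aes(x = stats::reorder(.data$species, .data$total),
                               y = .data$mismatches, fill = .data$region)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "differential nucleotides (IUPAC-aware)",
                  fill = NULL,
                  title = "Primer-region differentials across species") +
    ggplot2::theme_minimal()
}
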