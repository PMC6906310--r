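# broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a distance summary into per-class range rows
#'
#' @param x A [distance_summary()] result.
#' @param ... Unused.
#' @return Tibble with one row per intra-species / inter-species-pair
#'   class: `class`, `unit`, `n_pairs`, `min`, `max`, `mean`, `sd`.
#' @export
tidy.distance_summary <- function(x, ...) {
  x$per_label
}

#' One-row overview of a distance summary
#'
#' @param x A [distance_summary()] result.
#' @param ... Unused.
#' @return One-row tibble with the model, pair counts and the
#'   barcoding-gap quantities.
#' @export
glance.distance_summary <- function(x, ...) {
  ov <- x$overall
  has <- function(cl) cl %in% ov$class
  gap <- if (has("intra") && has("inter")) barcoding_gap(x) else
    tibble::tibble(upper_intra = NA_real_, lower_inter = NA_real_,
                   gap_width = NA_real_)
  tibble::tibble(
    model = x$model,
    n_intra_pairs = if (has("intra")) ov$n_pairs[ov$class == "intra"] else 0L,
    n_inter_pairs = if (has("inter")) ov$n_pairs[ov$class == "inter"] else 0L,
    upper_intra = gap$upper_intra,
    lower_inter = gap$lower_inter,
    gap_width = gap$gap_width
  )
}

#' Tidy a reference panel into its site table
#'
#' @param x A `reference_panel`.
#' @param ... Unused.
#' @return The panel's site tibble (`rcrs`, `fragment_index`,
#'   `interspecific`, `s_clade_specific`).
#' @export
tidy.reference_panel <- function(x, ...) {
  x$sites
}

#' One-row overview of a reference panel
#'
#' @param x A `reference_panel`.
#' @param ... Unused.
#' @return One-row tibble of panel-level counts.
#' @export
glance.reference_panel <- function(x, ...) {
  tibble::tibble(
    n_haplotypes = nrow(x$haplotypes),
    n_groups = length(unique(x$haplotypes$group)),
    n_variable_sites = nrow(x$sites),
    n_interspecific_sites = length(interspecific_sites(x)),
    n_s_clade_sites = length(s_clade_sites(x)),
    compared_sites = if (is.null(x$exclude_site)) INSERT_LEN
                     else INSERT_LEN - 1L
  )
}
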