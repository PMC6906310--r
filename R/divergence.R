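# Transitions-only p and K2P distances, intra/inter range summaries,
# barcoding-gap statistic and nucleotide diversity.

#' Compare two aligned sequences position by position
#'
#' Positions where either sequence carries anything other than a concrete
#' base (N, gap, ambiguity code) are excluded from the comparison (pairwise
#' deletion). Transitions are A<->G and C<->T; every other difference is a
#' transversion.
#'
#' @param a,b Equal-length aligned sequences.
#' @return Object of class `pairwise_comparison` with fields
#'   `compared_sites`, `ts_diffs`, `tv_diffs`, `P` (transitions per compared
#'   site) and `Q` (transversions per compared site).
#' @examples
#' compare_pair("ACGT", "ACGA")
#' @export
compare_pair <- function(a, b) {
  ca <- .seq_chars(a)
  cb <- .seq_chars(b)
  if (length(ca) != length(cb)) {
    stop("alignment error: sequences have lengths ", length(ca), " and ",
         length(cb), call. = FALSE)
  }
  concrete <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  ca <- ca[concrete]
  cb <- cb[concrete]
  diff <- ca != cb
  purine <- c("A", "G")
  ts <- diff & ((ca %in% purine) == (cb %in% purine))
  n <- sum(concrete)
  structure(
    list(
      compared_sites = n,
      ts_diffs = sum(ts),
      tv_diffs = sum(diff & !ts),
      P = if (n > 0L) sum(ts) / n else NaN,
      Q = if (n > 0L) sum(diff & !ts) / n else NaN
    ),
    class = "pairwise_comparison"
  )
}

#' @export
print.pairwise_comparison <- function(x, ...) {
  cat("<pairwise_comparison> sites:", x$compared_sites,
      " ts:", x$ts_diffs, " tv:", x$tv_diffs, "\n")
  invisible(x)
}

.as_comparison <- function(x) {
  if (inherits(x, "pairwise_comparison")) return(x)
  stop("expected a pairwise_comparison (see compare_pair())", call. = FALSE)
}

#' Transitions-only p-distance
#'
#' The proportion of compared sites at which the two sequences differ by a
#' transition.
#'
#' @param comparison A [compare_pair()] result.
#' @return Numeric distance.
#' @export
p_distance_ts <- function(comparison) {
  c <- .as_comparison(comparison)
  if (c$compared_sites == 0L) {
    stop("distance undefined: no comparable sites", call. = FALSE)
  }
  c$P
}

#' Transitions-only Kimura 2-parameter distance
#'
#' The transitional component of the K2P model,
#' `-1/2 log(1 - 2P - Q) + 1/4 log(1 - 2Q)`, which reduces to
#' `-1/2 log(1 - 2P)` when no transversions are observed.
#'
#' @param comparison A [compare_pair()] result.
#' @return Numeric distance.
#' @export
k2p_ts <- function(comparison) {
  c <- .as_comparison(comparison)
  if (c$compared_sites == 0L) {
    stop("distance undefined: no comparable sites", call. = FALSE)
  }
  a1 <- 1 - 2 * c$P - c$Q
  a2 <- 1 - 2 * c$Q
  if (a1 <= 0 || a2 <= 0) {
    stop("K2P saturation: log argument non-positive (P = ",
         signif(c$P, 4), ", Q = ", signif(c$Q, 4), ")", call. = FALSE)
  }
  -0.5 * log(a1) + 0.25 * log(a2)
}

.distance_fun <- function(model) {
  model <- match.arg(model, c("k2p", "p"))
  if (model == "k2p") k2p_ts else p_distance_ts
}

#' All pairwise transitions-only distances for a labelled sequence set
#'
#' @param data Tibble with columns `id`, `sequence` and a label column.
#' @param model `"k2p"` or `"p"`.
#' @param label Name of the grouping (species/clade) column; pairs sharing
#'   the label are classed `intra`, others `inter`. If the column is absent
#'   every pair is classed `inter`.
#' @return Tibble of all unordered pairs with columns `id_a`, `id_b`,
#'   `label_a`, `label_b`, `class`, `compared_sites`, `ts_diffs`,
#'   `tv_diffs`, `distance`.
#' @export
pairwise_distances <- function(data, model = c("k2p", "p"),
                               label = "species") {
  tbl <- .as_sequence_tbl_lab(data, label)
  fun <- .distance_fun(model)
  n <- nrow(tbl)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  pairs <- utils::combn(n, 2L)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]
    j <- pairs[2L, k]
    cmp <- compare_pair(tbl$sequence[i], tbl$sequence[j])
    tibble::tibble(
      id_a = tbl$id[i], id_b = tbl$id[j],
      label_a = tbl$label[i], label_b = tbl$label[j],
      class = ifelse(!is.na(tbl$label[i]) && !is.na(tbl$label[j]) &&
                       tbl$label[i] == tbl$label[j], "intra", "inter"),
      compared_sites = cmp$compared_sites,
      ts_diffs = cmp$ts_diffs,
      tv_diffs = cmp$tv_diffs,
      distance = fun(cmp)
    )
  })
}

.as_sequence_tbl_lab <- function(data, label) {
  tbl <- .as_sequence_tbl(data)
  if (is.data.frame(data) && label %in% names(data)) {
    tbl$label <- data[[label]]
  } else {
    tbl$label <- NA_character_
  }
  tbl
}

#' Square distance matrix for a sequence set
#'
#' @inheritParams pairwise_distances
#' @return Symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
distance_matrix <- function(data, model = c("k2p", "p")) {
  tbl <- .as_sequence_tbl(data)
  fun <- .distance_fun(model)
  n <- nrow(tbl)
  m <- matrix(0, n, n, dimnames = list(tbl$id, tbl$id))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- fun(compare_pair(tbl$sequence[i], tbl$sequence[j]))
      m[i, j] <- d
      m[j, i] <- d
    }
  }
  m
}

#' Intra/inter-specific distance range summary
#'
#' Computes all unordered pairwise distances and summarises them per species
#' (intra ranges), per species pair (inter ranges) and overall, following
#' the range-matrix presentation conventional in barcoding studies.
#'
#' @inheritParams pairwise_distances
#' @return Object of class `distance_summary`: list with `model`, `pairs`
#'   (the full pair table), `per_label` (per-class range tibble) and
#'   `overall`.
#' @export
distance_summary <- function(data, model = c("k2p", "p"),
                             label = "species") {
  model <- match.arg(model)
  pairs <- pairwise_distances(data, model = model, label = label)
  per_label <- pairs |>
    dplyr::mutate(
      unit = ifelse(.data$class == "intra", .data$label_a,
                    paste(pmin(.data$label_a, .data$label_b),
                          pmax(.data$label_a, .data$label_b), sep = " vs "))
    ) |>
    dplyr::group_by(.data$class, .data$unit) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      min = min(.data$distance), max = max(.data$distance),
      mean = mean(.data$distance), sd = stats::sd(.data$distance),
      .groups = "drop"
    )
  overall <- pairs |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      min = min(.data$distance), max = max(.data$distance),
      mean = mean(.data$distance), sd = stats::sd(.data$distance),
      .groups = "drop"
    )
  structure(
    list(model = model, pairs = pairs, per_label = per_label,
         overall = overall),
    class = "distance_summary"
  )
}

#' @export
print.distance_summary <- function(x, ...) {
  cat("<distance_summary> model:", x$model, "\n")
  print(x$overall)
  invisible(x)
}

#' Barcoding-gap statistic
#'
#' The gap between the maximum intraspecific distance and the minimum
#' interspecific distance. A negative gap (overlapping distributions) is
#' reported as such, never clamped.
#'
#' @param summary A [distance_summary()] result.
#' @return One-row tibble with `upper_intra`, `lower_inter`, `gap_width`.
#' @export
barcoding_gap <- function(summary) {
  stopifnot(inherits(summary, "distance_summary"))
  ov <- summary$overall
  if (!all(c("intra", "inter") %in% ov$class)) {
    stop("barcoding gap undefined: need at least one intra- and one ",
         "inter-class pair", call. = FALSE)
  }
  upper_intra <- ov$max[ov$class == "intra"]
  lower_inter <- ov$min[ov$class == "inter"]
  tibble::tibble(
    upper_intra = upper_intra,
    lower_inter = lower_inter,
    gap_width = lower_inter - upper_intra
  )
}

#' Nucleotide diversity (pi)
#'
#' Average proportion of differing sites over all unordered sequence pairs,
#' counting all substitution types (the DnaSP convention, unlike the
#' transitions-only distances).
#'
#' @param data Tibble with `id`, `sequence`, or a character vector of
#'   aligned sequences.
#' @return One-row tibble with `pi`, `n_sequences`, `n_segregating_sites`.
#' @export
nucleotide_diversity <- function(data) {
  tbl <- .as_sequence_tbl(data)
  n <- nrow(tbl)
  if (n < 2L) stop("nucleotide diversity needs at least 2 sequences",
                   call. = FALSE)
  pairs <- utils::combn(n, 2L)
  props <- vapply(seq_len(ncol(pairs)), function(k) {
    cmp <- compare_pair(tbl$sequence[pairs[1L, k]],
                        tbl$sequence[pairs[2L, k]])
    if (cmp$compared_sites == 0L) {
      stop("no comparable sites between '", tbl$id[pairs[1L, k]], "' and '",
           tbl$id[pairs[2L, k]], "'", call. = FALSE)
    }
    (cmp$ts_diffs + cmp$tv_diffs) / cmp$compared_sites
  }, numeric(1))
  mat <- do.call(rbind, strsplit(toupper(tbl$sequence), ""))
  seg <- sum(apply(mat, 2L, function(col) {
    col <- col[col %in% c("A", "C", "G", "T")]
    length(unique(col)) > 1L
  }))
  tibble::tibble(
    pi = mean(props),
    n_sequences = n,
    n_segregating_sites = seg
  )
}
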