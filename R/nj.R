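# Neighbour-joining trees, monophyly checks and site-resampling bootstrap.

#' Neighbour-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (via \pkg{ape}); output is deterministic given
#' the input row order. Input is validated: square, symmetric, zero
#' diagonal, at least three taxa.
#'
#' @param d Symmetric numeric matrix (or `dist`) of pairwise distances.
#' @param labels Optional taxon labels overriding the matrix dimnames.
#' @return An object of class `phylo`.
#' @export
nj_tree <- function(d, labels = NULL) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop("distance input must be a square matrix or dist", call. = FALSE)
  }
  if (nrow(d) < 3L) stop("NJ needs at least 3 taxa", call. = FALSE)
  if (any(abs(diag(d)) > 1e-12)) {
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  }
  if (any(abs(d - t(d)) > 1e-9)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(d))
    dimnames(d) <- list(labels, labels)
  }
  if (is.null(rownames(d))) {
    dimnames(d) <- list(paste0("t", seq_len(nrow(d))),
                        paste0("t", seq_len(nrow(d))))
  }
  ape::nj(stats::as.dist(d))
}

#' Test monophyly of label groups on an (unrooted) tree
#'
#' A label is monophyletic when some edge bipartition isolates exactly its
#' leaves (either side of the split); singleton labels and a label covering
#' all leaves are trivially monophyletic.
#'
#' @param tree A `phylo` object.
#' @param labels Named character vector mapping every tip label to a group
#'   label, or a data frame with columns `id` and `label`.
#' @return Tibble with columns `label` and `monophyletic`.
#' @export
check_monophyly <- function(tree, labels) {
  stopifnot(inherits(tree, "phylo"))
  if (is.data.frame(labels)) {
    labels <- stats::setNames(labels$label, labels$id)
  }
  tips <- tree$tip.label
  if (!all(tips %in% names(labels))) {
    missing <- setdiff(tips, names(labels))
    stop("unlabeled leaves: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lab <- labels[tips]
  n <- length(tips)
  parts <- ape::prop.part(tree)
  sides <- lapply(parts, function(p) sort(as.integer(p)))
  purrr::map_dfr(unique(unname(lab)), function(g) {
    leafset <- sort(unname(which(lab == g)))
    mono <- length(leafset) %in% c(1L, n) ||
      any(vapply(sides, function(s) {
        identical(s, leafset) ||
          identical(sort(setdiff(seq_len(n), s)), leafset)
      }, logical(1)))
    tibble::tibble(label = g, monophyletic = mono)
  })
}

#' Site-resampling bootstrap support for an NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate and counts how often each original bipartition recurs.
#'
#' @param data Tibble with `id`, `sequence` (aligned, equal length).
#' @param n_replicates Number of bootstrap replicates.
#' @param model Distance model passed to [distance_matrix()]; the p model
#'   is the default because resampled columns can saturate the K2P
#'   transform.
#' @param seed Optional integer seed for reproducibility.
#' @return List with `tree` (the NJ tree on the full alignment) and
#'   `support` (integer vector of per-node bootstrap counts).
#' @export
nj_bootstrap <- function(data, n_replicates = 100L, model = "p",
                         seed = NULL) {
  tbl <- .as_sequence_tbl(data)
  if (!is.null(seed)) set.seed(seed)
  mat <- do.call(rbind, strsplit(toupper(tbl$sequence), ""))
  rownames(mat) <- tbl$id
  build <- function(m) {
    seqs <- apply(m, 1L, paste, collapse = "")
    nj_tree(distance_matrix(tibble::tibble(id = rownames(m),
                                           sequence = seqs),
                            model = model))
  }
  tree <- build(mat)
  support <- ape::boot.phylo(tree, mat, build, B = n_replicates,
                             quiet = TRUE)
  list(tree = tree, support = support)
}
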