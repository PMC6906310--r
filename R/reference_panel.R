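# Reconstructed 116 bp cytochrome b haplotype panel for the four elephantid
# species groups, with coordinate helpers and panel export.

RCRS_FIRST <- 15124L  # first insert base (rCRS, 1-based)
RCRS_LAST  <- 15239L  # last insert base
INSERT_LEN <- 116L

TAXON_EMAX <- "E. maximus"
TAXON_S    <- "L. africana (S clade)"
TAXON_F    <- "Loxodonta F clade"
TAXON_MAM  <- "M. primigenius"
TAXON_NONE <- "unassigned"

#' Convert an rCRS coordinate to a 0-based insert offset
#'
#' The 116 bp target fragment spans rCRS positions 15124-15239 (the region
#' between the primer sites at 15123 and 15240 of the human mitochondrial
#' reference, which anchors the coordinate system).
#'
#' @param pos Integer vector of rCRS coordinates.
#' @return Integer vector of 0-based offsets within the insert.
#' @examples
#' rcrs_to_fragment_index(15124)  # 0
#' rcrs_to_fragment_index(15239)  # 115
#' @export
rcrs_to_fragment_index <- function(pos) {
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < RCRS_FIRST | pos > RCRS_LAST)) {
    stop("rCRS position out of range: insert positions lie in [",
         RCRS_FIRST, ", ", RCRS_LAST, "]", call. = FALSE)
  }
  pos - RCRS_FIRST
}

#' Convert a 0-based insert offset back to an rCRS coordinate
#'
#' @param idx Integer vector of 0-based offsets (0-115).
#' @return Integer vector of rCRS coordinates.
#' @export
fragment_index_to_rcrs <- function(idx) {
  idx <- as.integer(idx)
  if (any(is.na(idx)) || any(idx < 0L | idx > INSERT_LEN - 1L)) {
    stop("fragment index out of range: valid offsets lie in [0, ",
         INSERT_LEN - 1L, "]", call. = FALSE)
  }
  idx + RCRS_FIRST
}

#' Variant states of the 14 polymorphic positions of the 116 bp fragment
#'
#' One row per polymorphic rCRS position and species group; `states` holds
#' the observed base(s), slash-separated where a group is polymorphic at the
#' site (within-group alternatives are unphased).
#'
#' @return A tibble with columns `group`, `species`, `clade`, `taxon`,
#'   `rcrs`, `states`.
#' @export
cytb_variant_states <- function() {
  groups <- .panel_groups()
  pos <- c(15124L, 15148L, 15151L, 15160L, 15184L, 15190L, 15193L,
           15205L, 15208L, 15210L, 15211L, 15221L, 15222L, 15238L)
  states <- list(
    `L. cyclotis (F)` = c("T/C", "G", "G/A", "A/G", "C", "C", "C", "T", "C", "A", "C", "A", "G/A", "C"),
    `L. africana (F)` = c("C", "G", "A/G", "A/G", "C", "C", "C", "T", "C", "A", "C", "A", "A/G", "C"),
    `L. africana (S)` = c("C", "G", "A", "A", "C", "C", "T", "C", "T", "A/G", "T", "A", "A", "C"),
    `M. primigenius`  = c("C", "G", "A", "A", "C", "C/T", "C", "T", "C", "A", "C", "G", "A", "C"),
    `E. maximus`      = c("C", "A", "A", "A", "T", "C", "C", "T", "C", "A", "C", "A", "A", "T")
  )
  purrr::map_dfr(groups$group, function(g) {
    tibble::tibble(
      group = g,
      species = groups$species[groups$group == g],
      clade = groups$clade[groups$group == g],
      taxon = groups$taxon[groups$group == g],
      rcrs = pos,
      states = states[[g]]
    )
  })
}

.panel_groups <- function() {
  tibble::tibble(
    group = c("L. cyclotis (F)", "L. africana (F)", "L. africana (S)",
              "M. primigenius", "E. maximus"),
    species = c("L. cyclotis", "L. africana", "L. africana",
                "M. primigenius", "E. maximus"),
    clade = c("F", "F", "S", NA, NA),
    taxon = c(TAXON_F, TAXON_F, TAXON_S, TAXON_MAM, TAXON_EMAX)
  )
}

.split_states <- function(s) strsplit(s, "/", fixed = TRUE)

#' Build the reference haplotype panel
#'
#' Reconstructs every haplotype implied by the variant table
#' ([cytb_variant_states()]) through Cartesian expansion of the unphased
#' within-group alternatives, over a shared constant background. Sites whose
#' fixed state in some group is absent from every other group are classified
#' interspecific; the subset unique to the S-clade savanna lineage is
#' additionally flagged. One background position (by default rCRS 15125) is
#' set to `N` so that pairwise comparisons use the 115-site denominator of
#' the deposited alignment; pass `exclude_site = NULL` for a raw 116-site
#' panel.
#'
#' @param exclude_site rCRS coordinate of the background position marked as
#'   excluded-from-comparison (`N`), or `NULL` for none. Must not be one of
#'   the 14 variant positions.
#' @param background Single base used at all non-variant positions.
#' @return An object of class `reference_panel`: a list with tibbles
#'   `haplotypes`, `sites`, `diagnostics`, `primer_regions`, `primers`, and
#'   scalars `background`, `exclude_site`.
#' @examples
#' panel <- build_reference_panel()
#' interspecific_sites(panel)
#' @export
build_reference_panel <- function(exclude_site = 15125L, background = "C") {
  background <- toupper(background)
  stopifnot(background %in% c("A", "C", "G", "T"))
  variants <- cytb_variant_states()
  var_pos <- sort(unique(variants$rcrs))
  if (!is.null(exclude_site)) {
    exclude_site <- as.integer(exclude_site)
    if (exclude_site %in% var_pos) {
      stop("exclude_site must be a background (non-variant) position",
           call. = FALSE)
    }
    rcrs_to_fragment_index(exclude_site)  # range check
  }

  sites <- .classify_sites(variants)
  haps <- .expand_haplotypes(variants, background, exclude_site)
  .check_panel_integrity(haps)

  structure(
    list(
      haplotypes = haps,
      sites = sites,
      diagnostics = .diagnostic_states(sites),
      primer_regions = primer_region_panel(),
      primers = elephantid_primers(),
      background = background,
      exclude_site = exclude_site
    ),
    class = "reference_panel"
  )
}

# A site is interspecific when at least one group carries a fixed state that
# no other group ever shows; the S-clade-specific subset is the sites whose
# S-clade fixed state is private to that lineage.
.classify_sites <- function(variants) {
  per_site <- split(variants, variants$rcrs)
  rows <- purrr::map_dfr(per_site, function(v) {
    st <- .split_states(v$states)
    names(st) <- v$group
    inter <- FALSE
    for (g in seq_along(st)) {
      others <- unique(unlist(st[-g]))
      if (length(st[[g]]) == 1L && !st[[g]] %in% others) inter <- TRUE
    }
    s <- st[["L. africana (S)"]]
    others <- unique(unlist(st[names(st) != "L. africana (S)"]))
    s_specific <- inter && length(s) == 1L && !s %in% others
    tibble::tibble(
      rcrs = v$rcrs[1L],
      fragment_index = rcrs_to_fragment_index(v$rcrs[1L]),
      interspecific = inter,
      s_clade_specific = s_specific
    )
  })
  dplyr::arrange(rows, .data$rcrs)
}

# Per-taxon diagnostic states at the interspecific sites: the fixed states
# private to E. maximus, the S clade and M. primigenius, plus the full
# F-clade background over all interspecific sites.
.diagnostic_states <- function(sites) {
  variants <- cytb_variant_states()
  inter <- sites$rcrs[sites$interspecific]
  v <- variants[variants$rcrs %in% inter, ]
  per_site <- split(v, v$rcrs)
  out <- purrr::map_dfr(per_site, function(x) {
    st <- .split_states(x$states)
    names(st) <- x$group
    rows <- list()
    for (g in names(st)) {
      others <- unique(unlist(st[names(st) != g]))
      if (length(st[[g]]) == 1L && !st[[g]] %in% others) {
        rows[[g]] <- tibble::tibble(
          taxon = x$taxon[x$group == g],
          rcrs = x$rcrs[1L],
          state = st[[g]]
        )
      }
    }
    dplyr::bind_rows(rows)
  })
  out <- dplyr::distinct(out)
  f_bg <- v[v$group == "L. cyclotis (F)", ]
  f_rows <- tibble::tibble(
    taxon = TAXON_F,
    rcrs = f_bg$rcrs,
    state = vapply(.split_states(f_bg$states), `[`, character(1), 1L)
  )
  dplyr::arrange(dplyr::bind_rows(out[out$taxon != TAXON_F, ], f_rows),
                 .data$taxon, .data$rcrs)
}

.expand_haplotypes <- function(variants, background, exclude_site) {
  groups <- .panel_groups()
  prefix <- c(`L. cyclotis (F)` = "LCF", `L. africana (F)` = "LAF",
              `L. africana (S)` = "LAS", `M. primigenius` = "MPR",
              `E. maximus` = "EMA")
  base <- rep(background, INSERT_LEN)
  if (!is.null(exclude_site)) {
    base[rcrs_to_fragment_index(exclude_site) + 1L] <- "N"
  }
  purrr::map_dfr(groups$group, function(g) {
    v <- variants[variants$group == g, ]
    combos <- expand.grid(.split_states(v$states), stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
    names(combos) <- as.character(v$rcrs)
    seqs <- vapply(seq_len(nrow(combos)), function(i) {
      ch <- base
      ch[rcrs_to_fragment_index(v$rcrs) + 1L] <-
        as.character(unlist(combos[i, ]))
      .chars_seq(ch)
    }, character(1))
    meta <- groups[groups$group == g, ]
    tibble::tibble(
      haplotype_id = sprintf("%s_%02d", prefix[[g]], seq_along(seqs)),
      species = meta$species,
      clade = meta$clade,
      group = g,
      taxon = meta$taxon,
      sequence = seqs
    )
  })
}

# Identical haplotypes are expected between the two F-clade groups (one
# shared matrilineal lineage); the same sequence appearing under two
# different assignment taxa would make classification ill-posed.
.check_panel_integrity <- function(haps) {
  dup <- haps |>
    dplyr::distinct(.data$sequence, .data$taxon) |>
    dplyr::count(.data$sequence) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    stop("panel integrity error: identical haplotype present in more than ",
         "one assignment group", call. = FALSE)
  }
  invisible(haps)
}

#' Interspecific variable positions of the panel
#' @param panel A `reference_panel`.
#' @return Integer vector of rCRS coordinates.
#' @export
interspecific_sites <- function(panel) {
  stopifnot(inherits(panel, "reference_panel"))
  panel$sites$rcrs[panel$sites$interspecific]
}

#' S-clade-specific diagnostic positions of the panel
#' @param panel A `reference_panel`.
#' @return Integer vector of rCRS coordinates.
#' @export
s_clade_sites <- function(panel) {
  stopifnot(inherits(panel, "reference_panel"))
  panel$sites$rcrs[panel$sites$s_clade_specific]
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("<reference_panel>\n")
  cat("  haplotypes:", nrow(x$haplotypes), "across",
      length(unique(x$haplotypes$group)), "species groups\n")
  cat("  interspecific sites:", length(interspecific_sites(x)),
      "(S-clade specific:", length(s_clade_sites(x)), ")\n")
  cat("  compared sites per pair:",
      if (is.null(x$exclude_site)) INSERT_LEN else INSERT_LEN - 1L, "\n")
  invisible(x)
}

#' Full-length (160 bp) templates for the panel haplotypes
#'
#' Embeds each 116 bp haplotype between concrete primer-region flanks: the
#' forward flank is the species' resolved forward primer region and the
#' 3' flank is the reverse complement of its resolved reverse primer region,
#' so the plus strand reads forward-region, insert, reverse-binding site.
#'
#' @param panel A `reference_panel`.
#' @return Tibble with columns `id`, `species`, `group`, `taxon`,
#'   `sequence` (160 nt).
#' @export
panel_templates <- function(panel) {
  stopifnot(inherits(panel, "reference_panel"))
  regions <- panel$primer_regions
  haps <- panel$haplotypes
  fwd <- regions$forward_region[match(haps$species, regions$species)]
  rev <- regions$reverse_region[match(haps$species, regions$species)]
  tibble::tibble(
    id = haps$haplotype_id,
    species = haps$species,
    group = haps$group,
    taxon = haps$taxon,
    sequence = paste0(fwd, haps$sequence,
                      vapply(rev, reverse_complement, character(1)))
  )
}

#' Full-length template for a non-target (non-elephantid) species
#'
#' Builds a synthetic plus-strand template from the species' primer-region
#' rows with a constant spacer standing in for its (unmodelled) internal
#' sequence; only the primer regions matter for amplification prediction.
#'
#' @param panel A `reference_panel`.
#' @param species Species name as in [primer_region_panel()] (e.g.
#'   `"H. sapiens"`).
#' @param spacer_length Length of the internal spacer.
#' @return Character scalar template sequence.
#' @export
nontarget_template <- function(panel, species, spacer_length = INSERT_LEN) {
  stopifnot(inherits(panel, "reference_panel"))
  regions <- panel$primer_regions
  row <- regions[regions$species == species, ]
  if (nrow(row) != 1L) {
    stop("unknown species '", species, "'; available: ",
         paste(regions$species, collapse = ", "), call. = FALSE)
  }
  paste0(row$forward_region,
         strrep(panel$background, spacer_length),
         reverse_complement(row$reverse_region))
}

#' Export the panel haplotypes as TSV
#'
#' Writes one row per haplotype with columns `species`, `clade`,
#' `haplotype_id`, then one column per polymorphic rCRS position.
#'
#' @param panel A `reference_panel`.
#' @param path Output path.
#' @return The exported tibble, invisibly.
#' @export
panel_export <- function(panel, path) {
  stopifnot(inherits(panel, "reference_panel"))
  haps <- panel$haplotypes
  pos <- panel$sites$rcrs
  states <- purrr::map_dfc(stats::setNames(pos, pos), function(p) {
    substr(haps$sequence, rcrs_to_fragment_index(p) + 1L,
           rcrs_to_fragment_index(p) + 1L)
  })
  out <- dplyr::bind_cols(
    haps[, c("species", "clade", "haplotype_id")], states
  )
  readr::write_tsv(out, path)
  invisible(out)
}
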