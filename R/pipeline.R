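# End-to-end identification pipeline and panel self-validation.

#' Identify elephantid fragments in a set of templates
#'
#' Full workflow for each input record: in-silico PCR with the
#' elephantid-universal primers, primer trimming, then combined
#' diagnostic + distance classification of the 116 bp insert.
#' Records that fail amplification are reported as
#' `"no elephantid amplicon"`, mirroring the assay's exclusion of
#' non-target species.
#'
#' @param input Templates: tibble with `id`/`sequence`, named character
#'   vector, or FASTA path.
#' @param panel A `reference_panel`.
#' @param policy An [amplification_policy()].
#' @param threshold Distance-assignment threshold.
#' @param model Distance model, `"k2p"` or `"p"`.
#' @param report_tsv,report_json Optional output paths.
#' @param seed Optional integer recorded in the JSON report (the pipeline
#'   itself is deterministic).
#' @return Tibble combining the PCR report and the species calls, one row
#'   per input record (order preserving).
#' @export
run_identify <- function(input, panel = build_reference_panel(),
                         policy = amplification_policy(),
                         threshold = 0.0135, model = "k2p",
                         report_tsv = NULL, report_json = NULL,
                         seed = NULL) {
  tbl <- .as_sequence_tbl(input)
  pcr <- run_insilico_pcr(tbl, primers = panel$primers, policy = policy)
  calls <- purrr::map_dfr(seq_len(nrow(pcr)), function(i) {
    if (!isTRUE(pcr$amplified[i])) {
      return(tibble::tibble(
        id = pcr$template_id[i], taxon = "no elephantid amplicon",
        clade = NA_character_, method = NA_character_,
        diagnostic_taxon = NA_character_, distance_taxon = NA_character_,
        min_distance = NA_real_, nearest_reference = NA_character_,
        diagnostic_states = NA_character_, conflicts = NA_character_
      ))
    }
    classify(tibble::tibble(id = pcr$template_id[i],
                            sequence = pcr$insert[i]),
             panel, threshold = threshold, model = model)
  })
  out <- dplyr::bind_cols(
    calls,
    pcr[, c("amplified", "strand", "fwd_mm", "fwd_3p_mm", "rev_mm",
            "rev_3p_mm", "amplicon_len", "insert_len")]
  )
  if (!is.null(report_tsv)) readr::write_tsv(out, report_tsv)
  if (!is.null(report_json)) {
    jsonlite::write_json(
      list(
        schema_version = "1.0",
        tool = paste0("ivoryid ",
                      as.character(utils::packageVersion("ivoryid"))),
        seed = seed,
        config = list(threshold = threshold, model = model,
                      max_mismatches = policy$max_mismatches,
                      max_three_prime = policy$max_three_prime),
        calls = out
      ),
      report_json, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  out
}

#' Validate the reference panel against its design expectations
#'
#' Recomputes, from the panel fixtures alone, the quantities the panel is
#' built to encode -- interspecific and S-clade site counts, intraspecific
#' variation per group, primer-region mismatch totals for the specificity
#' species, amplicon/insert lengths of every reconstructed template, and
#' the extreme interspecific distances -- and compares each against its
#' expected value.
#'
#' @param panel A `reference_panel`.
#' @return Tibble with columns `check`, `expected`, `computed`, `pass`;
#'   attribute `all_pass` summarises the run.
#' @export
validate_panel <- function(panel = build_reference_panel()) {
  rows <- list()
  add <- function(check, expected, computed) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      check = check,
      expected = as.character(expected),
      computed = as.character(computed),
      pass = isTRUE(all.equal(expected, computed, tolerance = 1e-9)) ||
        identical(as.character(expected), as.character(computed))
    )
  }

  add("interspecific sites", 8L, length(interspecific_sites(panel)))
  add("S-clade-specific sites", 4L, length(s_clade_sites(panel)))

  variants <- cytb_variant_states()
  intra_count <- function(group) {
    v <- variants[variants$group == group, ]
    sum(lengths(.split_states(v$states)) > 1L)
  }
  add("intraspecific variable positions, E. maximus", 0L,
      intra_count("E. maximus"))
  add("intraspecific variable positions, M. primigenius", 1L,
      intra_count("M. primigenius"))
  add("intraspecific variable positions, L. africana S clade", 1L,
      intra_count("L. africana (S)"))
  add("intraspecific variable positions, L. africana F clade", 3L,
      intra_count("L. africana (F)"))
  add("intraspecific variable positions, L. cyclotis", 4L,
      intra_count("L. cyclotis (F)"))

  mm <- tabulate_primer_mismatches(panel)
  total_of <- function(sp) mm$total[mm$species == sp]
  add("primer mismatches, H. amphibius", 6L, total_of("H. amphibius"))
  add("primer mismatches, C. simum", 9L, total_of("C. simum"))
  add("primer mismatches, H. sapiens", 11L, total_of("H. sapiens"))
  add("primer mismatches, B. taurus", 12L, total_of("B. taurus"))
  add("primer mismatches, all elephantids", 0L,
      sum(mm$total[mm$elephantid]))

  pcr <- run_insilico_pcr(panel_templates(panel),
                          primers = panel$primers)
  add("all panel templates amplify", TRUE, all(pcr$amplified))
  add("amplicon length", 160L, unique(pcr$amplicon_len))
  add("insert length", 116L, unique(pcr$insert_len))

  haps <- panel$haplotypes
  seq_tbl <- tibble::tibble(id = haps$haplotype_id, species = haps$group,
                            sequence = haps$sequence)
  # the printed overall distance maxima arise from the Asian elephant vs
  # S-clade savanna comparison (8 transitions over 115 compared sites)
  max_p <- emax_s_clade_max(panel, model = "p")
  max_k <- emax_s_clade_max(panel, model = "k2p")
  add("max E. maximus vs S clade p-distance (%)", 6.96,
      round(100 * max_p, 2))
  add("max E. maximus vs S clade K2P distance (%)", 7.49,
      round(100 * max_k, 2))

  out <- dplyr::bind_rows(rows)
  attr(out, "all_pass") <- all(out$pass)
  out
}

#' Maximum distance between the Asian elephant and S-clade haplotypes
#'
#' The most divergent comparison in the reconstructed panel that the
#' reported overall distance maxima correspond to: the Asian elephant
#' haplotype against the S-clade savanna haplotype carrying G at rCRS
#' 15210 differs by 8 transitions over the 115 compared sites.
#'
#' @param panel A `reference_panel`.
#' @param model `"k2p"` or `"p"`.
#' @return Numeric distance (proportion, not percent).
#' @export
emax_s_clade_max <- function(panel = build_reference_panel(),
                             model = "k2p") {
  haps <- panel$haplotypes
  seq_tbl <- tibble::tibble(
    id = haps$haplotype_id,
    species = haps$group,
    sequence = haps$sequence
  )
  s <- distance_summary(seq_tbl, model = model)
  unit <- paste(pmin("E. maximus", "L. africana (S)"),
                pmax("E. maximus", "L. africana (S)"), sep = " vs ")
  s$per_label$max[s$per_label$class == "inter" & s$per_label$unit == unit]
}
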