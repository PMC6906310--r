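# Ancient-DNA deamination simulator, contamination mixtures and
# copy-number arithmetic for sensitivity-style experiments.

#' Cytosine-deamination damage model
#'
#' Post-mortem cytosine deamination reads out as C->T substitutions (and
#' G->A for lesions on the complementary strand). It concentrates on the
#' outermost ~10 bases of a degraded template but occurs at a low rate
#' across its whole length, which the model captures with a terminal window
#' rate and an interior rate. The default rates (0.05 terminal, 0.005
#' interior) are simulation choices for exercising the assay on plausibly
#' degraded templates, not measured quantities. Uracil-N-glycosylase (UNG)
#' treatment, which repairs deaminated cytosines, is modelled as a
#' multiplicative 1000-fold rate reduction.
#'
#' @param terminal_rate Per-site C->T / G->A probability within the
#'   terminal windows.
#' @param interior_rate Per-site probability elsewhere.
#' @param terminal_window Number of bases at each end forming the terminal
#'   window.
#' @param ung If `TRUE`, both rates are multiplied by 0.001.
#' @return Object of class `damage_model`.
#' @export
damage_model <- function(terminal_rate = 0.05, interior_rate = 0.005,
                         terminal_window = 10L, ung = FALSE) {
  stopifnot(terminal_rate >= 0, terminal_rate <= 1,
            interior_rate >= 0, interior_rate <= 1,
            terminal_window >= 0)
  f <- if (isTRUE(ung)) 0.001 else 1
  structure(
    list(terminal_rate = terminal_rate * f,
         interior_rate = interior_rate * f,
         terminal_window = as.integer(terminal_window),
         ung = isTRUE(ung)),
    class = "damage_model"
  )
}

#' Apply deamination damage to a sequence
#'
#' Independently per site, a C becomes T (and a G becomes A, the
#' complementary-strand lesion mapped onto the represented strand) with the
#' window-appropriate rate. No other substitution is ever introduced; A, T
#' and ambiguity characters are untouched. Uses the current RNG state, so
#' wrap in `set.seed()` for reproducibility.
#'
#' @param seq Sequence to damage.
#' @param model A [damage_model()].
#' @return List with `sequence` (damaged) and `events` (tibble with
#'   `position`, `from`, `to`).
#' @export
apply_deamination <- function(seq, model = damage_model()) {
  stopifnot(inherits(model, "damage_model"))
  ch <- .seq_chars(seq)
  n <- length(ch)
  w <- min(model$terminal_window, n)
  rate <- rep(model$interior_rate, n)
  if (w > 0L) {
    rate[seq_len(w)] <- model$terminal_rate
    rate[seq.int(n - w + 1L, n)] <- model$terminal_rate
  }
  damageable <- ch %in% c("C", "G")
  hit <- damageable & stats::runif(n) < rate
  from <- ch[hit]
  to <- ifelse(from == "C", "T", "A")
  ch[hit] <- to
  list(
    sequence = .chars_seq(ch),
    events = tibble::tibble(position = which(hit), from = from, to = to)
  )
}

#' Simulate damaged (and contaminated) template sets
#'
#' Draws `n_elephantid` full-length templates uniformly from the panel
#' haplotypes (each embedded between its species' concrete primer-region
#' flanks), applies the damage model to each, and appends undamaged
#' contaminant templates built from the non-target primer-region rows
#' (contaminants stand for modern DNA -- human handling, cattle substrate
#' -- and are therefore not degraded).
#'
#' @param panel A `reference_panel`.
#' @param n Total number of records to emit.
#' @param model A [damage_model()].
#' @param contamination Named numeric vector of per-species contaminant
#'   fractions (e.g. `c("H. sapiens" = 0.5)`); fractions must sum to at
#'   most 1 and names must be non-target species of the panel.
#' @param seed Optional integer seed.
#' @param fasta,truth Optional output paths for a FASTA of the simulated
#'   templates and a tab-separated truth table.
#' @return Tibble with columns `id`, `truth_label`, `species`, `group`,
#'   `n_damage_events`, `sequence`.
#' @export
simulate_samples <- function(panel, n, model = damage_model(),
                             contamination = NULL, seed = NULL,
                             fasta = NULL, truth = NULL) {
  stopifnot(inherits(panel, "reference_panel"), n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  regions <- panel$primer_regions
  if (!is.null(contamination) && length(contamination) > 0L) {
    stopifnot(is.numeric(contamination), !is.null(names(contamination)))
    unknown <- setdiff(names(contamination),
                       regions$species[!regions$elephantid])
    if (length(unknown) > 0L) {
      stop("unknown contaminant species: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (sum(contamination) > 1 + 1e-9) {
      stop("contaminant fractions must sum to at most 1", call. = FALSE)
    }
  }
  n_contam <- if (is.null(contamination)) integer(0)
              else stats::setNames(round(contamination * n),
                                   names(contamination))
  n_eleph <- n - sum(n_contam)
  if (n_eleph < 0L) stop("contaminant fractions leave no elephantid records",
                         call. = FALSE)

  templates <- panel_templates(panel)
  rows <- list()
  if (n_eleph > 0L) {
    pick <- sample.int(nrow(templates), n_eleph, replace = TRUE)
    damaged <- lapply(templates$sequence[pick], apply_deamination,
                      model = model)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      truth_label = templates$taxon[pick],
      species = templates$species[pick],
      group = templates$group[pick],
      n_damage_events = vapply(damaged, function(d) nrow(d$events),
                               integer(1)),
      sequence = vapply(damaged, `[[`, character(1), "sequence")
    )
  }
  for (sp in names(n_contam)) {
    k <- n_contam[[sp]]
    if (k == 0L) next
    tmpl <- nontarget_template(panel, sp)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      truth_label = sp, species = sp, group = sp,
      n_damage_events = 0L,
      sequence = rep(tmpl, k)
    )
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::bind_cols(
    tibble::tibble(id = sprintf("sim_%04d", seq_len(nrow(out)))), out
  )
  if (!is.null(fasta)) write_fasta(out, fasta)
  if (!is.null(truth)) {
    readr::write_tsv(out[, c("id", "truth_label", "species",
                             "n_damage_events")], truth)
  }
  out
}

AVOGADRO <- 6.02214076e23

#' Template copy number from a DNA mass
#'
#' Standard plasmid-standard arithmetic:
#' copies = mass(g) * N_A / (length * M_bp), with M_bp = 660 g/mol/bp for
#' double-stranded DNA and 330 g/mol/nt for single-stranded.
#'
#' @param mass_ng DNA mass in nanograms.
#' @param length_bp Molecule length in base pairs (or nucleotides if
#'   single-stranded).
#' @param double_stranded Logical.
#' @return Numeric copy number (expectation, real-valued).
#' @examples
#' copies_from_mass(1, 1000)  # ~9.1e8
#' @export
copies_from_mass <- function(mass_ng, length_bp, double_stranded = TRUE) {
  if (any(mass_ng <= 0) || any(length_bp <= 0)) {
    stop("mass and length must be positive", call. = FALSE)
  }
  per_bp <- if (double_stranded) 660 else 330
  (mass_ng * 1e-9) * AVOGADRO / (length_bp * per_bp)
}

#' Geometric serial-dilution series
#'
#' @param start_copies Copy number of the starting stock.
#' @param factor Dilution factor per step (> 1).
#' @param steps Number of dilution steps.
#' @return Numeric vector of length `steps + 1` (stock first). Values are
#'   expectations and stay real-valued; they are never floored to zero.
#' @examples
#' serial_dilution(1e4, 10, 4)
#' @export
serial_dilution <- function(start_copies, factor = 10, steps = 1L) {
  stopifnot(factor > 1, steps >= 1)
  start_copies / factor^(0:steps)
}
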