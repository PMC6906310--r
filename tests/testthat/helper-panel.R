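# shared fixtures built once per test run
the_panel <- build_reference_panel()
the_templates <- panel_templates(the_panel)

panel_seq_tbl <- function(panel = the_panel) {
  haps <- panel$haplotypes
  tibble::tibble(id = haps$haplotype_id, species = haps$group,
                 sequence = haps$sequence)
}

# pull one haplotype sequence by group, with given states at given rCRS
# positions (first matching haplotype)
hap_with_states <- function(panel, group, states = NULL) {
  haps <- panel$haplotypes[panel$haplotypes$group == group, ]
  if (is.null(states)) return(haps$sequence[1L])
  for (s in haps$sequence) {
    ok <- all(vapply(names(states), function(p) {
      i <- rcrs_to_fragment_index(as.integer(p)) + 1L
      substr(s, i, i) == states[[p]]
    }, logical(1)))
    if (ok) return(s)
  }
  stop("no haplotype in ", group, " with requested states")
}

set_rcrs <- function(seq, pos, base) {
  i <- rcrs_to_fragment_index(pos) + 1L
  substr(seq, i, i) <- base
  seq
}
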