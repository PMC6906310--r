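---
title: "Identifying elephantid ivory from a 116 bp cytochrome b fragment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying elephantid ivory from a 116 bp cytochrome b fragment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivoryid)
```

## The problem

Trade in ivory from the extant elephants — Asian elephant (*Elephas
maximus*), African savanna elephant (*Loxodonta africana*) and African
forest elephant (*Loxodonta cyclotis*) — is regulated, while ivory from the
extinct woolly mammoth (*Mammuthus primigenius*) is not. Telling them apart
on worked ivory is a forensic problem: the morphological cue (Schreger-line
angles) is often absent on carved pieces, and DNA recovered from fossil
ivory is too fragmented for the 180+ bp amplicons of earlier molecular
assays. A short mitochondrial marker solves both issues: a 116 bp internal
fragment of the cytochrome *b* gene, amplified by a degenerate primer pair
(L15123/H15240, 160 bp amplicon with primers included) that binds all
elephantid lineages with zero mismatches while carrying 6–12 differential
nucleotides against ivory-substitute species and human DNA.

`ivoryid` is an in-silico re-implementation of that assay: it reconstructs
the reference haplotype panel, simulates the PCR (including its failure on
non-target species and on damaged primer sites), computes the
transitions-only distance framework that underpins distance-based
assignment, classifies fragments by diagnostic nucleotides and by distance,
and provides an ancient-DNA deamination simulator to exercise the whole
pipeline on degraded templates.

## The reference panel

Coordinates follow the revised Cambridge Reference Sequence (rCRS) for the
human mitochondrial genome; the insert spans rCRS 15124–15239 and all
user-facing output uses rCRS positions, never 0-based offsets.

The panel encodes the 14 polymorphic positions of the fragment as observed
across the four elephantid species groups (`cytb_variant_states()`). Eight
positions carry fixed interspecific differences — every one of them a
transition — and four of those are private to the S-clade savanna lineage:

```{r}
panel <- build_reference_panel()
glance(panel)
interspecific_sites(panel)
s_clade_sites(panel)
```

Three reconstruction choices matter:

* **Constant background.** All non-variant positions are set to a single
  base (`C`). Distances, diagnostics and amplicon arithmetic depend only on
  the variant sites being correct and the background being shared; the true
  background would require the deposited GenBank accessions, which the
  panel deliberately does not fetch.
* **The 115-site denominator.** The printed distance extremes are
  reproduced exactly by transition counts over 115 (not 116) compared
  sites, so the source alignment evidently contained one non-comparable
  column. The panel marks one background position (rCRS 15125) with `N`;
  pairwise deletion then yields 115 compared sites per pair. Whether the
  real cause was one excluded column or a 115 bp effective fragment is not
  decidable from the published tables; `build_reference_panel(exclude_site
  = NULL)` gives the raw 116-site behaviour.
* **Cartesian expansion.** Within-group polymorphisms are reported per site
  without phase, so the panel expands every combination (29 haplotypes:
  16 forest-elephant, 8 savanna F-clade, 2 S-clade, 2 mammoth, 1 Asian
  elephant). Expansion guarantees the extreme pairs the reported distance
  ranges require, and classification is unaffected because assignment is
  driven by the fixed diagnostic states. It does, however, over-generate
  combinations relative to the real haplotype set, with two documented
  artifacts: expanded intra-group and S-vs-F distances can exceed the
  reported ranges (the reported overall maxima, 6.96% *p* / 7.49% K2P,
  correspond to the Asian elephant × S-clade comparison, exposed as
  `emax_s_clade_max()`); and in neighbour-joining trees of the full
  expansion the F clade is paraphyletic, because the mammoth haplotype
  sits one transition from the F-clade background while expanded F
  haplotypes lie up to four apart. Real F haplotypes are coherent lineages
  (intraspecific distances at most ~0.9% against interspecific ones of
  1.8%+), and on subsets with that structure all four lineages are
  recovered as clades.

Because the F clade is a single matrilineal lineage shared by forest
elephants and introgressed savanna elephants, the expanded F-clade
haplotypes of the two African species overlap exactly. The panel-integrity
check therefore rejects duplicate haplotypes across *assignment taxa*
(Asian elephant / S clade / F clade / mammoth), not across species labels
within the F clade, where duplication is biologically expected.

## In-silico PCR

Primer matching is IUPAC-aware: a template base counts as a mismatch only
if it falls outside the expansion of the primer code, so bases covered by
the degenerate R/Y positions are never penalised. This convention is what
reproduces the published differential-nucleotide totals (hippopotamus 6,
white rhinoceros 9, human 11, domestic cattle 12; all elephantids 0):

```{r}
tabulate_primer_mismatches(panel)
```

A template `N` is treated as incompatible with every primer code — the
conservative choice for forensic prediction.

Amplification requires both primers to pass a configurable policy. The
observed data pin down only the extremes (0 mismatches amplify, 6+ do
not), so the default thresholds — at most 3 total mismatches per primer
and at most 1 within the five 3'-terminal positions — sit between those
regimes and encode the standard PCR observation that 3'-end mismatches are
disproportionately disruptive. Binding-site search scans both strands at
every offset (no gapped alignment; primer-region indels are out of scope);
among candidate site pairs the one minimising total mismatches wins, with
ties resolved to the leftmost plus-strand sites, so output is
deterministic.

```{r}
pcr <- run_insilico_pcr(panel_templates(panel))
table(amplified = pcr$amplified, insert_len = pcr$insert_len)
```

## Distances, the barcoding gap and trees

Following the assay's analysis settings, distances count transitions only:
`p_distance_ts()` is the proportion of compared sites differing by a
transition, and `k2p_ts()` is the transitional component of Kimura's
two-parameter model,

$$d = -\tfrac{1}{2}\ln(1 - 2P - Q) + \tfrac{1}{4}\ln(1 - 2Q),$$

which reduces to $-\tfrac12\ln(1-2P)$ at $Q = 0$. Positions with `N`, gaps
or ambiguity codes in either sequence are excluded per pair (pairwise
deletion). Saturated pairs (non-positive log argument) raise an error
naming the offending quantities rather than returning `NaN`. Note that the
familiar bound $d_{K2P} \ge p$ holds strictly only in the transversion-free
regime the marker operates in; at high transversion load the
$\tfrac14\ln(1-2Q)$ term can dominate. Nucleotide diversity deliberately
uses the complementary convention — all substitution types — mirroring the
asymmetry in the original analysis tools (distance matrices from a
transitions-only setting, diversity from DnaSP defaults).

```{r}
haps <- panel$haplotypes
tbl <- tibble::tibble(id = haps$haplotype_id, species = haps$group,
                      sequence = haps$sequence)
s <- distance_summary(tbl, model = "k2p")
glance(s)
round(100 * c(p = emax_s_clade_max(panel, "p"),
              k2p = emax_s_clade_max(panel, "k2p")), 2)
```

`barcoding_gap()` reports the difference between the maximum intraspecific
and minimum interspecific distance, negative when the distributions
overlap (as they do on the full expansion — see the artifacts above) —
never clamped. Trees come from standard neighbour-joining (`nj_tree()`,
validated input, deterministic given row order) with bipartition-based
monophyly checks and an optional site-resampling bootstrap; the bootstrap
defaults to the *p* model because resampled columns can saturate the K2P
transform. Likelihood and Bayesian inference are out of scope.

## Classification

`diagnostic_assign()` reads the eight interspecific positions and applies
majority rules: at least 2 of the 3 Asian-elephant diagnostics
(15148=A, 15184=T, 15238=T), at least 3 of the 4 S-clade diagnostics
(15193=T, 15205=C, 15208=T, 15211=T), the single mammoth diagnostic
(15221=G) with no competing lineage firing, or an exact match of all eight
F-clade background states. The assay's description fixes the diagnostic
table but no decision rule; majority-with-conflict-flags is this
package's choice. It tolerates single deamination hits while surfacing every stray
state (for example, C→T damage at 15238 on a mammoth fragment creates the
Asian-elephant state there; the call stays mammoth because 15148 and 15184
still disagree, and the stray state is flagged). F-clade calls are
genus-level by design — F-clade mtDNA cannot separate forest elephants
from introgressed savanna elephants, and hybrids carry the matrilineal
species' mtDNA regardless; nuclear markers are out of scope.

`distance_assign()` assigns the group of the nearest panel haplotype by
K2P-Ts distance when that distance is at most the threshold. The default,
1.35%, is the midpoint of the reported barcoding gap (0.89% to 1.80%
K2P); the assay defines the gap, not a cutoff, so the threshold is
configurable. Nearest-neighbour ties across groups yield an unassigned
call.

`classify()` combines both. Agreement gives the shared taxon; two
conflicting taxa give unassigned with both recorded; a fragment whose
diagnostic characters support no lineage stays unassigned even if the
distance screen passes (the diagnostic characters are the forensic basis
of the assay); a diagnostic call whose distance check merely abstains
(threshold exceeded, ambiguous neighbour) is retained with the abstention
flagged. The asymmetry is deliberate: under realistic interior damage
rates, two background deamination hits already push a fragment past the
1.35% threshold (2/115 ≈ 1.74%) without touching a single diagnostic
site, and an abstention is not evidence against the diagnostic call —
whereas a diagnostic pattern that matches no lineage is.

```{r}
calls <- classify(tibble::tibble(id = haps$haplotype_id,
                                 sequence = haps$sequence), panel)
table(truth = haps$taxon, called = calls$taxon)
```

## The damage simulator

Post-mortem cytosine deamination reads out as C→T (and, for lesions on the
complementary strand, G→A) substitutions, concentrated on the outermost
~10 bases of a fragment but present at low level throughout.
`damage_model()` captures exactly that: a terminal-window rate over the
outer `terminal_window` bases (default 10) and an interior rate elsewhere,
each applied independently per C/G site; no other substitution is ever
introduced. The defaults (terminal 0.05, interior 0.005 per site) are
simulation choices for exercising the assay on plausibly degraded
templates — published characterisations of the phenomenon are
qualitative.
UNG treatment is modelled as a multiplicative 1000-fold rate reduction
(`ung = TRUE`), not as a sequence operation. Damage is applied to a single
represented strand with both C→T and G→A possible; strand-specific 5'/3'
asymmetry, fragment-length distributions, base qualities and amplification
kinetics are not modelled. Contaminant templates in `simulate_samples()`
stand for modern DNA (human handling, cattle substrate) and are therefore
left undamaged.

What passing simulations do and do not show: because terminal windows of a
160 bp template coincide with the primer regions, terminal damage stresses
amplification while interior damage stresses classification — the two
failure modes of the real assay — but the simulator's templates are exact
reconstructions plus damage, so results say nothing about haplotypes
absent from the panel, co-amplifying paralogues, or sequencing error.

```{r}
set.seed(1)
sim <- simulate_samples(panel, 20, damage_model(0.05, 0.005))
res <- run_identify(sim, panel)
table(res$taxon == sim$truth_label)
```

Copy-number arithmetic for designing sensitivity-style dilution series is
included (`copies_from_mass()`, using 660 g/mol/bp for duplex DNA, and
`serial_dilution()`); the empirically measured copy numbers and detection
limits of the wet-lab assay are laboratory observations and are not
asserted anywhere in this package.

## Problem sizes and numerical choices

The test suite sizes its stochastic checks as follows: binomial
calibration of the damage simulator at 10^4 replicates (mean event count
within 3 standard errors of expectation); end-to-end damaged-mammoth
recovery at n = 500 templates (terminal 0.05 / interior 0.005; at least
95% correct calls); a 3-point interior-rate grid (0, 0.01, 0.05) at n =
500 per point for the monotone accuracy check; all under fixed seeds.
Distance ties use an absolute tolerance of 1e-12; matrix symmetry is
checked at 1e-9. Degenerate inputs (all-`N` fragments, empty FASTA,
saturated pairs, single-sequence species) raise informative errors or
documented unassigned calls rather than propagating `NaN`.

## Command line

A thin CLI over these functions ships in `inst/cli/ivoryid` with
subcommands `identify`, `insilico-pcr`, `distances`, `simulate`,
`validate-panel` and `panel-export`; exit codes are 0 (success),
1 (validation failure) and 2 (usage or input error).

## Limitations

* The panel covers the assay's four elephantid groups; other
  mammoths (*M. columbi*, *M. jeffersonii*) are expected to amplify but
  have no diagnostic states in the panel and are out of scope.
* Cartesian expansion over-generates haplotype combinations (see the
  artifacts above); expansion-wide distance ranges and trees must be read
  with that in mind.
* In-silico amplification is a mismatch-count model: no melting
  temperature, thermodynamics, template competition or nested designs.
* mtDNA cannot assign hybrids to species, and F-clade calls are
  genus-level by construction.
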