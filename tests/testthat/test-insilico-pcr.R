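test_that("IUPAC compatibility follows the code expansions", {
  expect_true(iupac_compatible("R", "A"))
  expect_true(iupac_compatible("R", "G"))
  expect_false(iupac_compatible("R", "T"))
  expect_true(iupac_compatible("Y", "T"))
  expect_false(iupac_compatible("Y", "A"))
  expect_false(iupac_compatible("N", "N"))  # template N never matches
  expect_false(iupac_compatible("A", "N"))
  expect_error(iupac_compatible("Z", "A"), "IUPAC")
  expect_error(iupac_compatible("A", "R"), "template base")
})

.seq_chars_test <- function(x) strsplit(x, "")[[1]]

test_that("primer pair has the documented structure", {
  pr <- elephantid_primers()
  expect_identical(nchar(pr$sequence), c(22L, 22L))
  deg <- function(s) sum(!.seq_chars_test(s) %in% c("A", "C", "G", "T"))
  expect_identical(deg(pr$sequence[1]), 3L)
  expect_identical(deg(pr$sequence[2]), 1L)
})

# independent re-count of the reference rows, not using the package's
# matching machinery
oracle_count <- function(primer, row) {
  expand <- list(A = "A", C = "C", G = "G", T = "T",
                 R = c("A", "G"), Y = c("C", "T"))
  pch <- .seq_chars_test(primer)
  toks <- primer_region_tokens(row)
  mm <- 0L
  for (i in seq_along(pch)) {
    if (toks[i] == ".") next
    alts <- strsplit(toks[i], "/", fixed = TRUE)[[1]]
    if (!any(alts %in% expand[[pch[i]]])) mm <- mm + 1L
  }
  mm
}

test_that("mismatch counting reproduces the differential-nucleotide totals", {
  pr <- elephantid_primers()
  tab <- tabulate_primer_mismatches(the_panel)
  # species named with explicit counts in the source study
  expect_identical(tab$total[tab$species == "H. amphibius"], 6L)
  expect_identical(tab$total[tab$species == "C. simum"], 9L)
  expect_identical(tab$total[tab$species == "H. sapiens"], 11L)
  expect_identical(tab$total[tab$species == "B. taurus"], 12L)
  expect_true(all(tab$total[tab$elephantid] == 0L))
  # full cross-check against the independent oracle
  regions <- the_panel$primer_regions
  for (i in seq_len(nrow(regions))) {
    expect_identical(
      tab$forward_mismatches[i],
      oracle_count(pr$sequence[1], regions$forward_row[i]),
      info = regions$species[i]
    )
    expect_identical(
      tab$reverse_mismatches[i],
      oracle_count(pr$sequence[2], regions$reverse_row[i]),
      info = regions$species[i]
    )
  }
})

test_that("count_primer_mismatches handles regions and the 3' window", {
  m <- count_primer_mismatches("TACTACTRATYACYATAGCCAC",
                               ".......A..C..C........")
  expect_identical(m$total_mismatches, 0L)
  # primer against its own resolved sequence
  m2 <- count_primer_mismatches("TACTACTRATYACYATAGCCAC",
                                "TACTACTAATCACCATAGCCAC")
  expect_identical(m2$total_mismatches, 0L)
  # mismatches at the 3' end are tracked separately
  region <- "TACTACTAATCACCATAGCCAC"
  substr(region, 21, 22) <- "TT"
  m3 <- count_primer_mismatches("TACTACTRATYACYATAGCCAC", region)
  expect_identical(m3$total_mismatches, 2L)
  expect_identical(m3$three_prime_mismatches, 2L)
  expect_identical(m3$mismatch_positions$offset, c(21L, 22L))
  expect_error(count_primer_mismatches("ACGT", "ACGTA"), "positions")
})

test_that("amplification policy applies totals and the 3'-end rule", {
  mk <- function(total, three) {
    structure(list(total_mismatches = total,
                   three_prime_mismatches = three),
              class = "primer_match")
  }
  ok <- mk(0L, 0L)
  expect_true(predict_amplification(ok, ok))
  expect_false(predict_amplification(mk(6L, 0L), ok))
  expect_false(predict_amplification(ok, mk(4L, 0L)))
  # two mismatches confined to the 3'-terminal five block amplification
  expect_false(predict_amplification(mk(2L, 2L), ok))
  expect_true(predict_amplification(mk(3L, 1L), mk(3L, 1L)))
  loose <- amplification_policy(max_mismatches = 6, max_three_prime = 2)
  expect_true(predict_amplification(mk(6L, 0L), ok, loose))
})

test_that("in-silico PCR amplifies every panel template exactly", {
  pcr <- run_insilico_pcr(the_templates)
  expect_true(all(pcr$amplified))
  expect_true(all(pcr$amplicon_len == 160L))
  expect_true(all(pcr$insert_len == 116L))
  # extraction introduces no mutation: insert equals the haplotype
  expect_identical(pcr$insert, the_panel$haplotypes$sequence)
})

test_that("PCR scanning is strand-symmetric and position-independent", {
  tmpl <- the_templates$sequence[1]
  fwd <- run_insilico_pcr(c(x = tmpl))
  rev <- run_insilico_pcr(c(x = reverse_complement(tmpl)))
  expect_true(rev$amplified)
  expect_identical(rev$insert, fwd$insert)
  expect_identical(rev$strand, "-")
  # template embedded deep inside a longer molecule
  set.seed(404)
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  long <- paste0(pad(70), tmpl, pad(90))
  res <- run_insilico_pcr(c(x = long))
  expect_true(res$amplified)
  expect_identical(res$insert, fwd$insert)
})

test_that("non-target species and primer-free sequences do not amplify", {
  for (sp in c("H. sapiens", "B. taurus", "H. amphibius", "C. simum")) {
    res <- run_insilico_pcr(stats::setNames(nontarget_template(the_panel, sp),
                                            sp))
    expect_false(res$amplified)
  }
  set.seed(101)
  noise <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  res <- run_insilico_pcr(c(noise = noise))
  expect_false(res$amplified)
  expect_true(is.na(res$amplicon))
})

test_that("mixed mammoth + human input amplifies only the mammoth", {
  mam <- the_templates$sequence[the_templates$taxon == "M. primigenius"][1]
  mix <- tibble::tibble(
    id = c("mammoth", paste0("human_", 1:5)),
    sequence = c(mam, rep(nontarget_template(the_panel, "H. sapiens"), 5))
  )
  res <- run_insilico_pcr(mix)
  expect_identical(res$template_id[res$amplified], "mammoth")
})

test_that("an empty region table tabulates to an empty report", {
  empty <- the_panel$primer_regions[0, ]
  tab <- tabulate_primer_mismatches(empty)
  expect_identical(nrow(tab), 0L)
})
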