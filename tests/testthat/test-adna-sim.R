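test_that("damage model validates and applies the UNG reduction", {
  m <- damage_model(0.05, 0.005, 10)
  expect_equal(m$terminal_rate, 0.05)
  ung <- damage_model(0.05, 0.005, ung = TRUE)
  expect_equal(ung$terminal_rate, 0.05 * 0.001)
  expect_equal(ung$interior_rate, 0.005 * 0.001)
  expect_error(damage_model(-0.1, 0), "terminal_rate")
  expect_error(damage_model(0.1, 1.5), "interior_rate")
})

test_that("deamination only ever converts C to T and G to A", {
  seq <- "ACGTACGTNN-ACGT"
  none <- apply_deamination(seq, damage_model(0, 0))
  expect_identical(none$sequence, toupper(seq))
  expect_identical(nrow(none$events), 0L)

  all <- apply_deamination(seq, damage_model(1, 1))
  expect_identical(all$sequence, gsub("G", "A", gsub("C", "T", toupper(seq))))
  expect_true(all(all$events$from %in% c("C", "G")))
  expect_true(all(ifelse(all$events$from == "C", "T", "A") == all$events$to))

  set.seed(31)
  for (i in 1:20) {
    res <- apply_deamination(strrep("ACGT", 29), damage_model(0.5, 0.1))
    ch_in <- strsplit(strrep("ACGT", 29), "")[[1]]
    ch_out <- strsplit(res$sequence, "")[[1]]
    changed <- which(ch_in != ch_out)
    expect_true(all(ch_in[changed] %in% c("C", "G")))
    expect_setequal(changed, res$events$position)
  }
})

test_that("damage events are reproducible under a fixed seed", {
  tmpl <- the_templates$sequence[1]
  set.seed(99)
  a <- apply_deamination(tmpl, damage_model())
  set.seed(99)
  b <- apply_deamination(tmpl, damage_model())
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$events, b$events)
})

test_that("event counts match the binomial expectation", {
  # uniform interior rate on a known C/G content: 40 damageable sites at
  # rate 0.01 over 10^4 replicates; mean within 3 standard errors of 0.4
  seq <- paste0(strrep("C", 20), strrep("G", 20), strrep("A", 76))
  model <- damage_model(terminal_rate = 0.01, interior_rate = 0.01,
                        terminal_window = 0)
  n_rep <- 10000L
  set.seed(20260928)
  counts <- vapply(seq_len(n_rep), function(i) {
    nrow(apply_deamination(seq, model)$events)
  }, integer(1))
  expectation <- 40 * 0.01
  se <- sqrt(40 * 0.01 * 0.99 / n_rep)
  expect_lt(abs(mean(counts) - expectation), 3 * se)
})

test_that("terminal windows are enriched as the rate ratio predicts", {
  # all-C template: 10 terminal sites each end at 0.05, 96 interior at
  # 0.005; expected terminal fraction = 1 / (1 + 96*0.005 / (20*0.05))
  seq <- strrep("C", 116)
  model <- damage_model(0.05, 0.005, 10)
  set.seed(4242)
  term <- 0L
  total <- 0L
  for (i in 1:4000) {
    ev <- apply_deamination(seq, model)$events
    total <- total + nrow(ev)
    term <- term + sum(ev$position <= 10 | ev$position > 106)
  }
  expected_frac <- (20 * 0.05) / (20 * 0.05 + 96 * 0.005)
  expect_equal(term / total, expected_frac, tolerance = 0.1)
})

test_that("simulated sample sets carry truth labels and determinism", {
  sim1 <- simulate_samples(the_panel, 30, damage_model(0, 0), seed = 5)
  sim2 <- simulate_samples(the_panel, 30, damage_model(0, 0), seed = 5)
  expect_identical(sim1, sim2)
  expect_identical(nrow(sim1), 30L)
  expect_true(all(sim1$truth_label %in% the_panel$haplotypes$taxon))
  expect_true(all(nchar(sim1$sequence) == 160L))

  # FASTA output is byte-identical on rerun
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  simulate_samples(the_panel, 10, damage_model(), seed = 77, fasta = f1)
  simulate_samples(the_panel, 10, damage_model(), seed = 77, fasta = f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("contamination fractions are honoured and validated", {
  sim <- simulate_samples(the_panel, 12, damage_model(0, 0),
                          contamination = c("H. sapiens" = 5 / 6),
                          seed = 3)
  expect_identical(sum(sim$species == "H. sapiens"), 10L)
  expect_identical(sum(sim$species != "H. sapiens"), 2L)
  expect_error(
    simulate_samples(the_panel, 10,
                     contamination = c("E. maximus" = 0.5)),
    "unknown contaminant"
  )
  expect_error(
    simulate_samples(the_panel, 10,
                     contamination = c("H. sapiens" = 0.7,
                                       "B. taurus" = 0.6)),
    "at most 1"
  )
})

test_that("undamaged simulation recovers every label end to end", {
  sim <- simulate_samples(the_panel, 60, damage_model(0, 0), seed = 11)
  pcr <- run_insilico_pcr(sim)
  expect_true(all(pcr$amplified))
  calls <- classify(tibble::tibble(id = pcr$template_id,
                                   sequence = pcr$insert), the_panel)
  expect_identical(calls$taxon, sim$truth_label)
})

test_that("accuracy is non-increasing in the interior damage rate", {
  rates <- c(0, 0.01, 0.05)
  acc <- vapply(seq_along(rates), function(k) {
    sim <- simulate_samples(the_panel, 500,
                            damage_model(0.05, rates[k]),
                            seed = 1000 + k)
    pcr <- run_insilico_pcr(sim)
    ok <- which(pcr$amplified)
    calls <- classify(tibble::tibble(id = pcr$template_id[ok],
                                     sequence = pcr$insert[ok]), the_panel)
    correct <- sum(calls$taxon == sim$truth_label[ok])
    correct / nrow(sim)
  }, numeric(1))
  expect_identical(acc, cummin(acc))
  expect_gte(acc[1], 0.99)
})

test_that("copy-number arithmetic follows the molar-mass formula", {
  expect_equal(copies_from_mass(1, 1000), 1e-9 * 6.02214076e23 / 660000)
  expect_equal(copies_from_mass(1, 1000) / 1e8, 9.1, tolerance = 0.01)
  expect_equal(copies_from_mass(2, 1000), 2 * copies_from_mass(1, 1000))
  expect_equal(copies_from_mass(1, 1000, double_stranded = FALSE),
               2 * copies_from_mass(1, 1000))
  expect_error(copies_from_mass(0, 100), "positive")
  expect_error(copies_from_mass(1, -5), "positive")
})

test_that("serial dilution is an exact geometric series", {
  expect_equal(serial_dilution(1e4, 10, 4), c(1e4, 1e3, 1e2, 10, 1))
  expect_equal(serial_dilution(100, 4, 1), c(100, 25))
  expect_equal(serial_dilution(253896, 10, 4)[5], 25.3896)
  expect_error(serial_dilution(10, 1, 3), "factor")
})
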