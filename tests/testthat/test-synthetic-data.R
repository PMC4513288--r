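test_that("default transcriptome encodes the study composition and CDS invariants", {
  tx <- fixture_tx()
  g <- tx$genes
  expect_setequal(g$gene, c("pGO1", "pGO2", "pUVO", "pTRP", "pTRPL", "actin", "GAPDH"))
  cn <- setNames(g$copy_number, g$gene)
  expect_equal(cn[["pGO1"]] / cn[["pGO2"]], 100)
  expect_equal(cn[["pTRPL"]] / cn[["pTRP"]], 10)
  for (i in seq_len(nrow(g))) {
    cds <- g$cds[i]
    expect_equal(nchar(cds) %% 3, 0)
    expect_equal(substr(cds, 1, 3), "ATG")
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    expect_true(codons[length(codons)] %in% c("TAA", "TAG", "TGA"))
    expect_equal(sum(codons %in% c("TAA", "TAG", "TGA")), 1)  # only the terminal stop
    expect_equal(g$seq[i], paste0(substr(g$seq[i], 1, g$cds_start[i] - 1), cds,
                                  substr(g$seq[i], g$cds_end[i] + 1, g$length[i])))
  }
})

test_that("green-opsin paralogs realize the configured nucleotide identity", {
  tx <- fixture_tx()
  a <- strsplit(tx$genes$cds[tx$genes$gene == "pGO1"], "")[[1]]
  b <- strsplit(tx$genes$cds[tx$genes$gene == "pGO2"], "")[[1]]
  ident <- mean(a == b)
  expect_equal(ident, 0.85, tolerance = 0.002)
  # every 100-nt window differs enough that 90/100 counting cannot cross-match
  diffs <- which(a != b)
  win_diff <- vapply(seq_len(length(a) - 99), function(s)
    sum(diffs >= s & diffs < s + 100), integer(1))
  expect_gt(min(win_diff), 10)

  tx100 <- make_transcriptome(retina_config(paralog_identity = 100), seed = 7)
  expect_identical(tx100$genes$cds[tx100$genes$gene == "pGO1"],
                   tx100$genes$cds[tx100$genes$gene == "pGO2"])
})

test_that("generators are byte-deterministic under a fixed seed", {
  t1 <- make_transcriptome(seed = 5)
  t2 <- make_transcriptome(seed = 5)
  expect_identical(t1$genes, t2$genes)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta(tibble::tibble(id = t1$genes$gene, seq = t1$genes$seq), f1)
  write_fasta(tibble::tibble(id = t2$genes$gene, seq = t2$genes$seq), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))
  r1 <- simulate_reads(t1, 50, seed = 9)
  r2 <- simulate_reads(t2, 50, seed = 9)
  expect_identical(r1, r2)
  expect_false(identical(r1, simulate_reads(t1, 50, seed = 10)))
})

test_that("invalid generator configurations are rejected", {
  expect_error(retina_config(paralog_identity = 60), "identity")
  comp <- retina_composition(); comp$copy_number[1] <- 0
  expect_error(retina_config(composition = comp), "copy numbers")
  expect_error(retina_config(composition = retina_composition()[0, ]), "at least one")
  tx <- fixture_tx()
  expect_error(simulate_reads(tx, 0), "empty library")
  expect_error(simulate_reads(tx, 10, error_rate = 0.5), "error_rate")
})

test_that("error-free reads are exact transcript substrings from both strands", {
  comp <- retina_composition()[6, ]  # actin only
  tx <- make_transcriptome(retina_config(composition = comp, paralog_pair = c("x", "y")),
                           seed = 3)
  reads <- simulate_reads(tx, 50, error_rate = 0, quality_model = "clean", seed = 4)
  truth <- tx$genes$seq[1]
  rc <- revcomp_chr(truth)
  fwd_hit <- vapply(reads$seq, grepl, logical(1), x = truth, fixed = TRUE, USE.NAMES = FALSE)
  rev_hit <- vapply(reads$seq, grepl, logical(1), x = rc, fixed = TRUE, USE.NAMES = FALSE)
  expect_true(all(fwd_hit | rev_hit))
  expect_true(any(reads$strand == "+") && any(reads$strand == "-"))
  # provenance: the recorded start/strand reproduces each read exactly
  at <- ifelse(reads$strand == "+",
               substring(truth, reads$start, reads$start + 99),
               revcomp_chr(substring(truth, reads$start, reads$start + 99)))
  expect_identical(reads$seq, at)
})

test_that("read sampling follows copy_number x length and clean quality floors at 30", {
  comp <- tibble::tibble(gene = c("hi", "lo"), copy_number = c(10, 1),
                         cds_length = c(501, 501), utr5_length = 50, utr3_length = 50)
  tx <- make_transcriptome(retina_config(composition = comp, paralog_pair = c("x", "y")),
                           seed = 11)
  reads <- simulate_reads(tx, 20000, error_rate = 0, quality_model = "clean", seed = 12)
  n_hi <- sum(reads$gene == "hi")
  p <- 10 / 11
  expect_lt(abs(n_hi - 40000 * p), 3 * sqrt(40000 * p * (1 - p)))
  expect_true(all(utf8ToInt(paste0(unique(reads$qual), collapse = "")) - 33 >= 30))
  expect_true(all(nchar(reads$seq) == 100))
})

test_that("qPCR plate simulator follows the closed-form Cq model", {
  truth <- tibble::tibble(gene = c("t", "actin", "GAPDH"), copy_number = c(8, 1, 1))
  effs <- c(t = 1, actin = 1, GAPDH = 1)
  sc <- rnai_scenario("t", knockdown = c(t = 0.5), sham_prob = 0)
  plate <- simulate_qpcr_plate(truth, sc, effs, n_animals = 1, n_replicates = 1,
                               noise_sd = 0, animal_sd_log2 = 0, seed = 1)
  cqs <- setNames(plate$cq, paste(plate$gene, plate$group))
  # halving the quantity at E = 1 costs exactly one cycle
  expect_equal(cqs[["t treated"]] - cqs[["t control"]], 1)
  # E = 0.875, quantity x 1/8: 3 / log2(1.875) cycles
  sc8 <- rnai_scenario("t", knockdown = c(t = 1 / 8), sham_prob = 0)
  plate8 <- simulate_qpcr_plate(truth, sc8, c(t = 0.875, actin = 1, GAPDH = 1),
                                n_animals = 1, n_replicates = 1,
                                noise_sd = 0, animal_sd_log2 = 0, seed = 1)
  cqs8 <- setNames(plate8$cq, paste(plate8$gene, plate8$group))
  expect_equal(cqs8[["t treated"]] - cqs8[["t control"]], 3 / log2(1.875),
               tolerance = 1e-9)
  expect_error(simulate_qpcr_plate(truth, sc, c(t = 1, actin = 1), seed = 1),
               "missing amplification efficiency")
})

test_that("ERG cohort maps functional knockdown onto amplitudes", {
  kin0 <- tibble::tibble(gene = "g", half_life_days = 0, lag_days = 0)
  sc <- rnai_scenario("g", knockdown = c(g = 0.25))
  cfg <- erg_cohort_config(nonresponder_prob = 0, animal_cv = 0, noise_sd = 0)
  erg <- simulate_erg_cohort(sc, cfg, days = 10, kinetics = kin0, seed = 1)
  m <- tapply(erg$amplitude_mv, erg$group, mean)
  expect_equal(unname(m[["treated"]] / m[["control"]]), 0.25, tolerance = 1e-12)

  cfg1 <- erg_cohort_config(nonresponder_prob = 1, animal_cv = 0, noise_sd = 0)
  erg1 <- simulate_erg_cohort(sc, cfg1, days = 10, kinetics = kin0, seed = 2)
  m1 <- tapply(erg1$amplitude_mv, erg1$group, mean)
  expect_equal(unname(m1[["treated"]]), unname(m1[["control"]]), tolerance = 1e-12)

  # expected non-responders per batch of eight at the default rate: one-ish
  cfg8 <- erg_cohort_config()
  counts <- vapply(1:200, function(i) {
    e <- simulate_erg_cohort(sc, cfg8, days = 10, kinetics = kin0, seed = i)
    length(unique(e$animal[e$nonresponder]))
  }, numeric(1))
  expect_gt(mean(counts), 0.6)
  expect_lt(mean(counts), 1.4)
})

test_that("functional fraction follows first-order decay with dead time", {
  kin <- tibble::tibble(gene = "g", half_life_days = 2, lag_days = 3)
  sc <- rnai_scenario("g", knockdown = c(g = 0.1))
  expect_equal(functional_fraction(sc, 2, kin), 1)
  expect_equal(functional_fraction(sc, 5, kin), 0.1 + 0.9 * 2^-1)
  expect_equal(functional_fraction(scenario_identity(), 10), 1)
})
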