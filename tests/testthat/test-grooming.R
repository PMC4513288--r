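test_that("single-read grooming follows the longest-run rule", {
  seq100 <- strrep("A", 100)
  all30 <- phred_encode_q(rep(30, 100))
  g <- groom_read(seq100, all30)
  expect_true(g$kept)
  expect_equal(c(g$start, g$end), c(1, 100))
  expect_equal(nchar(g$seq), 100)

  # longest qualifying run of 79 -> rejected: threshold is "at least 80"
  q79 <- c(rep(30, 79), rep(10, 21))
  expect_false(groom_read(seq100, phred_encode_q(q79))$kept)
  q80 <- c(rep(30, 80), rep(10, 20))
  g80 <- groom_read(seq100, phred_encode_q(q80))
  expect_true(g80$kept)
  expect_equal(c(g80$start, g80$end), c(1, 80))

  # one bad base at position 50 splits the read into runs of 49 and 50
  qmid <- rep(30, 100); qmid[50] <- 10
  expect_false(groom_read(seq100, phred_encode_q(qmid))$kept)

  # Phred 20 passes (> 19 is strict), Phred 19 does not
  expect_true(groom_read(seq100, phred_encode_q(rep(20, 100)))$kept)
  expect_false(groom_read(seq100, phred_encode_q(rep(19, 100)))$kept)

  expect_error(groom_read("ACGT", "II"), "lengths differ")
})

test_that("library grooming equals the per-read oracles on random reads", {
  set.seed(42)
  n <- 300
  # mixture: clean reads, reads with a few low-quality dips, noisy tails
  quals <- replicate(n, {
    base <- rep(sample(c(25, 30, 35), 1), 100)
    n_dip <- sample(0:3, 1, prob = c(.35, .3, .2, .15))
    if (n_dip > 0) base[sample(100, n_dip)] <- sample(c(2, 10, 19), n_dip, TRUE)
    if (runif(1) < 0.3) {
      tail_from <- sample(60:100, 1)
      base[tail_from:100] <- sample(c(5, 12, 18), 101 - tail_from, TRUE)
    }
    base
  }, simplify = FALSE)
  reads <- tibble::tibble(
    id = paste0("r", seq_len(n)),
    seq = vapply(seq_len(n), function(i)
      paste0(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = ""), character(1)),
    qual = vapply(quals, phred_encode_q, character(1))
  )
  g <- groom_reads(reads)
  oracle <- lapply(quals, groom_oracle_rle)
  kept_oracle <- !vapply(oracle, is.null, logical(1))
  expect_equal(g$report$n_kept, sum(kept_oracle))
  expect_equal(g$report$n_rejected, n - sum(kept_oracle))
  expect_identical(g$reads$id, reads$id[kept_oracle])
  spans <- do.call(rbind, lapply(oracle[kept_oracle], function(o) c(o$start, o$end)))
  expect_equal(unname(cbind(g$reads$source_start, g$reads$source_end)), unname(spans))
  # trimmed sequence is the retained run
  expect_identical(g$reads$seq,
                   substring(reads$seq[kept_oracle], spans[, 1], spans[, 2]))
  # quadratic oracle agrees on a subsample
  for (i in seq_len(50)) {
    o2 <- groom_oracle_quadratic(quals[[i]])
    expect_identical(is.null(o2), !kept_oracle[i])
  }
})

test_that("grooming is idempotent and handles degenerate libraries", {
  set.seed(7)
  reads <- tibble::tibble(
    id = paste0("r", 1:50),
    seq = replicate(50, paste0(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")),
    qual = replicate(50, phred_encode_q(sample(c(12, 25, 33), 100, TRUE)))
  )
  g1 <- groom_reads(reads)
  g2 <- groom_reads(g1$reads)
  expect_identical(g2$reads$seq, g1$reads$seq)
  expect_identical(g2$reads$qual, g1$reads$qual)
  expect_equal(g2$report$n_rejected, 0)
  expect_equal(g2$report$n_trimmed, 0)

  all_pass <- tibble::tibble(id = "a", seq = strrep("A", 90), qual = strrep("I", 90))
  gp <- groom_reads(all_pass)
  expect_equal(gp$report$n_rejected, 0)
  expect_equal(nrow(gp$reads), 1)
  all_fail <- tibble::tibble(id = "b", seq = strrep("A", 90), qual = strrep("!", 90))
  gf <- groom_reads(all_fail)
  expect_equal(gf$report$n_kept, 0)
  expect_equal(nrow(gf$reads), 0)
})

test_that("no-trim mode keeps whole reads containing a qualifying run", {
  seq100 <- strrep("ACGT", 25)
  q <- c(rep(10, 10), rep(30, 85), rep(10, 5))
  g <- groom_read(seq100, phred_encode_q(q), trim = FALSE)
  expect_true(g$kept)
  expect_equal(nchar(g$seq), 100)
  expect_equal(c(g$start, g$end), c(11, 95))
})

test_that("FASTQ grooming preserves counts and keeps surviving mates", {
  tx <- fixture_tx()
  reads <- simulate_reads(tx, 150, seed = 33)
  f1 <- tempfile(fileext = ".fq"); f2 <- tempfile(fileext = ".fq")
  o1 <- tempfile(fileext = ".fq"); o2 <- tempfile(fileext = ".fq")
  write_fastq(reads[reads$mate == 1, ], f1)
  write_fastq(reads[reads$mate == 2, ], f2)
  rep <- groom_fastq(f1, o1, f2, o2)
  expect_equal(rep$n_input_reads, 300)
  expect_equal(rep$n_kept + rep$n_rejected, rep$n_input_reads)
  expect_equal(nrow(read_fastq(o1)) + nrow(read_fastq(o2)), rep$n_kept)
  # a pair where only one mate survives is still represented by the survivor
  in_mem <- groom_reads(reads)$reads
  surv_ids <- table(in_mem$id)
  expect_true(any(surv_ids == 1))
})
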