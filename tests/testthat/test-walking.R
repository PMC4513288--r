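# tile error-free reads of length `rl` every `by` nt across a transcript
tile_reads <- function(seq, rl = 100L, by = 4L, prefix = "t") {
  starts <- seq(1L, nchar(seq) - rl + 1L, by = by)
  tibble::tibble(id = paste0(prefix, starts),
                 seq = substring(seq, starts, starts + rl - 1L))
}

test_that("read index postings match a brute-force scan", {
  r <- tibble::tibble(id = "r1", seq = strrep("ACGT", 25))
  expect_error(build_read_index(r, k = 7), "k")
  expect_error(build_read_index(r, k = 16), "k")

  set.seed(1)
  one <- tibble::tibble(id = "solo",
                        seq = paste0(sample(c("A","C","G","T"), 15, TRUE), collapse = ""))
  idx1 <- build_read_index(one, k = 15)
  hit <- index_lookup(idx1, one$seq)
  expect_equal(nrow(hit[hit$strand == "+", ]), 1)
  rc_hit <- index_lookup(idx1, revcomp_chr(one$seq))
  expect_equal(nrow(rc_hit[rc_hit$strand == "-", ]), 1)
  expect_equal(nrow(index_lookup(idx1, strrep("A", 15))), 0)

  set.seed(2)
  lib <- tibble::tibble(
    id = paste0("r", 1:40),
    seq = replicate(40, paste0(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")))
  idx <- build_read_index(lib, k = 9)
  for (i in 1:15) {
    src <- sample(40, 1); pos <- sample(52, 1)
    kmer <- substr(lib$seq[src], pos, pos + 8)
    got <- index_lookup(idx, kmer)
    # brute force: every occurrence on either strand of every read
    fwd <- gregexpr(kmer, lib$seq, fixed = TRUE)
    rev <- gregexpr(kmer, revcomp_chr(lib$seq), fixed = TRUE)
    want <- sum(vapply(fwd, function(m) sum(m > 0), numeric(1))) +
      sum(vapply(rev, function(m) sum(m > 0), numeric(1)))
    expect_equal(nrow(got), want)
  }
})

test_that("extension reaches transcript ends on error-free tilings and stops on empty index", {
  tx <- fixture_tx()
  truth <- tx$genes$seq[tx$genes$gene == "pUVO"]
  lib <- tile_reads(truth)
  idx <- build_read_index(lib)
  mid <- lib$seq[[length(lib$seq) %/% 2]]
  at <- walk(mid, idx)
  expect_true(grepl(at$seq, truth, fixed = TRUE))
  # depth 25 tiling every 4 nt: only support-starved terminal bases may be lost
  expect_gte(nchar(at$seq), nchar(truth) - 2 * 12)
  expect_true(at$has_stop)
  expect_identical(substr(at$seq, at$cds_start, at$cds_end),
                   tx$genes$cds[tx$genes$gene == "pUVO"])

  empty_idx <- build_read_index(lib[0, ])
  res <- extend_step(strrep("ACGT", 20), empty_idx, "3prime")
  expect_true(res$stopped)
  expect_equal(res$bases_added, 0)

  solo <- build_read_index(lib[1, ])
  at1 <- walk(lib$seq[1], solo)
  # no extension possible; final orientation is whichever frame reads longer
  expect_true(at1$seq %in% c(lib$seq[1], revcomp_chr(lib$seq[1])))
})

test_that("consensus equals truth under 1% read error at depth 30", {
  tx <- fixture_tx()
  truth <- tx$genes$seq[tx$genes$gene == "GAPDH"]
  set.seed(99)
  starts <- sample(nchar(truth) - 99, 360, replace = TRUE)
  seqs <- substring(truth, starts, starts + 99)
  err <- rbinom(length(seqs), 100, 0.01)
  for (i in which(err > 0)) {
    ch <- strsplit(seqs[i], "")[[1]]
    pos <- sample(100, err[i])
    ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(c("A","C","G","T"), b), 1), "")
    seqs[i] <- paste0(ch, collapse = "")
  }
  lib <- tibble::tibble(id = paste0("e", seq_along(seqs)), seq = seqs)
  idx <- build_read_index(lib)
  seed <- substring(truth, 500, 599)  # error-free seed from the middle
  at <- walk(seed, idx)
  expect_true(grepl(at$seq, truth, fixed = TRUE))
  expect_gte(nchar(at$seq), nchar(truth) - 2 * 15)
})

test_that("walking is deterministic and separates 85%-identical paralogs", {
  tx <- fixture_tx()
  g1 <- tx$genes$seq[tx$genes$gene == "pGO1"]
  g2 <- tx$genes$seq[tx$genes$gene == "pGO2"]
  lib <- rbind(tile_reads(g1, prefix = "a"), tile_reads(g2, prefix = "b"))
  idx <- build_read_index(lib)
  seed2 <- substring(g2, 601, 700)
  at_a <- walk(seed2, idx)
  at_b <- walk(seed2, idx)
  expect_identical(at_a$seq, at_b$seq)
  expect_identical(at_a$trace, at_b$trace)
  # assembled from the pGO2-unique seed: matches pGO2 truth, zero pGO1 bases
  expect_true(grepl(at_a$seq, g2, fixed = TRUE))
  off <- as.integer(regexpr(at_a$seq, g2, fixed = TRUE))
  cmp2 <- substring(g2, off, off + nchar(at_a$seq) - 1L)
  expect_identical(at_a$seq, cmp2)
  # coverage: every non-seed position carries at least min_support votes
  expect_true(all(at_a$coverage[at_a$coverage != 1] >= 3))
})

test_that("find_orf matches exhaustive enumeration", {
  expect_equal(find_orf("ATGAAATAA")[c("cds_start", "cds_end", "has_stop")],
               list(cds_start = 1L, cds_end = 9L, has_stop = TRUE))
  open <- find_orf("ATGAAA")
  expect_false(open$has_stop)
  expect_equal(open$length, 6)
  none <- find_orf("CCCCCC")
  expect_true(is.na(none$cds_start))

  set.seed(17)
  for (i in 1:60) {
    s <- paste0(sample(c("A", "C", "G", "T"), sample(10:120, 1), TRUE), collapse = "")
    got <- find_orf(s)
    want <- orf_oracle(s)
    expect_equal(got[c("cds_start", "cds_end", "has_stop", "length")],
                 want[c("cds_start", "cds_end", "has_stop", "length")], info = s)
  }
})
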