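#' Build a k-mer read index for transcriptome walking
#'
#' Indexes every k-mer of every read, on both strands, as integer-packed
#' 2-bit codes in a keyed [data.table::data.table], so that walking can find
#' all reads overlapping a contig anchor in one join. `k` is limited to
#' 8-15 so codes fit a signed 32-bit integer.
#'
#' @param reads Tibble with `id` and `seq` (a groomed library).
#' @param k K-mer length (8-15, default 15).
#' @return An object of class `read_index`.
#' @examples
#' idx <- build_read_index(tibble::tibble(id = "r1", seq = strrep("ACGT", 25)))
#' index_lookup(idx, "ACGTACGTACGTACG")
#' @export
build_read_index <- function(reads, k = 15L) {
  if (k < 8 || k > 15) abort("`k` must be in [8, 15]")
  stopifnot(all(c("id", "seq") %in% names(reads)))
  seqs <- toupper(reads$seq)
  rc <- revcomp(seqs)
  make_postings <- function(ss, strand) {
    codes <- .kmer_codes_cpp(ss, k)
    nk <- lengths(codes)
    data.table::data.table(
      code = unlist(codes, use.names = FALSE),
      read = rep.int(seq_along(ss), nk),
      pos = unlist(lapply(nk, seq_len), use.names = FALSE),
      strand = strand
    )
  }
  postings <- if (length(seqs) == 0) {
    data.table::data.table(code = integer(), read = integer(),
                           pos = integer(), strand = character())
  } else {
    data.table::rbindlist(list(make_postings(seqs, "+"), make_postings(rc, "-")))
  }
  postings <- postings[!is.na(postings$code)]
  data.table::setkeyv(postings, "code")
  structure(list(k = as.integer(k), postings = postings, seqs = seqs,
                 rc_seqs = rc, ids = reads$id),
            class = "read_index")
}

#' @export
print.read_index <- function(x, ...) {
  cat("<read_index> ", length(x$seqs), " reads, k = ", x$k, ", ",
      nrow(x$postings), " postings\n", sep = "")
  invisible(x)
}

#' Look up one k-mer in a read index
#'
#' @param index A [build_read_index()] object.
#' @param kmer A k-length DNA string.
#' @return Tibble `read_id`, `pos` (1-based position of the k-mer in the
#'   read, in the orientation given by `strand`), `strand` (`+` the read as
#'   sequenced, `-` its reverse complement).
#' @export
index_lookup <- function(index, kmer) {
  stopifnot(inherits(index, "read_index"))
  if (nchar(kmer) != index$k) abort("`kmer` must have length k")
  wanted <- data.table::data.table(code = .kmer_codes_cpp(toupper(kmer), index$k)[[1]])
  hit <- index$postings[wanted, on = "code", nomatch = NULL]
  tibble(read_id = index$ids[hit$read], pos = hit$pos, strand = hit$strand)
}

# Candidate oriented reads overlapping the 3' anchor of `contig`.
# Returns a tibble: read row, strand, offset (contig coordinate of oriented
# read position 1), oriented sequence.
anchor_candidates <- function(contig, index, anchor_len) {
  lc <- nchar(contig)
  anchor <- substr(contig, lc - anchor_len + 1L, lc)
  codes <- .kmer_codes_cpp(anchor, index$k)[[1]]
  ao <- which(!is.na(codes))
  if (!length(ao)) return(NULL)
  wanted <- data.table::data.table(code = codes[ao])
  hits <- index$postings[wanted, on = "code", nomatch = NULL]
  if (nrow(hits) == 0) return(NULL)
  # recover which anchor offset(s) each matched code came from
  lookup <- data.table::data.table(code = codes[ao], aoff = ao)
  hits <- lookup[hits, on = "code", allow.cartesian = TRUE]
  off <- (lc - anchor_len + hits$aoff) - hits$pos + 1L
  cand <- tibble(read = hits$read, strand = hits$strand, offset = off) %>% distinct()
  cand$oseq <- ifelse(cand$strand == "+", index$seqs[cand$read], index$rc_seqs[cand$read])
  cand
}

#' One walking extension step
#'
#' Extends a contig in one direction by overlap-and-consensus: reads sharing
#' an exact index k-mer with the terminal anchor are aligned at the implied
#' ungapped offset, kept if they disagree with the anchor at no more than
#' `max_mismatch` positions, and their overhanging bases vote per position.
#' Extension takes the strict-majority base while at least `min_support`
#' reads cover the position, up to `step_cap` bases; a tie or loss of support
#' emits a stop signal (a normal outcome, not an error).
#'
#' @param contig Current contig sequence (>= `anchor_len` nt).
#' @param index A [build_read_index()].
#' @param direction `"3prime"` or `"5prime"`.
#' @param anchor_len Terminal anchor length (default 25).
#' @param min_support Minimum reads covering a position (default 3).
#' @param max_mismatch Mismatches tolerated in the anchor (default 1);
#'   tolerates sequencing error while excluding a ~85%-identical paralog.
#' @param step_cap Maximum bases added per step (default 50); prevents
#'   runaway extension.
#' @return List `seq` (possibly extended contig), `bases_added`, `support`
#'   (vote counts of the added positions), `stopped` (`TRUE` when no further
#'   extension was possible).
#' @export
extend_step <- function(contig, index, direction = c("3prime", "5prime"),
                        anchor_len = 25L, min_support = 3L, max_mismatch = 1L,
                        step_cap = 50L) {
  direction <- match.arg(direction)
  if (nchar(contig) < anchor_len) abort("contig shorter than `anchor_len`")
  if (direction == "5prime") {
    res <- extend_step(revcomp(contig), index, "3prime", anchor_len,
                       min_support, max_mismatch, step_cap)
    res$seq <- revcomp(res$seq)
    res$support <- rev(res$support)
    return(res)
  }
  lc <- nchar(contig)
  cand <- anchor_candidates(contig, index, anchor_len)
  if (is.null(cand) || nrow(cand) == 0) {
    return(list(seq = contig, bases_added = 0L, support = integer(), stopped = TRUE))
  }
  lr <- nchar(cand$oseq)
  # must extend beyond the contig 3' end
  cand <- cand[cand$offset + lr - 1L > lc, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(list(seq = contig, bases_added = 0L, support = integer(), stopped = TRUE))
  }
  # mismatches within the anchor region of the overlap
  a_from <- pmax(lc - anchor_len + 1L, cand$offset)
  in_read_from <- a_from - cand$offset + 1L
  in_read_to <- lc - cand$offset + 1L
  ok <- in_read_from <= in_read_to & in_read_from >= 1L
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(list(seq = contig, bases_added = 0L, support = integer(), stopped = TRUE))
  }
  a_from <- a_from[ok]; in_read_from <- in_read_from[ok]; in_read_to <- in_read_to[ok]
  mm <- .count_mismatches_cpp(substring(cand$oseq, in_read_from, in_read_to),
                              substring(contig, a_from, lc))
  cand <- cand[mm <= max_mismatch, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(list(seq = contig, bases_added = 0L, support = integer(), stopped = TRUE))
  }
  over <- substring(cand$oseq, lc - cand$offset + 2L,
                    pmin(nchar(cand$oseq), lc - cand$offset + 1L + step_cap))
  over <- over[nchar(over) > 0]
  if (!length(over)) {
    return(list(seq = contig, bases_added = 0L, support = integer(), stopped = TRUE))
  }
  maxo <- max(nchar(over))
  chars <- vapply(strsplit(over, ""), function(x) c(x, rep(NA, maxo - length(x))),
                  character(maxo))
  chars <- matrix(chars, nrow = maxo)
  added <- character(0); support <- integer(0)
  for (j in seq_len(maxo)) {
    votes <- chars[j, !is.na(chars[j, ])]
    if (length(votes) < min_support) break
    tab <- sort(table(votes), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) break  # tie: no arbitrary call
    if (tab[1] <= length(votes) / 2) break          # strict majority required
    added <- c(added, names(tab)[1])
    support <- c(support, length(votes))
  }
  if (!length(added)) {
    return(list(seq = contig, bases_added = 0L, support = integer(), stopped = TRUE))
  }
  list(seq = paste0(contig, paste0(added, collapse = "")),
       bases_added = length(added), support = support, stopped = FALSE)
}

# Re-derive the consensus over contig positions [from, to] from all indexed
# reads overlapping that window (ungapped placement implied by shared
# k-mers, kept when their whole-overlap mismatch fraction is small). Used to
# polish the original seed read, the only contig region whose bases were
# never put to a vote; everything else already carries >= min_support votes.
polish_region <- function(contig, coverage, index, from, to,
                          min_support = 3L, max_mismatch_frac = 0.06) {
  lc <- nchar(contig)
  w_from <- max(1L, from - 25L); w_to <- min(lc, to + 25L)
  window <- substr(contig, w_from, w_to)
  codes <- .kmer_codes_cpp(window, index$k)[[1]]
  ao <- which(!is.na(codes))
  if (!length(ao)) return(list(seq = contig, coverage = coverage))
  wanted <- data.table::data.table(code = codes[ao])
  hits <- index$postings[wanted, on = "code", nomatch = NULL]
  if (nrow(hits) == 0) return(list(seq = contig, coverage = coverage))
  lookup <- data.table::data.table(code = codes[ao], aoff = ao)
  hits <- lookup[hits, on = "code", allow.cartesian = TRUE]
  off <- (w_from - 1L + hits$aoff) - hits$pos + 1L
  cand <- tibble(read = hits$read, strand = hits$strand, offset = off) %>% distinct()
  cand$oseq <- ifelse(cand$strand == "+", index$seqs[cand$read], index$rc_seqs[cand$read])
  lr <- nchar(cand$oseq)
  ov_from <- pmax(1L, cand$offset); ov_to <- pmin(lc, cand$offset + lr - 1L)
  keep <- ov_to >= ov_from
  cand <- cand[keep, , drop = FALSE]
  ov_from <- ov_from[keep]; ov_to <- ov_to[keep]
  mm <- .count_mismatches_cpp(
    substring(cand$oseq, ov_from - cand$offset + 1L, ov_to - cand$offset + 1L),
    substring(contig, ov_from, ov_to))
  keep <- mm <= ceiling(max_mismatch_frac * (ov_to - ov_from + 1L))
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) return(list(seq = contig, coverage = coverage))
  chars <- strsplit(contig, "")[[1]]
  for (p in from:to) {
    in_read <- p - cand$offset + 1L
    sel <- in_read >= 1L & in_read <= nchar(cand$oseq)
    if (sum(sel) < min_support) next
    votes <- substring(cand$oseq[sel], in_read[sel], in_read[sel])
    tab <- sort(table(votes), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) next
    if (tab[1] <= length(votes) / 2) next
    chars[p] <- names(tab)[1]
    coverage[p] <- sum(sel)
  }
  list(seq = paste0(chars, collapse = ""), coverage = coverage)
}

#' Longest open reading frame of a contig
#'
#' Scans the three forward frames for the longest ATG-initiated reading
#' frame. If a stop codon closes it inside the sequence, `has_stop` is `TRUE`
#' and the span includes the stop codon; otherwise the longest open
#' (stop-less) ATG frame is reported, signalling that 3' walking must
#' continue. Ties prefer a closed frame, then the smallest start.
#'
#' @param seq Contig sequence.
#' @return List `cds_start`, `cds_end` (1-based inclusive, `NA` if no ATG),
#'   `has_stop`, `length` (nt, divisible by 3 when closed).
#' @examples
#' find_orf("ATGAAATAA")
#' @export
find_orf <- function(seq) {
  n <- nchar(seq)
  best <- list(cds_start = NA_integer_, cds_end = NA_integer_,
               has_stop = FALSE, length = 0L)
  if (n < 3) return(best)
  for (f in 0:2) {
    n_codons <- (n - f) %/% 3L
    if (n_codons < 1) next
    at <- seq(1L + f, by = 3L, length.out = n_codons)
    codons <- substring(seq, at, at + 2L)
    starts <- which(codons == "ATG")
    stops <- which(codons %in% STOP_CODONS)
    for (s in starts) {
      k <- findInterval(s, stops) + 1L
      if (k <= length(stops)) {
        len <- 3L * (stops[k] - s + 1L)
        closed <- TRUE
      } else {
        len <- 3L * (n_codons - s + 1L)
        closed <- FALSE
      }
      cs <- at[s]
      better <- len > best$length ||
        (len == best$length && closed && !best$has_stop) ||
        (len == best$length && closed == best$has_stop &&
           (is.na(best$cds_start) || cs < best$cds_start))
      if (better) {
        best <- list(cds_start = cs, cds_end = cs + len - 1L,
                     has_stop = closed, length = len)
      }
    }
  }
  best
}

#' Walk a seed read out to a full transcript
#'
#' Alternately extends the seed 3' then 5' by [extend_step()] until both
#' directions emit stop signals (loss of read support, which on an adequately
#' covered library happens at the transcript ends — after the coding sequence
#' and its 3' stop codon are fully covered). A completeness criterion based on
#' the current longest reading frame cannot distinguish the true start codon
#' from an internal ATG on a partial contig, so walking deliberately runs to
#' support loss instead of stopping at the first closed frame. The contig
#' is finally reported in the orientation whose longest reading frame is
#' maximal, so a seed from either strand yields the same transcript.
#' Walking is deterministic: identical library, seed and parameters give an
#' identical transcript and trace.
#'
#' @param seed_seq Seed read sequence (>= `anchor_len` nt; normally a groomed
#'   read).
#' @param index A [build_read_index()] over the groomed library.
#' @inheritParams extend_step
#' @param polish_seed After walking, re-derive the consensus over the
#'   original seed span from all overlapping reads (default `TRUE`). The
#'   seed is the only contig region whose bases were never voted on, so a
#'   sequencing error in the seed read would otherwise survive into the
#'   transcript.
#' @param max_steps Safety cap on extension steps.
#' @return Object of class `assembled_transcript`: list with `seq`,
#'   `coverage` (per-position supporting-read count; the original seed
#'   carries 1), `cds_start`, `cds_end`, `has_stop`, and `trace`, a tibble of
#'   extension steps (`step`, `direction`, `n_supporting_reads`,
#'   `bases_added`).
#' @examples
#' tx <- make_transcriptome(seed = 1)
#' lib <- groom_reads(simulate_reads(tx, 4000, error_rate = 0, seed = 2))$reads
#' idx <- build_read_index(lib)
#' seed <- lib$seq[match("pTRPL", lib$gene)]
#' at <- walk(seed, idx)
#' at$has_stop
#' @export
walk <- function(seed_seq, index, anchor_len = 25L, min_support = 3L,
                 max_mismatch = 1L, step_cap = 50L, polish_seed = TRUE,
                 max_steps = 10000L) {
  if (nchar(seed_seq) < anchor_len) abort("seed shorter than `anchor_len`")
  contig <- toupper(seed_seq)
  coverage <- rep(1L, nchar(contig))
  done3 <- FALSE; done5 <- FALSE
  trace <- list()
  step <- 0L
  while (!(done3 && done5) && step < max_steps) {
    if (!done3) {
      step <- step + 1L
      res <- extend_step(contig, index, "3prime", anchor_len, min_support,
                         max_mismatch, step_cap)
      contig <- res$seq
      coverage <- c(coverage, res$support)
      done3 <- res$stopped
      trace[[length(trace) + 1L]] <- tibble(
        step = step, direction = "3prime",
        n_supporting_reads = if (length(res$support)) max(res$support) else 0L,
        bases_added = res$bases_added)
    }
    if (!done5) {
      step <- step + 1L
      res <- extend_step(contig, index, "5prime", anchor_len, min_support,
                         max_mismatch, step_cap)
      contig <- res$seq
      coverage <- c(res$support, coverage)
      done5 <- res$stopped
      trace[[length(trace) + 1L]] <- tibble(
        step = step, direction = "5prime",
        n_supporting_reads = if (length(res$support)) max(res$support) else 0L,
        bases_added = res$bases_added)
    }
  }
  if (polish_seed) {
    added5 <- sum(vapply(trace, function(t)
      if (t$direction == "5prime") t$bases_added else 0L, integer(1)))
    res <- polish_region(contig, coverage, index,
                         from = added5 + 1L, to = added5 + nchar(seed_seq),
                         min_support = min_support)
    contig <- res$seq
    coverage <- res$coverage
  }
  # orient so the longest reading frame is maximal
  orf_f <- find_orf(contig)
  orf_r <- find_orf(revcomp(contig))
  if (orf_r$length > orf_f$length) {
    contig <- revcomp(contig)
    coverage <- rev(coverage)
    orf_f <- orf_r
  }
  structure(
    list(seq = contig, coverage = coverage, cds_start = orf_f$cds_start,
         cds_end = orf_f$cds_end, has_stop = orf_f$has_stop,
         trace = bind_rows(trace),
         params = list(anchor_len = anchor_len, min_support = min_support,
                       max_mismatch = max_mismatch, step_cap = step_cap)),
    class = "assembled_transcript"
  )
}

#' @export
print.assembled_transcript <- function(x, ...) {
  cat("<assembled_transcript> ", nchar(x$seq), " nt, CDS ",
      if (is.na(x$cds_start)) "none" else paste0(x$cds_start, "-", x$cds_end),
      if (isTRUE(x$has_stop)) " (stop found)" else " (no stop)",
      ", ", nrow(x$trace), " steps\n", sep = "")
  invisible(x)
}

#' @export
as.character.assembled_transcript <- function(x, ...) x$seq

#' @rdname walk
#' @param x An `assembled_transcript`.
#' @param ... Unused.
#' @export
glance.assembled_transcript <- function(x, ...) {
  tibble(length = nchar(x$seq), cds_start = x$cds_start, cds_end = x$cds_end,
         has_stop = x$has_stop, n_steps = nrow(x$trace),
         mean_coverage = mean(x$coverage))
}
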