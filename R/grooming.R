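#' Groom a single read by the longest high-quality run rule
#'
#' Retains the longest contiguous run of bases whose Phred quality is
#' strictly above `min_phred`; the read is kept (and by default trimmed to
#' that run) only if the run is at least `min_run` bases long. Ties between
#' equal-length runs keep the leftmost.
#'
#' @param seq Read sequence (single string).
#' @param qual Phred+33 quality string, or an integer vector of Phred scores.
#' @param min_run Minimum qualifying run length (default 80).
#' @param min_phred Exclusive Phred threshold (default 19: Phred 20 passes).
#' @param trim If `TRUE` (default) the kept read is trimmed to the qualifying
#'   run; if `FALSE` the whole read is kept when a qualifying run exists.
#' @return A one-row tibble `kept`, `seq`, `qual`, `start`, `end` (1-based
#'   inclusive span of the retained run within the original read; `NA` when
#'   rejected).
#' @examples
#' groom_read(strrep("A", 100), strrep("I", 100))
#' @export
groom_read <- function(seq, qual, min_run = 80L, min_phred = 19L, trim = TRUE) {
  if (is.numeric(qual)) qual <- phred_encode(qual)
  if (nchar(seq) != nchar(qual)) abort("`seq` and `qual` lengths differ")
  span <- .groom_spans_cpp(qual, as.integer(min_phred), as.integer(min_run))
  if (span[1, 1] == 0L) {
    return(tibble(kept = FALSE, seq = NA_character_, qual = NA_character_,
                  start = NA_integer_, end = NA_integer_))
  }
  s <- span[1, 1]; e <- span[1, 2]
  if (trim) {
    tibble(kept = TRUE, seq = substr(seq, s, e), qual = substr(qual, s, e),
           start = s, end = e)
  } else {
    tibble(kept = TRUE, seq = seq, qual = qual, start = s, end = e)
  }
}

#' Groom a read library
#'
#' Applies the longest-high-quality-run rule to every read of a library
#' tibble. Grooming is idempotent: a groomed library passes unchanged.
#' When mates are present (a `mate` column), each mate is groomed
#' independently and a surviving mate is kept even if its partner is
#' rejected; downstream walking and counting treat the library as a read
#' pool.
#'
#' @param reads Tibble with columns `seq` and `qual` (plus any others, which
#'   are carried through).
#' @inheritParams groom_read
#' @return List with `reads` (the groomed tibble, with `source_start` /
#'   `source_end` span columns) and `report`, a one-row tibble
#'   `n_input_reads`, `n_kept`, `n_trimmed`, `n_rejected`.
#' @examples
#' tx <- make_transcriptome(seed = 1)
#' lib <- simulate_reads(tx, n_pairs = 200, seed = 2)
#' groomed <- groom_reads(lib)
#' groomed$report
#' @export
groom_reads <- function(reads, min_run = 80L, min_phred = 19L, trim = TRUE) {
  stopifnot(all(c("seq", "qual") %in% names(reads)))
  spans <- .groom_spans_cpp(reads$qual, as.integer(min_phred), as.integer(min_run))
  keep <- spans[, 1] != 0L
  out <- reads[keep, , drop = FALSE]
  s <- spans[keep, 1]; e <- spans[keep, 2]
  full <- s == 1L & e == nchar(out$seq)
  if (trim) {
    out$seq <- substring(out$seq, s, e)
    out$qual <- substring(out$qual, s, e)
  }
  out$source_start <- s
  out$source_end <- e
  report <- tibble(
    n_input_reads = nrow(reads),
    n_kept = sum(keep),
    n_trimmed = sum(!full),
    n_rejected = sum(!keep)
  )
  list(reads = as_tibble(out), report = report)
}

#' Groom a FASTQ file pair on disk
#'
#' File-level wrapper around [groom_reads()]: reads one or two FASTQ files,
#' grooms every record, and writes the survivors. Mate pairing is not
#' enforced on output; a read whose mate failed survives as an unpaired read.
#'
#' @param in1,in2 Input FASTQ paths (`in2` optional).
#' @param out1,out2 Output FASTQ paths matching the inputs.
#' @inheritParams groom_read
#' @return The grooming report tibble (see [groom_reads()]), invisibly
#'   returning file paths as attributes.
#' @export
groom_fastq <- function(in1, out1, in2 = NULL, out2 = NULL,
                        min_run = 80L, min_phred = 19L, trim = TRUE) {
  g1 <- groom_reads(read_fastq(in1), min_run, min_phred, trim)
  write_fastq(g1$reads, out1)
  report <- g1$report
  if (!is.null(in2)) {
    if (is.null(out2)) abort("`out2` is required when `in2` is given")
    g2 <- groom_reads(read_fastq(in2), min_run, min_phred, trim)
    write_fastq(g2$reads, out2)
    report <- tibble(
      n_input_reads = report$n_input_reads + g2$report$n_input_reads,
      n_kept = report$n_kept + g2$report$n_kept,
      n_trimmed = report$n_trimmed + g2$report$n_trimmed,
      n_rejected = report$n_rejected + g2$report$n_rejected
    )
  }
  report
}
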