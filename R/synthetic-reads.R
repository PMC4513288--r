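#' Simulate paired short reads from the synthetic transcriptome
#'
#' Draws cDNA fragments with sampling probability proportional to
#' `copy_number x transcript length` (each transcript copy contributes
#' fragments in proportion to its length), sequences 100 nt from each fragment
#' end, and records full per-read provenance. The library is unstranded:
#' read 1 comes from either strand of the fragment with equal probability.
#' Sequencing errors are uniform single-base substitutions; realistic
#' platform error profiles are deliberately out of scope.
#'
#' Quality model `"default"` draws, per read, a logistic quality decay along
#' the read with a random midpoint, emulating the 3' quality drop that the
#' grooming stage is designed to remove (so a tunable fraction of reads fails
#' the 80-base rule); `"clean"` assigns Phred 37 everywhere.
#'
#' @param tx A `retina_transcriptome` from [make_transcriptome()].
#' @param n_pairs Number of read pairs (>= 1).
#' @param error_rate Per-base substitution probability in `[0, 0.1]`.
#' @param quality_model `"default"` or `"clean"`.
#' @param read_length Read length in nt (default 100).
#' @param fragment_mean,fragment_sd Fragment-length distribution (nt); lengths
#'   are clamped to `[read_length, transcript length]`.
#' @param seed Integer seed; same seed, same library, byte for byte.
#' @return A tibble with one row per read: `id`, `mate` (1 or 2), `seq`,
#'   `qual` (Phred+33), and provenance columns `gene`, `start` (1-based
#'   position of the read's 5'-most base on the forward transcript), `strand`
#'   (strand of the transcript the read sequence matches).
#' @examples
#' tx <- make_transcriptome(seed = 1)
#' reads <- simulate_reads(tx, n_pairs = 100, seed = 2)
#' dplyr::count(reads, gene)
#' @export
simulate_reads <- function(tx, n_pairs, error_rate = 0.01,
                           quality_model = c("default", "clean"),
                           read_length = 100L, fragment_mean = 250,
                           fragment_sd = 30, seed = NULL) {
  stopifnot(inherits(tx, "retina_transcriptome"))
  quality_model <- match.arg(quality_model)
  if (n_pairs < 1) abort("`n_pairs` must be >= 1: empty library requested")
  if (error_rate < 0 || error_rate > 0.1) abort("`error_rate` must be in [0, 0.1]")
  genes <- tx$genes
  if (any(genes$length < read_length)) abort("all transcripts must be >= read_length")

  with_seed_if(seed, {
    w <- genes$copy_number * genes$length
    gi <- sample.int(nrow(genes), n_pairs, replace = TRUE, prob = w / sum(w))
    tlen <- genes$length[gi]
    flen <- pmin(pmax(round(rnorm(n_pairs, fragment_mean, fragment_sd)), read_length), tlen)
    fs <- floor(runif(n_pairs) * (tlen - flen + 1)) + 1L
    fe <- fs + flen - 1L
    flip <- runif(n_pairs) < 0.5  # TRUE: read 1 on the reverse strand

    seqs <- genes$seq[gi]
    left <- substring(seqs, fs, fs + read_length - 1L)          # forward strand
    right <- revcomp(substring(seqs, fe - read_length + 1L, fe)) # reverse strand

    r1 <- ifelse(flip, right, left)
    r2 <- ifelse(flip, left, right)
    s1 <- ifelse(flip, "-", "+")
    start1 <- ifelse(flip, fe - read_length + 1L, fs)
    start2 <- ifelse(flip, fs, fe - read_length + 1L)

    reads <- tibble(
      id = rep(sprintf("read%07d", seq_len(n_pairs)), 2L),
      mate = rep(c(1L, 2L), each = n_pairs),
      seq = c(r1, r2),
      gene = rep(genes$gene[gi], 2L),
      start = c(start1, start2),
      strand = c(s1, ifelse(flip, "+", "-"))
    )

    if (error_rate > 0) {
      n_tot <- nrow(reads) * read_length
      hit <- which(runif(n_tot) < error_rate)
      if (length(hit)) {
        ridx <- (hit - 1L) %/% read_length + 1L
        pos <- (hit - 1L) %% read_length + 1L
        old <- substring(reads$seq[ridx], pos, pos)
        shift <- sample.int(3L, length(hit), replace = TRUE)
        bases <- c("A", "C", "G", "T")
        new <- bases[(match(old, bases) - 1L + shift) %% 4L + 1L]
        reads$seq <- .mutate_bases_cpp(reads$seq, ridx, pos, new)
      }
    }

    reads$qual <- simulate_qualities(nrow(reads), read_length, quality_model)
    reads[, c("id", "mate", "seq", "qual", "gene", "start", "strand")]
  })
}

# Per-read logistic quality decay: high plateau, random midpoint, low floor.
simulate_qualities <- function(n_reads, read_length, quality_model,
                               q_max = 38, q_floor = 12, midpoint_mean = 85,
                               midpoint_sd = 12, scale = 4, jitter_sd = 1.5) {
  if (quality_model == "clean") {
    return(rep(strrep(intToUtf8(37L + 33L), read_length), n_reads))
  }
  out <- character(n_reads)
  chunk <- 50000L
  pos <- seq_len(read_length)
  done <- 0L
  while (done < n_reads) {
    m <- min(chunk, n_reads - done)
    x0 <- rnorm(m, midpoint_mean, midpoint_sd)
    q <- q_floor + (q_max - q_floor) * stats::plogis(outer(x0, pos, `-`) / scale)
    q <- round(q + matrix(rnorm(m * read_length, 0, jitter_sd), m, read_length))
    q[q < 2] <- 2L
    q[q > 40] <- 40L
    out[(done + 1L):(done + m)] <- .phred_rows_to_ascii_cpp(matrix(as.integer(q), m, read_length))
    done <- done + m
  }
  out
}
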