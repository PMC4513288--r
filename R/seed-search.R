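#' Six-frame translation
#'
#' Translates a nucleotide sequence in all six reading frames: `+1..+3` from
#' the forward strand, `-1..-3` from the reverse complement. Stop codons are
#' rendered `*`; trailing partial codons are dropped.
#'
#' @param nt A DNA string (>= 3 nt, IUPAC letters; ambiguity codes translate
#'   to `X` where the codon is ambiguous).
#' @return Named character vector of six peptides
#'   (`"+1" "+2" "+3" "-1" "-2" "-3"`).
#' @examples
#' translate_six_frames("ATGGCC")[["+1"]]
#' @export
translate_six_frames <- function(nt) {
  if (nchar(nt) < 3) abort("`nt` must be at least 3 nt")
  check_dna_iupac(nt)
  fwd <- Biostrings::DNAString(nt)
  rev <- Biostrings::reverseComplement(fwd)
  frames <- function(x) {
    vapply(1:3, function(f) {
      n <- length(x) - f + 1L
      if (n < 3) return("")
      sub <- Biostrings::subseq(x, f, f + (n %/% 3L) * 3L - 1L)
      as.character(Biostrings::translate(sub, if.fuzzy.codon = "X"))
    }, character(1))
  }
  setNames(c(frames(fwd), frames(rev)), c("+1", "+2", "+3", "-1", "-2", "-3"))
}

check_dna_iupac <- function(nt) {
  ok <- strsplit(toupper(nt), "")[[1]] %in%
    strsplit("ACGTRYSWKMBDHVN", "")[[1]]
  if (!all(ok)) abort("non-IUPAC character in nucleotide sequence")
  invisible(nt)
}

#' Fetch a BLOSUM scoring matrix
#'
#' @param name One of `"BLOSUM45"`, `"BLOSUM62"`, `"BLOSUM80"` (lower numbers
#'   are more permissive, for low-stringency searches against distant
#'   homologs).
#' @return The integer scoring matrix.
#' @export
blosum_matrix <- function(name = c("BLOSUM62", "BLOSUM45", "BLOSUM80")) {
  name <- match.arg(name)
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  get(name, envir = env)
}

# ASCII-indexed 128x128 score lookup. Peptide mode: BLOSUM entries, with X
# and '*' forced to -4 against everything (translated frames are full of
# stops; they must never seed an alignment). Nucleotide mode: +1/-1.
score_lut <- function(matrix = NULL, mode = c("peptide", "nucleotide"),
                      match = 1L, mismatch = -1L, xstar_penalty = -4L) {
  mode <- match.arg(mode)
  lut <- base::matrix(xstar_penalty, 128, 128)
  if (mode == "nucleotide") {
    lut[, ] <- mismatch
    for (b in utf8ToInt("ACGT") + 1L) lut[b, b] <- match
    return(lut)
  }
  stopifnot(is.matrix(matrix))
  letters_m <- rownames(matrix)
  for (a in letters_m) {
    for (b in letters_m) {
      lut[utf8ToInt(a) + 1L, utf8ToInt(b) + 1L] <- matrix[a, b]
    }
  }
  x <- utf8ToInt("X") + 1L; s <- utf8ToInt("*") + 1L
  lut[x, ] <- xstar_penalty; lut[, x] <- xstar_penalty
  lut[s, ] <- xstar_penalty; lut[, s] <- xstar_penalty
  lut
}

#' Best ungapped local segment score
#'
#' Maximum-scoring contiguous (gap-free) segment over every relative offset
#' of the two sequences, i.e. an ungapped local alignment. An all-negative
#' comparison scores 0 with an empty span. Ties are broken toward the
#' smallest query start, then the smallest subject start.
#'
#' @param query,subject Peptide strings (or nucleotide strings with
#'   `mode = "nucleotide"`).
#' @param matrix BLOSUM matrix name or matrix (peptide mode).
#' @param mode `"peptide"` or `"nucleotide"` (+1/-1 scoring).
#' @return One-row tibble `score`, `query_start`, `query_end`,
#'   `subject_start`, `subject_end` (1-based inclusive; 0 when empty).
#' @examples
#' local_ungapped_score("WLLLVMAGKR", "WLLLVMAGKR")
#' @export
local_ungapped_score <- function(query, subject, matrix = "BLOSUM62",
                                 mode = c("peptide", "nucleotide")) {
  mode <- match.arg(mode)
  if (nchar(query) == 0 || nchar(subject) == 0) abort("empty sequence")
  lut <- if (mode == "peptide") {
    if (is.character(matrix)) matrix <- blosum_matrix(matrix)
    score_lut(matrix, "peptide")
  } else {
    score_lut(mode = "nucleotide")
  }
  v <- .local_segment_cpp(toupper(query), toupper(subject), lut)
  tibble(score = v[1], query_start = v[2], query_end = v[3],
         subject_start = v[4], subject_end = v[5])
}

#' Low-stringency seed search of a read library
#'
#' Scores a query sequence against every read of the library by ungapped
#' local alignment — in peptide mode against all six translation frames of
#' each read under a BLOSUM matrix, in nucleotide mode against both strands
#' with +1/-1 scoring — and reports each read whose best score reaches the
#' threshold, once, in its best frame.
#'
#' When `min_score` is `NULL` it is calibrated from a permutation null: a
#' sample of reads is base-shuffled (destroying any real homology while
#' keeping composition), scored the same way, and the threshold set just
#' above the `null_quantile` quantile of the null scores.
#'
#' @param reads Tibble with `id` and `seq` (a groomed library).
#' @param query Query peptide (peptide mode) or DNA (nucleotide mode).
#' @param mode `"peptide"` or `"nucleotide"`.
#' @param matrix BLOSUM matrix name, peptide mode only.
#' @param min_score Integer score threshold; `NULL` to null-calibrate.
#' @param null_quantile,null_sample Calibration settings.
#' @param seed Seed for the calibration shuffle.
#' @return Tibble `read_id`, `mode`, `frame` (`+1..+3`/`-1..-3` in peptide
#'   mode; `+`/`-` strand in nucleotide mode), `score`, `query_start`,
#'   `query_end`, `read_start`, `read_end` — sorted by score descending then
#'   `read_id`; spans are in frame coordinates (peptide positions for peptide
#'   mode). The chosen threshold is attached as attribute `min_score`.
#' @examples
#' tx <- make_transcriptome(seed = 1)
#' lib <- groom_reads(simulate_reads(tx, 300, seed = 2))$reads
#' hits <- find_seed_reads(lib, tx$queries$peptide[1], min_score = 40)
#' head(hits)
#' @export
find_seed_reads <- function(reads, query, mode = c("peptide", "nucleotide"),
                            matrix = "BLOSUM62", min_score = NULL,
                            null_quantile = 0.999, null_sample = 2000L,
                            seed = 1L) {
  mode <- match.arg(mode)
  empty <- tibble(read_id = character(), mode = character(), frame = character(),
                  score = integer(), query_start = integer(), query_end = integer(),
                  read_start = integer(), read_end = integer())
  if (nrow(reads) == 0) {
    warn("empty read library: no seed hits possible")
    return(empty)
  }
  if (mode == "peptide" && is.character(matrix)) matrix <- blosum_matrix(matrix)
  scores <- score_reads(reads$seq, query, mode, matrix)

  if (is.null(min_score)) {
    idx <- with_seed_if(seed, sample.int(nrow(reads), min(null_sample, nrow(reads))))
    shuffled <- with_seed_if(seed + 1L, vapply(reads$seq[idx], function(s) {
      paste0(sample(strsplit(s, "")[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE))
    null_best <- score_reads(shuffled, query, mode, matrix)$best_score
    min_score <- floor(quantile(null_best, null_quantile, names = FALSE)) + 1L
  }

  hits <- scores %>%
    mutate(read_id = reads$id) %>%
    filter(.data$best_score >= min_score) %>%
    mutate(mode = mode) %>%
    select(read_id = "read_id", mode = "mode", frame = "frame",
           score = "best_score", query_start = "query_start",
           query_end = "query_end", read_start = "read_start",
           read_end = "read_end") %>%
    arrange(desc(.data$score), .data$read_id)
  attr(hits, "min_score") <- min_score
  hits
}

# best ungapped local score of `query` vs each read (over frames/strands)
score_reads <- function(seqs, query, mode, matrix) {
  if (mode == "peptide") {
    lut <- score_lut(matrix, "peptide")
    x <- Biostrings::DNAStringSet(seqs)
    rc <- Biostrings::reverseComplement(x)
    frame_of <- function(set, f) {
      w <- Biostrings::width(set) - f + 1L
      ok <- w >= 3L
      out <- rep("", length(set))
      if (any(ok)) {
        sub <- Biostrings::subseq(set[ok], start = f,
                                  width = (w[ok] %/% 3L) * 3L)
        out[ok] <- as.character(Biostrings::translate(sub, if.fuzzy.codon = "X"))
      }
      out
    }
    frames <- c(lapply(1:3, function(f) frame_of(x, f)),
                lapply(1:3, function(f) frame_of(rc, f)))
    labels <- c("+1", "+2", "+3", "-1", "-2", "-3")
    mats <- lapply(frames, function(p) .local_segment_many_cpp(toupper(query), p, lut))
  } else {
    lut <- score_lut(mode = "nucleotide")
    labels <- c("+", "-")
    mats <- list(
      .local_segment_many_cpp(toupper(query), seqs, lut),
      .local_segment_many_cpp(toupper(query), revcomp(seqs), lut)
    )
  }
  score_mat <- do.call(cbind, lapply(mats, function(m) m[, 1]))
  best_f <- max.col(score_mat, ties.method = "first")
  n <- length(seqs)
  pick <- cbind(seq_len(n), best_f)
  get_col <- function(j) {
    vapply(seq_len(n), function(i) mats[[best_f[i]]][i, j], integer(1))
  }
  tibble(
    frame = labels[best_f],
    best_score = score_mat[pick],
    query_start = get_col(2), query_end = get_col(3),
    read_start = get_col(4), read_end = get_col(5)
  )
}
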