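# Independent brute-force oracles used to validate the fast implementations.
# These deliberately re-derive every quantity with the simplest possible
# algorithm, sharing no code with the package internals they check.

# longest run of Phred > min_phred by explicit quadratic scan over all
# (start, end) windows; leftmost longest; NULL if best run < min_run
groom_oracle_quadratic <- function(phred, min_run = 80L, min_phred = 19L) {
  n <- length(phred)
  best <- c(0L, 0L, 0L)  # len, start, end
  for (s in seq_len(n)) {
    for (e in s:n) {
      if (all(phred[s:e] > min_phred)) {
        len <- e - s + 1L
        if (len > best[1]) best <- c(len, s, e)
      } else {
        break
      }
    }
  }
  if (best[1] >= min_run) list(start = best[2], end = best[3]) else NULL
}

# rle-based independent check of the same rule (linear, different algorithm)
groom_oracle_rle <- function(phred, min_run = 80L, min_phred = 19L) {
  r <- rle(phred > min_phred)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values)
  if (!length(ok)) return(NULL)
  lens <- r$lengths[ok]
  i <- ok[which.max(lens)]  # which.max takes the first: leftmost tie
  if (max(lens) < min_run) return(NULL)
  list(start = starts[i], end = ends[i])
}

phred_encode_q <- function(q) intToUtf8(as.integer(q) + 33L)

revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, ""), function(ch)
    paste(rev(ch), collapse = ""), character(1)))
}

# max identical bases over all ungapped offsets, both strands, pure R
identity_oracle <- function(read, transcript) {
  best <- 0L
  tr <- strsplit(transcript, "")[[1]]
  for (r in c(read, revcomp_chr(read))) {
    rd <- strsplit(r, "")[[1]]
    lr <- length(rd); lt <- length(tr)
    for (d in (-(lr - 1L)):(lt - 1L)) {
      j <- seq_len(lr)
      tpos <- j + d
      sel <- tpos >= 1L & tpos <= lt
      m <- sum(rd[sel] == tr[tpos[sel]])
      if (m > best) best <- m
    }
  }
  best
}

# best ungapped local segment by enumerating every (qstart, sstart, len)
local_score_oracle <- function(query, subject, score_fun) {
  q <- strsplit(query, "")[[1]]; s <- strsplit(subject, "")[[1]]
  best <- 0L
  for (qs in seq_along(q)) {
    for (ss in seq_along(s)) {
      tot <- 0L
      maxlen <- min(length(q) - qs, length(s) - ss) + 1L
      for (l in seq_len(maxlen)) {
        tot <- tot + score_fun(q[qs + l - 1L], s[ss + l - 1L])
        if (tot > best) best <- tot
      }
    }
  }
  best
}

# longest ATG-initiated frame by direct enumeration of every ATG position;
# ties prefer a closed frame, then the smallest start
orf_oracle <- function(seq) {
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  best <- list(cds_start = NA_integer_, cds_end = NA_integer_,
               has_stop = FALSE, length = 0L)
  for (p in seq_len(max(0L, n - 2L))) {
    if (substr(seq, p, p + 2L) != "ATG") next
    i <- 1L
    closed <- FALSE
    while (p + 3L * i + 2L <= n) {
      codon <- substr(seq, p + 3L * i, p + 3L * i + 2L)
      if (codon %in% stops) { closed <- TRUE; break }
      i <- i + 1L
    }
    len <- if (closed) 3L * (i + 1L) else 3L * ((n - p + 1L) %/% 3L)
    better <- len > best$length ||
      (len == best$length && closed && !best$has_stop) ||
      (len == best$length && closed == best$has_stop && p < best$cds_start)
    if (better) best <- list(cds_start = p, cds_end = p + len - 1L,
                             has_stop = closed, length = len)
  }
  best
}

# shared small fixture, built once per test run
fixture_tx <- local({
  tx <- NULL
  function() {
    if (is.null(tx)) tx <<- make_transcriptome(seed = 101)
    tx
  }
})
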