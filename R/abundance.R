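#' Best ungapped identity of a read against a transcript
#'
#' Maximum count of identical bases over every ungapped placement of the read
#' on the transcript, on both strands. Placements overhanging a transcript
#' end are scored over the overlap only, so the attainable identity is capped
#' at the overlap length.
#'
#' @param read_seq Read sequence.
#' @param transcript_seq Transcript (or CDS) sequence.
#' @return Integer identity count.
#' @examples
#' best_identity("ACGTACGT", "TTTACGTACGTTTT")
#' @export
best_identity <- function(read_seq, transcript_seq) {
  check_dna(read_seq, "read_seq"); check_dna(transcript_seq, "transcript_seq")
  .best_identity_cpp(toupper(read_seq), toupper(transcript_seq))
}

#' Count reads attributable to each gene by the identical-nucleotide criterion
#'
#' A read is scored as derived from a gene when its best ungapped placement
#' on the gene's reading frame (CDS) reaches at least `min_identity`
#' identical bases on either strand — by default 90 of a 100-nt read,
#' substitution-only. A read can satisfy the criterion for several genes and
#' then counts for each (the criterion is per gene, not an assignment);
#' `multi_gene` in the attached diagnostics reports how often that happened.
#'
#' Internally each transcript is screened with an exact k-mer prefilter that
#' is provably equivalent to the exhaustive scan for `min_identity` at least
#' 90 on reads up to 100 nt (any qualifying placement must share an exact
#' 9-mer); when shorter guarantees are impossible the code falls back to the
#' exhaustive scan.
#'
#' @param transcripts Tibble with `gene` and `cds` columns (or named
#'   character vector of CDS sequences).
#' @param reads Groomed read tibble with `seq` (or character vector).
#' @param min_identity Minimum identical bases, in (50, 100] (default 90).
#' @return Tibble `gene`, `read_count`, with a `diagnostics` attribute
#'   (tibble `n_reads`, `multi_gene`).
#' @examples
#' tx <- make_transcriptome(seed = 1)
#' lib <- groom_reads(simulate_reads(tx, 500, seed = 2))$reads
#' count_reads(tx$genes, lib)
#' @export
count_reads <- function(transcripts, reads, min_identity = 90L) {
  if (min_identity <= 50 || min_identity > 100)
    abort("`min_identity` must be in (50, 100]")
  if (is.character(transcripts)) {
    transcripts <- tibble(gene = names(transcripts), cds = unname(transcripts))
  }
  stopifnot(all(c("gene", "cds") %in% names(transcripts)))
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  seqs <- toupper(seqs)
  max_len <- if (length(seqs)) max(nchar(seqs)) else 0L
  # largest k with a guaranteed exact seed under min_identity
  k_guaranteed <- if (max_len > min_identity) {
    floor(min_identity / (max_len - min_identity + 1))
  } else {
    min_identity
  }
  k <- min(15L, k_guaranteed)
  hit_mat <- vapply(seq_len(nrow(transcripts)), function(i) {
    cds <- toupper(transcripts$cds[i])
    if (k >= 7L) {
      .reads_match_cpp(seqs, cds, as.integer(min_identity), as.integer(k))
    } else {
      vapply(seqs, function(s) .best_identity_cpp(s, cds) >= min_identity,
             logical(1), USE.NAMES = FALSE)
    }
  }, logical(length(seqs)))
  hit_mat <- matrix(hit_mat, ncol = nrow(transcripts))
  out <- tibble(gene = transcripts$gene, read_count = colSums(hit_mat))
  attr(out, "diagnostics") <- tibble(
    n_reads = length(seqs),
    multi_gene = sum(rowSums(hit_mat) > 1)
  )
  out
}

#' Length-normalized abundance relative to a reference gene
#'
#' Divides each gene's read count by its reading-frame length and expresses
#' the result relative to the reference gene's value, the convention used
#' for transcriptome read-count abundance estimates.
#'
#' @param counts Tibble `gene`, `read_count` (from [count_reads()]).
#' @param lengths Tibble with `gene` and `cds_length` (e.g.
#'   `make_transcriptome()$truth`), or a named numeric vector.
#' @param reference Reference gene name (default `"actin"`); its read count
#'   must be positive.
#' @return Tibble of class `abundance_table`: `gene`, `read_count`,
#'   `frame_length`, `per_length`, `rel_to_reference`.
#' @examples
#' counts <- tibble::tibble(gene = c("A", "actin"), read_count = c(500, 100))
#' lens <- c(A = 2000, actin = 1000)
#' relative_abundance(counts, lens)
#' @export
relative_abundance <- function(counts, lengths, reference = "actin") {
  if (is.numeric(lengths)) {
    lengths <- tibble(gene = names(lengths), cds_length = unname(lengths))
  }
  out <- counts %>%
    left_join(lengths[, c("gene", "cds_length")], by = "gene") %>%
    rename(frame_length = "cds_length") %>%
    mutate(per_length = .data$read_count / .data$frame_length)
  if (!reference %in% out$gene) abort(paste0("reference gene ", reference, " not present"))
  ref <- out$per_length[out$gene == reference]
  if (ref == 0) abort("reference gene has zero reads: relative abundance undefined")
  out <- out %>% mutate(rel_to_reference = .data$per_length / ref)
  class(out) <- c("abundance_table", class(out))
  attr(out, "reference") <- reference
  out
}

#' One-call read-count abundance estimate
#'
#' Convenience wrapper: count reads against each gene's CDS and normalize.
#'
#' @param transcripts Tibble with `gene`, `cds` (and `cds_length`, otherwise
#'   computed from `cds`).
#' @inheritParams count_reads
#' @inheritParams relative_abundance
#' @return An `abundance_table` (see [relative_abundance()]).
#' @export
abundance_table <- function(transcripts, reads, reference = "actin",
                            min_identity = 90L) {
  counts <- count_reads(transcripts, reads, min_identity)
  if (!"cds_length" %in% names(transcripts)) {
    transcripts$cds_length <- nchar(transcripts$cds)
  }
  relative_abundance(counts, transcripts[, c("gene", "cds_length")], reference)
}
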