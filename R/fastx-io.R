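#' Read and write FASTQ/FASTA as tibbles
#'
#' Thin wrappers around [Biostrings] I/O that move sequence data between plain
#' files and the tibble representation used throughout the package: one row
#' per read with columns `id`, `seq` and (FASTQ only) `qual`, qualities
#' encoded Phred+33.
#'
#' @param path File path.
#' @param reads A tibble with columns `id`, `seq` and, for FASTQ, `qual`.
#' @return `read_fastq()` and `read_fasta()` return a tibble; the writers
#'   return `path` invisibly.
#' @examples
#' tf <- tempfile(fileext = ".fq")
#' write_fastq(tibble::tibble(id = "r1", seq = "ACGT", qual = "IIII"), tf)
#' read_fastq(tf)
#' @name fastx_io
NULL

#' @rdname fastx_io
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(
    id = names(x),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities)
  )
}

#' @rdname fastx_io
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' @rdname fastx_io
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(id = names(x), seq = as.character(x))
}

#' @rdname fastx_io
#' @export
write_fasta <- function(reads, path) {
  stopifnot(all(c("id", "seq") %in% names(reads)))
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
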