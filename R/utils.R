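# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed when `seed` is non-NULL, leaving the
# caller's RNG state untouched; otherwise use the current RNG stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Deterministic per-stage child seeds fanned out from one master seed, so each
# pipeline stage is independently reproducible. Kept strictly below 2^31.
child_seed <- function(seed, stage) {
  offsets <- c(
    transcriptome = 11L, reads = 23L, qpcr = 37L, erg = 53L,
    walk = 71L, seed_search = 89L, mc = 97L
  )
  if (!stage %in% names(offsets)) abort(paste0("unknown pipeline stage: ", stage))
  as.integer((as.numeric(seed) * 48271 + offsets[[stage]]) %% 2147483399) + 1L
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

check_dna <- function(x, arg = "seq") {
  if (!is.character(x) || anyNA(x)) abort(paste0("`", arg, "` must be a character vector of DNA"))
  bad <- grepl("[^ACGTNacgtn]", x)
  if (any(bad)) abort(paste0("`", arg, "` contains non-IUPAC characters"))
  invisible(toupper(x))
}

# Phred+33 string -> integer vector (and back)
phred_decode <- function(qual) utf8ToInt(qual) - 33L
phred_encode <- function(q) intToUtf8(as.integer(q) + 33L)

STOP_CODONS <- c("TAA", "TAG", "TGA")
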