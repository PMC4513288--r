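#' Default composition of the synthetic retina
#'
#' Per-gene relative transcript abundances (arbitrary copy-number units) and
#' sequence dimensions for the seven-gene toy retina: two green-opsin paralogs
#' (`pGO1`, `pGO2`), a UV opsin (`pUVO`), the two light-activated channel
#' homologs (`pTRP`, `pTRPL`) and two housekeeping references (`actin`,
#' `GAPDH`). The copy-number defaults encode the composition reported for the
#' nocturnal-insect retina this generator emulates: pGO1:pGO2 = 100:1,
#' pTRPL:pTRP = 10:1, pUVO at the geometric middle of its reported 25-100 fold
#' deficit below pGO1, and actin as the abundant reference. GAPDH is not
#' reported as a point value anywhere; its default is a plausible housekeeping
#' level and no actin-free quantity depends on it.
#'
#' @return A tibble with columns `gene`, `copy_number`, `cds_length`,
#'   `utr5_length`, `utr3_length`.
#' @export
retina_composition <- function() {
  tribble(
    ~gene,   ~copy_number, ~cds_length, ~utr5_length, ~utr3_length,
    "pGO1",  100,          1131,        60,           120,
    "pGO2",  1,            1131,        60,           120,
    "pUVO",  2,            1131,        60,           120,
    "pTRP",  1,            1650,        60,           120,
    "pTRPL", 10,           1650,        60,           120,
    "actin", 100,          1131,        60,           120,
    "GAPDH", 30,           1002,        60,           120
  )
}

#' Generator settings for the synthetic retina transcriptome
#'
#' @param composition Tibble as returned by [retina_composition()]; copy
#'   numbers must be positive and CDS lengths divisible by 3.
#' @param paralog_identity Nucleotide identity between the two green-opsin
#'   paralogs, in percent (70-100). `pGO2` is derived from `pGO1` by random
#'   codon-safe substitution down to this identity.
#' @param paralog_pair Character vector of length 2 naming the paralog pair.
#' @param query_identity Amino-acid identity (fraction) of the bundled
#'   "related species" query peptides used to seed low-stringency searches.
#' @return A list of class `retina_config`.
#' @export
retina_config <- function(composition = retina_composition(),
                          paralog_identity = 85,
                          paralog_pair = c("pGO1", "pGO2"),
                          query_identity = 0.70) {
  if (nrow(composition) == 0) abort("`composition` must contain at least one gene")
  if (any(composition$copy_number <= 0)) abort("composition copy numbers must be > 0")
  if (any(composition$cds_length %% 3 != 0)) abort("cds lengths must be divisible by 3")
  if (any(composition$utr5_length < 0) || any(composition$utr3_length < 0))
    abort("UTR lengths must be >= 0")
  if (paralog_identity < 70 || paralog_identity > 100)
    abort("`paralog_identity` must be in [70, 100] percent")
  structure(
    list(composition = composition, paralog_identity = paralog_identity,
         paralog_pair = paralog_pair, query_identity = query_identity),
    class = "retina_config"
  )
}

# random CDS: ATG + uniform non-stop codons + one stop codon
random_cds <- function(cds_length) {
  n_codons <- cds_length / 3L
  codons <- apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                              c("T", "C", "A", "G")), 1, paste0, collapse = "")
  sense <- setdiff(codons, STOP_CODONS)
  body <- sample(sense, n_codons - 2L, replace = TRUE)
  paste0("ATG", paste0(body, collapse = ""), sample(STOP_CODONS, 1L))
}

# random UTR with no ATG anywhere (so the CDS stays the dominant open frame)
random_utr <- function(len) {
  if (len == 0) return("")
  s <- paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  while (grepl("ATG", s, fixed = TRUE)) s <- sub("ATG", "ACG", s, fixed = TRUE)
  s
}

# Derive a paralog from `cds` at the requested nucleotide identity (percent),
# substituting single bases while never touching the start/stop codons and
# never creating an in-frame stop. Substitutions are stratified — one per
# equal-width block — so differences are spread evenly: at 85% identity every
# 100-nt window then carries well over 10 differences, and reads from one
# paralog can never reach 90/100 identity against the other.
mutate_cds_to_identity <- function(cds, identity_pct) {
  len <- nchar(cds)
  n_mut <- round((1 - identity_pct / 100) * len)
  if (n_mut == 0) return(cds)
  eligible <- setdiff(seq_len(len), c(1:3, (len - 2):len))
  bounds <- round(seq(0, len, length.out = n_mut + 1))
  pos <- vapply(seq_len(n_mut), function(i) {
    in_block <- eligible[eligible > bounds[i] & eligible <= bounds[i + 1]]
    if (!length(in_block)) NA_integer_ else if (length(in_block) == 1) in_block
    else sample(in_block, 1L)
  }, integer(1))
  pos <- pos[!is.na(pos)]
  chars <- strsplit(cds, "")[[1]]
  for (p in pos) {
    repeat {
      new <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
      codon_i <- (p - 1L) %/% 3L
      codon <- chars[(codon_i * 3L + 1L):(codon_i * 3L + 3L)]
      codon[(p - 1L) %% 3L + 1L] <- new
      if (!paste0(codon, collapse = "") %in% STOP_CODONS) {
        chars[p] <- new
        break
      }
    }
  }
  paste0(chars, collapse = "")
}

# Degrade a peptide to the requested amino-acid identity (fraction); used for
# the synthetic "published homolog" query sequences.
degrade_peptide <- function(pep, identity) {
  aa <- strsplit(pep, "")[[1]]
  keep <- aa != "*"
  n_mut <- round((1 - identity) * sum(keep))
  pos <- sample(which(keep)[-1], n_mut)  # keep initial M
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (p in pos) aa[p] <- sample(setdiff(alphabet, aa[p]), 1L)
  paste0(aa, collapse = "")
}

#' Generate the ground-truthed synthetic retina transcriptome
#'
#' Builds one transcript per configured gene (5' UTR + CDS + 3' UTR), with the
#' green-opsin paralog pair sharing a configured nucleotide identity, and
#' returns the sequences together with a truth table of copy numbers and a set
#' of divergent "related species" query peptides for seeding low-stringency
#' searches. Every CDS starts with ATG, ends with a stop codon, and contains
#' no internal in-frame stop.
#'
#' @param config A [retina_config()].
#' @param seed Integer seed for reproducibility; identical seeds give
#'   byte-identical output.
#' @return An object of class `retina_transcriptome`: a list with
#'   * `genes`: tibble `gene`, `seq`, `cds`, `cds_start`, `cds_end`,
#'     `length`, `copy_number`;
#'   * `truth`: tibble of configured copy numbers and lengths;
#'   * `queries`: tibble `family`, `source_gene`, `peptide` of degraded
#'     homolog peptides (one per gene family);
#'   * `config`: the configuration used.
#' @examples
#' tx <- make_transcriptome(seed = 1)
#' tx$truth
#' @export
make_transcriptome <- function(config = retina_config(), seed = NULL) {
  stopifnot(inherits(config, "retina_config"))
  with_seed_if(seed, {
    comp <- config$composition
    pair <- config$paralog_pair
    cds <- setNames(vector("character", nrow(comp)), comp$gene)
    for (g in comp$gene) {
      len <- comp$cds_length[comp$gene == g]
      if (g == pair[2]) next
      cds[[g]] <- random_cds(len)
    }
    if (all(pair %in% comp$gene)) {
      if (comp$cds_length[comp$gene == pair[1]] != comp$cds_length[comp$gene == pair[2]])
        abort("paralog pair must share cds_length")
      cds[[pair[2]]] <- mutate_cds_to_identity(cds[[pair[1]]], config$paralog_identity)
    }
    genes <- comp %>%
      mutate(
        utr5 = vapply(.data$utr5_length, random_utr, character(1)),
        cds = unname(cds[.data$gene]),
        utr3 = vapply(.data$utr3_length, random_utr, character(1)),
        seq = paste0(.data$utr5, .data$cds, .data$utr3),
        cds_start = .data$utr5_length + 1L,
        cds_end = .data$utr5_length + .data$cds_length,
        length = nchar(.data$seq)
      ) %>%
      select("gene", "seq", "cds", "cds_start", "cds_end", "length", "copy_number")

    # one degraded homolog query per family (paralogs share one query)
    fam <- tibble(
      family = c("green_opsin", "uv_opsin", "trp", "trpl", "actin", "gapdh"),
      source_gene = c(pair[1], "pUVO", "pTRP", "pTRPL", "actin", "GAPDH")
    ) %>% filter(.data$source_gene %in% genes$gene)
    fam$peptide <- vapply(fam$source_gene, function(g) {
      pep <- as.character(Biostrings::translate(Biostrings::DNAString(genes$cds[genes$gene == g])))
      degrade_peptide(sub("\\*$", "", pep), config$query_identity)
    }, character(1))

    truth <- genes %>%
      mutate(cds_length = .data$cds_end - .data$cds_start + 1L) %>%
      select("gene", "copy_number", "cds_length", "length")

    structure(list(genes = genes, truth = truth, queries = fam, config = config),
              class = "retina_transcriptome")
  })
}

#' @export
print.retina_transcriptome <- function(x, ...) {
  cat("<retina_transcriptome> ", nrow(x$genes), " genes, paralog identity ",
      x$config$paralog_identity, "%\n", sep = "")
  print(x$truth)
  invisible(x)
}
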