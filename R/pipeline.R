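#' Configuration for a full in-silico replication run
#'
#' Desk-scale problem sizes for the end-to-end pipeline: enough reads that
#' the minor green-opsin paralog is still deeply covered, but small enough
#' that the whole replication runs in minutes on one CPU.
#'
#' @param n_pairs Read pairs to simulate (default 200,000).
#' @param error_rate,quality_model Passed to [simulate_reads()].
#' @param walk_reads Groomed reads indexed for walking (default 60,000).
#' @param search_reads Groomed reads scored during seed search
#'   (default 10,000).
#' @param min_identity Identical-base criterion for read counting
#'   (default 90).
#' @param run_assembly Assemble transcripts by seed search + walking and
#'   count against the assembled CDS (default `TRUE`); when `FALSE`, counting
#'   uses the generator's true CDS directly.
#' @param erg_days Named list of recording-day vectors per scenario.
#' @return List of class `replication_config`.
#' @export
replication_config <- function(n_pairs = 200000L, error_rate = 0.01,
                               quality_model = "default",
                               walk_reads = 60000L, search_reads = 10000L,
                               min_identity = 90L, run_assembly = TRUE,
                               erg_days = list(
                                 pGO1 = c(2L, 5L, 7L, 14L, 19L),
                                 pTRP = c(7L, 14L, 21L),
                                 pTRPL = c(7L, 14L, 21L),
                                 combined_day16 = c(6L, 14L, 21L)
                               )) {
  structure(
    list(n_pairs = n_pairs, error_rate = error_rate,
         quality_model = quality_model, walk_reads = walk_reads,
         search_reads = search_reads, min_identity = min_identity,
         run_assembly = run_assembly, erg_days = erg_days),
    class = "replication_config"
  )
}

# Assemble one gene family: seed-search the library with the family's
# degraded homolog query, walk the best seed; optionally mask reads matching
# an already-assembled paralog and walk the best remaining seed. Masking is
# fractional (90% of each read's length against the whole assembled
# transcript), so trimmed reads and reads straddling the CDS boundary cannot
# slip past it.
assemble_family <- function(search_lib, walk_index, query, mask_seq = NULL,
                            mask_frac = 0.9, ...) {
  hits <- find_seed_reads(search_lib, query, mode = "peptide",
                          matrix = "BLOSUM45", min_score = NULL)
  if (nrow(hits) == 0) return(NULL)
  if (!is.null(mask_seq)) {
    seed_seqs <- search_lib$seq[match(hits$read_id, search_lib$id)]
    masked <- vapply(seed_seqs, function(s) {
      .best_identity_cpp(s, mask_seq) >= mask_frac * nchar(s)
    }, logical(1), USE.NAMES = FALSE)
    hits <- hits[!masked, , drop = FALSE]
    if (nrow(hits) == 0) return(NULL)
  }
  seed <- search_lib$seq[match(hits$read_id[1], search_lib$id)]
  walk(seed, walk_index, ...)
}

#' Run the full in-silico replication
#'
#' Generates the synthetic retina, simulates and grooms a read library,
#' re-assembles the transcripts by low-stringency seed search plus
#' transcriptome walking, estimates relative abundance by both the
#' read-count and the qPCR route, quantifies every RNAi scenario's knockdown
#' from simulated plates, and analyses simulated ERG cohorts — comparing
#' every estimate against the generator's truth. Deterministic given `seed`;
#' each stage derives its own child seed so stages can be reproduced
#' independently.
#'
#' @param config A [replication_config()].
#' @param seed Master integer seed.
#' @param out_dir Optional directory; when given, stage outputs (FASTA,
#'   groomed FASTQ sample, TSV tables, JSON report) are written there.
#' @return Object of class `replication_report` with sections `assembly`,
#'   `abundance`, `knockdown`, `erg`, `grooming`, and `provenance`.
#' @examples
#' \donttest{
#' rep <- run_replication(replication_config(n_pairs = 20000L), seed = 1)
#' rep$abundance
#' }
#' @export
run_replication <- function(config = replication_config(), seed = 1L,
                            out_dir = NULL) {
  stopifnot(inherits(config, "replication_config"))
  tx <- make_transcriptome(seed = child_seed(seed, "transcriptome"))
  reads <- simulate_reads(tx, config$n_pairs, config$error_rate,
                          config$quality_model, seed = child_seed(seed, "reads"))
  groomed <- groom_reads(reads)
  lib <- groomed$reads

  # --- targeted assembly ---------------------------------------------------
  assembly <- NULL
  assembled_cds <- NULL
  if (config$run_assembly) {
    idx_lib <- with_seed_if(child_seed(seed, "walk"), {
      lib[sample.int(nrow(lib), min(config$walk_reads, nrow(lib))), ]
    })
    search_lib <- with_seed_if(child_seed(seed, "seed_search"), {
      idx_lib[sample.int(nrow(idx_lib), min(config$search_reads, nrow(idx_lib))), ]
    })
    walk_index <- build_read_index(idx_lib)
    q <- tx$queries
    asm <- list()
    go1 <- assemble_family(search_lib, walk_index,
                           q$peptide[q$family == "green_opsin"])
    if (!is.null(go1)) {
      asm$green_1 <- go1
      go2 <- assemble_family(search_lib, walk_index,
                             q$peptide[q$family == "green_opsin"],
                             mask_seq = go1$seq)
      if (!is.null(go2)) asm$green_2 <- go2
    }
    for (fam in c("uv_opsin", "trp", "trpl", "actin", "gapdh")) {
      a <- assemble_family(search_lib, walk_index, q$peptide[q$family == fam])
      if (!is.null(a)) asm[[fam]] <- a
    }
    # label: the abundant green paralog is paralog 1, by definition
    fam_gene <- c(uv_opsin = "pUVO", trp = "pTRP", trpl = "pTRPL",
                  actin = "actin", gapdh = "GAPDH")
    labels <- character(length(asm))
    names(labels) <- names(asm)
    if (!is.null(asm$green_1) && !is.null(asm$green_2)) {
      n1 <- sum(.reads_match_cpp(head(lib$seq, 20000L),
                                 substr(asm$green_1$seq, asm$green_1$cds_start, asm$green_1$cds_end),
                                 as.integer(config$min_identity), 9L))
      n2 <- sum(.reads_match_cpp(head(lib$seq, 20000L),
                                 substr(asm$green_2$seq, asm$green_2$cds_start, asm$green_2$cds_end),
                                 as.integer(config$min_identity), 9L))
      labels[c("green_1", "green_2")] <- if (n1 >= n2) c("pGO1", "pGO2") else c("pGO2", "pGO1")
    } else if (!is.null(asm$green_1)) {
      labels["green_1"] <- "pGO1"
    }
    labels[names(fam_gene)[names(fam_gene) %in% names(asm)]] <-
      fam_gene[names(fam_gene) %in% names(asm)]

    assembly <- purrr::map_dfr(names(asm), function(nm) {
      a <- asm[[nm]]
      gene <- labels[[nm]]
      truth_seq <- tx$genes$seq[tx$genes$gene == gene]
      tibble(
        gene = gene,
        assembled_length = nchar(a$seq),
        cds_complete = isTRUE(a$has_stop),
        cds_length = if (is.na(a$cds_start)) NA_integer_ else a$cds_end - a$cds_start + 1L,
        identity_to_truth = .best_identity_cpp(a$seq, truth_seq) / nchar(a$seq)
      )
    })
    assembled_cds <- tibble(
      gene = unname(labels),
      cds = vapply(names(asm), function(nm) {
        a <- asm[[nm]]
        if (is.na(a$cds_start)) a$seq else substr(a$seq, a$cds_start, a$cds_end)
      }, character(1))
    )
  }

  # --- abundance, two routes ----------------------------------------------
  cds_tbl <- if (!is.null(assembled_cds) &&
                 all(c("pGO1", "pGO2", "pTRP", "pTRPL", "actin") %in% assembled_cds$gene)) {
    assembled_cds
  } else {
    tx$genes[, c("gene", "cds")]
  }
  ab_counts <- abundance_table(cds_tbl, lib, reference = "actin",
                               min_identity = config$min_identity)
  control_plate <- simulate_qpcr_plate(tx$truth, scenario_identity(),
                                       groups = "control",
                                       seed = child_seed(seed, "qpcr"))
  ab_qpcr <- qpcr_abundance(control_plate)
  truth_rel <- tx$truth %>%
    mutate(truth_rel = .data$copy_number /
             .data$copy_number[.data$gene == "actin"]) %>%
    select("gene", "truth_rel")
  abundance <- ab_counts %>%
    select("gene", readcount_rel = "rel_to_reference") %>%
    left_join(ab_qpcr %>% rename(qpcr_rel = "rel_to_reference"), by = "gene") %>%
    left_join(truth_rel, by = "gene") %>%
    mutate(
      log2_err_readcount = log2(.data$readcount_rel / .data$truth_rel),
      log2_err_qpcr = log2(.data$qpcr_rel / .data$truth_rel)
    )

  # --- knockdown quantitation ----------------------------------------------
  scenarios <- default_scenarios()
  knockdown <- purrr::imap_dfr(scenarios, function(sc, nm) {
    plate <- simulate_qpcr_plate(tx$truth, sc,
                                 seed = child_seed(seed, "qpcr") + match(nm, names(scenarios)))
    kd <- knockdown_table(plate) %>% filter(.data$group == "treated", !.data$is_reference)
    truth_f <- scenario_factors(sc, tx$truth$gene)
    kd %>%
      mutate(scenario = nm, day = sc$day, truth = unname(truth_f[.data$gene]),
             log2_err = log2(.data$ratio_vs_control / .data$truth)) %>%
      select("scenario", "day", "gene", "ratio_vs_control", "sd", "n",
             "truth", "log2_err")
  })

  # --- ERG cohorts ----------------------------------------------------------
  erg <- purrr::imap(config$erg_days, function(days, nm) {
    sc <- scenarios[[nm]]
    cohort <- simulate_erg_cohort(sc, days = days,
                                  seed = child_seed(seed, "erg") + match(nm, names(config$erg_days)))
    attenuation_timecourse(cohort)
  })

  report <- structure(
    list(grooming = groomed$report, assembly = assembly, abundance = abundance,
         knockdown = knockdown, erg = erg,
         provenance = list(seed = seed, config_hash = hash(config),
                           package_version = as.character(utils::packageVersion("retinawalk")))),
    class = "replication_report"
  )
  if (!is.null(out_dir)) write_report(report, tx, out_dir)
  report
}

write_report <- function(report, tx, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(tibble(id = tx$genes$gene, seq = tx$genes$seq),
              file.path(out_dir, "transcripts.fa"))
  for (nm in c("abundance", "knockdown")) {
    utils::write.table(report[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  json <- list(
    grooming = report$grooming, assembly = report$assembly,
    abundance = report$abundance, knockdown = report$knockdown,
    erg = lapply(report$erg, function(x) as.data.frame(x)),
    provenance = report$provenance
  )
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.replication_report <- function(x, ...) {
  cat("<replication_report> seed ", x$provenance$seed, "\n", sep = "")
  cat("\nGrooming:\n"); print(x$grooming)
  if (!is.null(x$assembly)) { cat("\nAssembly:\n"); print(x$assembly) }
  cat("\nRelative abundance (vs actin):\n"); print(x$abundance)
  cat("\nKnockdown (treated vs untreated control):\n"); print(x$knockdown)
  cat("\nERG time courses: ", paste(names(x$erg), collapse = ", "), "\n", sep = "")
  invisible(x)
}
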