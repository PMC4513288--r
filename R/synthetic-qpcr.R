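#' Primer amplification efficiencies for the synthetic assays
#'
#' Fractional per-cycle amplification efficiencies `E` (a perfect doubling is
#' `E = 1`) for each gene's primer pair, as determined from dilution standard
#' curves in the emulated study. Used both by the plate simulator (to place
#' Cq values) and by the comparative-Cq quantitation (to correct them).
#'
#' @return Tibble with columns `gene`, `efficiency`.
#' @export
qpcr_efficiencies <- function() {
  tribble(
    ~gene,    ~efficiency,
    "pGO1",   0.8750,
    "pUVO",   0.9453,
    "pGO2",   0.9626,
    "pTRP",   0.9007,
    "pTRPL",  0.9319,
    "actin",  0.8560,
    "GAPDH",  0.8951
  )
}

eff_vector <- function(efficiencies, genes) {
  e <- if (is.data.frame(efficiencies)) {
    setNames(efficiencies$efficiency, efficiencies$gene)
  } else {
    efficiencies
  }
  missing <- setdiff(genes, names(e))
  if (length(missing))
    abort(paste0("missing amplification efficiency for: ", paste(missing, collapse = ", ")))
  if (any(e[genes] <= 0.5) || any(e[genes] > 1.1))
    abort("efficiencies must lie in (0.5, 1.1]")
  e[genes]
}

#' Simulate a qPCR plate under an RNAi scenario
#'
#' Inverts the efficiency-corrected comparative-Cq model as a generator: for a
#' gene with efficiency `E` and relative template quantity `q`,
#' `Cq = cq_at_unit - log(q) / log(1 + E) + noise`. Control animals carry the
#' configured copy numbers; treated animals carry scenario-modified
#' quantities; saline animals occasionally show sham inflation. Between-animal
#' biological variability is multiplicative log-normal on quantity.
#'
#' @param truth Truth tibble with `gene` and `copy_number` (e.g.
#'   `make_transcriptome()$truth`).
#' @param scenario An [rnai_scenario].
#' @param efficiencies Tibble or named vector of fractional efficiencies in
#'   (0.5, 1.1]; every gene in `truth` must be present.
#' @param n_animals Biological replicates per group (default 3).
#' @param n_replicates Technical (well) replicates per animal x gene
#'   (default 3, the usual triplicate protocol).
#' @param noise_sd Technical Cq noise, cycles (default 0.2).
#' @param animal_sd_log2 Between-animal biological variability, sd of
#'   log2 quantity (default 0.2).
#' @param cq_at_unit Cq of one quantity unit; an instrument constant shared by
#'   all assays on the plate (default 36).
#' @param groups Which of `control`, `saline`, `treated` to simulate.
#' @param seed Integer seed.
#' @return Tibble `gene`, `group`, `animal`, `replicate`, `cq`.
#' @examples
#' tx <- make_transcriptome(seed = 1)
#' plate <- simulate_qpcr_plate(tx$truth, scenario_pgo1(), seed = 2)
#' head(plate)
#' @export
simulate_qpcr_plate <- function(truth, scenario, efficiencies = qpcr_efficiencies(),
                                n_animals = 3L, n_replicates = 3L, noise_sd = 0.2,
                                animal_sd_log2 = 0.2, cq_at_unit = 36,
                                groups = c("control", "saline", "treated"),
                                seed = NULL) {
  stopifnot(inherits(scenario, "rnai_scenario"))
  if (n_replicates < 1) abort("`n_replicates` must be >= 1")
  genes <- truth$gene
  e <- eff_vector(efficiencies, genes)
  treat_f <- scenario_factors(scenario, genes)

  with_seed_if(seed, {
    grid <- tidyr::expand_grid(group = groups, animal_i = seq_len(n_animals), gene = genes) %>%
      left_join(truth[, c("gene", "copy_number")], by = "gene") %>%
      mutate(
        factor = case_when(
          .data$group == "treated" ~ unname(treat_f[.data$gene]),
          .data$group == "saline" ~ ifelse(
            runif(n()) < scenario$sham_prob,
            runif(n(), scenario$sham_range[1], scenario$sham_range[2]), 1),
          TRUE ~ 1
        ),
        quantity = .data$copy_number * .data$factor *
          2^rnorm(n(), 0, animal_sd_log2),
        animal = paste0(.data$group, "_a", .data$animal_i)
      )
    plate <- grid[rep(seq_len(nrow(grid)), each = n_replicates), ] %>%
      group_by(.data$group, .data$animal, .data$gene) %>%
      mutate(replicate = row_number()) %>%
      ungroup() %>%
      mutate(cq = cq_at_unit - log(.data$quantity) / log(1 + e[.data$gene]) +
               rnorm(n(), 0, noise_sd)) %>%
      select("gene", "group", "animal", "replicate", "cq")
    plate
  })
}

#' Simulate a noiseless-to-noisy dilution standard curve
#'
#' @param efficiency True fractional amplification efficiency.
#' @param dilutions Relative template quantities (default five 10-fold steps).
#' @param cq_at_max Cq of the most concentrated point.
#' @param noise_sd Cq noise in cycles.
#' @param seed Integer seed.
#' @return Tibble `dilution`, `log10_dilution`, `cq`.
#' @export
simulate_dilution_series <- function(efficiency, dilutions = 10^(0:-4),
                                     cq_at_max = 18, noise_sd = 0, seed = NULL) {
  stopifnot(efficiency > 0, efficiency <= 1.1)
  with_seed_if(seed, {
    l10 <- log10(dilutions)
    cq <- cq_at_max - (l10 - max(l10)) / log10(1 + efficiency) + rnorm(length(l10), 0, noise_sd)
    tibble(dilution = dilutions, log10_dilution = l10, cq = cq)
  })
}
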