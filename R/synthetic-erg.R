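#' Protein turnover constants linking mRNA knockdown to functional loss
#'
#' After dsRNA injection the targeted mRNA is assumed to drop immediately to
#' its scenario residual, while the already-synthesized protein pool decays
#' toward the new steady state with first-order kinetics, optionally after a
#' dead-time lag. The functional-protein fraction at `t` days is
#' `f(t) = r + (1 - r) * 2^(-(t - lag)/half_life)` for `t > lag`, else 1.
#' The ERG amplitude of a responding animal scales with `f(t)` (identity link;
#' for multi-target injections the per-gene fractions multiply).
#'
#' Defaults were solved from the emulated study's printed attenuation figures
#' at the default non-responder rate: the opsin effect is fast (maximal by a
#' week), the TRP effect very slow (weak even after three weeks), and the
#' TRPL effect delayed but then fast (strong only after three weeks).
#'
#' @return Tibble `gene`, `half_life_days`, `lag_days`.
#' @export
protein_kinetics <- function() {
  tribble(
    ~gene,    ~half_life_days, ~lag_days,
    "pGO1",   2.40,            0,
    "pGO2",   2.40,            0,
    "pUVO",   2.40,            0,
    "pTRP",   27.75,           0,
    "pTRPL",  3.41,            7
  )
}

#' Functional-protein fraction implied by a scenario at a given day
#'
#' @param scenario An [rnai_scenario]; only its `target_genes` contribute.
#' @param day Days post-injection.
#' @param kinetics Tibble as [protein_kinetics()].
#' @return Numeric fraction in (0, 1]; the product over target genes.
#' @export
functional_fraction <- function(scenario, day, kinetics = protein_kinetics()) {
  stopifnot(inherits(scenario, "rnai_scenario"))
  f <- 1
  for (g in scenario$target_genes) {
    r <- if (g %in% names(scenario$knockdown)) scenario$knockdown[[g]] else 1
    k <- kinetics[kinetics$gene == g, ]
    if (nrow(k) == 0) abort(paste0("no protein kinetics for gene ", g))
    t_eff <- day - k$lag_days
    fg <- if (t_eff <= 0) 1
          else if (k$half_life_days <= 0) r
          else r + (1 - r) * 2^(-t_eff / k$half_life_days)
    f <- f * fg
  }
  f
}

#' ERG cohort design settings
#'
#' @param n_control,n_treated Animals per group; each contributes
#'   `eyes_per_animal` retinas at each recording position.
#' @param eyes_per_animal Usually 2.
#' @param positions Tibble `position`, `baseline_mv`: mean flash-response
#'   amplitude of an untreated retina at each recording position. The default
#'   encodes the strong positional dependence of the compound-eye ERG:
#'   transient responses at the top (1), very small signals in the center (2),
#'   larger responses at the bottom (3).
#' @param nonresponder_prob Probability an injected animal shows control-level
#'   responses in both eyes (default 2/16: typically one, occasionally up to
#'   three, per batch of eight).
#' @param animal_cv Between-animal amplitude coefficient of variation.
#' @param noise_sd Trace noise sd per sweep (mV); recordings average
#'   `n_sweeps` sweeps.
#' @param n_sweeps Sweeps averaged per recording (default 10).
#' @param sample_rate_hz,baseline_s,flash_s Trace geometry: sampling rate,
#'   pre-flash baseline window and flash window lengths (seconds).
#' @return List of class `erg_cohort_config`.
#' @export
erg_cohort_config <- function(n_control = 15L, n_treated = 8L, eyes_per_animal = 2L,
                              positions = tibble(position = 1:3,
                                                 baseline_mv = c(3, 0.5, 5)),
                              nonresponder_prob = 2 / 16, animal_cv = 0.15,
                              noise_sd = 0.3, n_sweeps = 10L,
                              sample_rate_hz = 100, baseline_s = 0.5, flash_s = 1) {
  if (nonresponder_prob < 0 || nonresponder_prob > 1)
    abort("`nonresponder_prob` must be in [0, 1]")
  if (any(positions$baseline_mv <= 0)) abort("baseline amplitudes must be > 0")
  structure(
    list(n_control = n_control, n_treated = n_treated,
         eyes_per_animal = eyes_per_animal, positions = positions,
         nonresponder_prob = nonresponder_prob, animal_cv = animal_cv,
         noise_sd = noise_sd, n_sweeps = n_sweeps,
         sample_rate_hz = sample_rate_hz, baseline_s = baseline_s,
         flash_s = flash_s),
    class = "erg_cohort_config"
  )
}

#' Simulate one averaged ERG trace
#'
#' A pre-flash baseline at 0 mV followed by a negative-going square response
#' of the given amplitude during the flash, with white noise scaled for the
#' number of averaged sweeps.
#'
#' @param amplitude_mv True response amplitude (mV, magnitude).
#' @param config An [erg_cohort_config()] supplying trace geometry and noise.
#' @param seed Integer seed.
#' @return Tibble `time_s`, `voltage_mv`.
#' @export
simulate_erg_trace <- function(amplitude_mv, config = erg_cohort_config(), seed = NULL) {
  with_seed_if(seed, {
    nb <- round(config$baseline_s * config$sample_rate_hz)
    nf <- round(config$flash_s * config$sample_rate_hz)
    v <- c(rep(0, nb), rep(-amplitude_mv, nf)) +
      rnorm(nb + nf, 0, config$noise_sd / sqrt(config$n_sweeps))
    tibble(time_s = (seq_len(nb + nf) - 1) / config$sample_rate_hz, voltage_mv = v)
  })
}

#' Simulate an ERG cohort under an RNAi scenario
#'
#' One shared batch of uninjected control animals (recorded at day 0) plus an
#' independent batch of injected animals for every requested day, following
#' the emulated study's design of fresh batches per recording day. Each
#' animal contributes both eyes at every recording position. Non-responder
#' animals are drawn per animal (both eyes unaffected). The measured
#' amplitude equals the baseline-window/flash-window estimate
#' (see [erg_amplitude()]) of the underlying noisy averaged trace.
#'
#' @param scenario An [rnai_scenario]; `scenario_identity()` gives an
#'   untreated-equivalent "treated" group.
#' @param config An [erg_cohort_config()].
#' @param days Integer vector of post-injection recording days.
#' @param kinetics Protein turnover table, see [protein_kinetics()].
#' @param include_saline Also simulate a saline-injected batch per day
#'   (no ERG effect).
#' @param seed Integer seed.
#' @return Tibble `group`, `animal`, `eye`, `position`, `day`,
#'   `amplitude_mv`, plus the truth columns `true_amplitude_mv` and
#'   `nonresponder`.
#' @examples
#' erg <- simulate_erg_cohort(scenario_pgo1(), days = 7, seed = 1)
#' dplyr::count(erg, group, day)
#' @export
simulate_erg_cohort <- function(scenario, config = erg_cohort_config(),
                                days = c(2L, 5L, 7L, 14L, 21L),
                                kinetics = protein_kinetics(),
                                include_saline = FALSE, seed = NULL) {
  stopifnot(inherits(config, "erg_cohort_config"))
  with_seed_if(seed, {
    batches <- list(
      tibble(group = "control", day = 0L,
             animal_i = seq_len(config$n_control), fraction = 1, injected = FALSE)
    )
    for (d in days) {
      fr <- functional_fraction(scenario, d, kinetics)
      batches[[length(batches) + 1L]] <-
        tibble(group = "treated", day = as.integer(d),
               animal_i = seq_len(config$n_treated), fraction = fr, injected = TRUE)
      if (include_saline) {
        batches[[length(batches) + 1L]] <-
          tibble(group = "saline", day = as.integer(d),
                 animal_i = seq_len(config$n_treated), fraction = 1, injected = TRUE)
      }
    }
    animals <- bind_rows(batches) %>%
      mutate(
        animal = paste0(.data$group, "_d", .data$day, "_a", .data$animal_i),
        nonresponder = .data$injected & runif(n()) < config$nonresponder_prob,
        animal_factor = exp(rnorm(n(), 0, config$animal_cv) - config$animal_cv^2 / 2),
        eff_fraction = ifelse(.data$nonresponder, 1, .data$fraction)
      )

    rec <- tidyr::expand_grid(
      animals %>% select("group", "day", "animal", "animal_factor",
                         "eff_fraction", "nonresponder"),
      eye = c("L", "R")[seq_len(config$eyes_per_animal)],
      position = config$positions$position
    ) %>%
      left_join(config$positions, by = "position") %>%
      mutate(true_amplitude_mv = .data$baseline_mv * .data$animal_factor * .data$eff_fraction)

    # measured amplitude: difference of flash-window and baseline-window means
    # of the averaged trace, without materializing every trace
    nb <- round(config$baseline_s * config$sample_rate_hz)
    nf <- round(config$flash_s * config$sample_rate_hz)
    sd_eff <- config$noise_sd / sqrt(config$n_sweeps) * sqrt(1 / nb + 1 / nf)
    rec %>%
      mutate(amplitude_mv = abs(.data$true_amplitude_mv + rnorm(n(), 0, sd_eff))) %>%
      select("group", "animal", "eye", "position", "day",
             "amplitude_mv", "true_amplitude_mv", "nonresponder")
  })
}
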