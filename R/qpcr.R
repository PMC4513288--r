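#' Fit a qPCR dilution standard curve
#'
#' Least-squares line `Cq = a + slope * log10(dilution)` through a serial
#' dilution series; the amplification efficiency follows as
#' `E = 10^(-1/slope) - 1` (a perfect doubling gives slope -3.32193 and
#' `E = 1`).
#'
#' @param data Tibble with `cq` and either `log10_dilution` or `dilution`.
#' @param gene Optional assay label carried into the result.
#' @return Object of class `standard_curve` with elements `gene`, `slope`,
#'   `intercept`, `efficiency`, `r2` and the underlying `lm` fit. `tidy()`,
#'   `glance()` and `autoplot()` methods are provided.
#' @examples
#' sc <- fit_standard_curve(simulate_dilution_series(0.875))
#' glance(sc)
#' @export
fit_standard_curve <- function(data, gene = NULL) {
  if (!"log10_dilution" %in% names(data)) {
    if (!"dilution" %in% names(data)) abort("need `dilution` or `log10_dilution`")
    data$log10_dilution <- log10(data$dilution)
  }
  if (length(unique(data$log10_dilution)) < 3)
    abort("need at least 3 distinct dilution points")
  fit <- lm(cq ~ log10_dilution, data = data)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope == 0) abort("singular standard-curve fit")
  structure(
    list(gene = gene, slope = slope, intercept = unname(coef(fit)[1]),
         efficiency = 10^(-1 / slope) - 1,
         r2 = {
           ss_tot <- sum((data$cq - mean(data$cq))^2)
           if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
         },
         model = fit, data = data),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("<standard_curve>", if (!is.null(x$gene)) x$gene else "", "\n",
      "  slope ", signif(x$slope, 6), "  E = ", signif(100 * x$efficiency, 4),
      "%  r2 = ", signif(x$r2, 4), "\n", sep = "")
  invisible(x)
}

#' @rdname fit_standard_curve
#' @param x A `standard_curve`.
#' @param ... Unused.
#' @export
tidy.standard_curve <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @rdname fit_standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble(gene = x$gene %||% NA_character_, slope = x$slope,
         efficiency = x$efficiency, efficiency_pct = 100 * x$efficiency,
         r2 = x$r2, n = nrow(x$data))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Efficiency-corrected comparative-Cq relative quantity
#'
#' The comparative-Cq model with per-assay efficiency correction and
#' multi-reference normalization: with `dCq = mean Cq(baseline) - mean
#' Cq(group)` per gene,
#' \deqn{ratio = (1+E_t)^{dCq_t} / \mathrm{geomean}_r\,(1+E_r)^{dCq_r}}
#' over reference genes `r`. Replicate Cq values are averaged per gene and
#' group before exponentiation. Shifting every Cq of a group by a constant
#' leaves the ratio unchanged; the geometric mean over references is the
#' standard aggregation for multi-reference normalization.
#'
#' @param plate Tibble `gene`, `group`, `cq` (replicate rows; extra columns
#'   ignored).
#' @param target Target gene name.
#' @param references Character vector of reference genes (default actin and
#'   GAPDH).
#' @param efficiencies Named vector or tibble of fractional efficiencies.
#' @param group Group to quantify.
#' @param baseline_group Baseline (default `"control"`).
#' @return The ratio (numeric scalar): target abundance in `group` relative
#'   to `baseline_group`, reference-normalized.
#' @examples
#' plate <- tibble::tibble(
#'   gene = rep(c("t", "ref"), each = 2),
#'   group = rep(c("control", "treated"), 2),
#'   cq = c(20, 23, 20, 20))
#' relative_quantity(plate, "t", "ref", c(t = 1, ref = 1), "treated")
#' @export
relative_quantity <- function(plate, target, references, efficiencies,
                              group, baseline_group = "control") {
  genes <- c(target, references)
  e <- eff_vector(efficiencies, genes)
  for (grp in c(group, baseline_group)) {
    missing <- setdiff(genes, plate$gene[plate$group == grp])
    if (length(missing))
      abort(paste0("group ", grp, " lacks genes: ", paste(missing, collapse = ", ")))
  }
  mean_cq <- function(g, grp) mean(plate$cq[plate$gene == g & plate$group == grp])
  dcq <- vapply(genes, function(g) mean_cq(g, baseline_group) - mean_cq(g, group),
                numeric(1))
  num <- (1 + e[target])^dcq[target]
  ref_factors <- (1 + e[references])^dcq[references]
  unname(num / exp(mean(log(ref_factors))))
}

#' Knockdown table: per-gene ratios vs untreated control
#'
#' Quantifies every target gene in every non-baseline group of a plate by the
#' efficiency-corrected comparative-Cq model, with biological dispersion:
#' replicate Cq values are first averaged within gene x animal, each animal
#' is quantified against the pooled baseline, and the per-animal ratios are
#' summarized as mean and sd (`n` animals). Reference genes are reported
#' with ratio 1 by construction.
#'
#' @param plate Tibble `gene`, `group`, `animal`, `replicate`, `cq`.
#' @param efficiencies Named vector or tibble of fractional efficiencies.
#' @param references Reference genes (default `c("actin", "GAPDH")`).
#' @param baseline_group Untreated baseline group (default `"control"`).
#' @param targets Genes to quantify; default all non-reference genes.
#' @return Tibble of class `knockdown_table`: `gene`, `group`,
#'   `ratio_vs_control`, `sd`, `n`, `is_reference`.
#' @examples
#' tx <- make_transcriptome(seed = 1)
#' plate <- simulate_qpcr_plate(tx$truth, scenario_ptrpl(), seed = 2)
#' knockdown_table(plate)
#' @export
knockdown_table <- function(plate, efficiencies = qpcr_efficiencies(),
                            references = c("actin", "GAPDH"),
                            baseline_group = "control", targets = NULL) {
  if (!baseline_group %in% plate$group) abort("baseline group missing from plate")
  targets <- targets %||% setdiff(unique(plate$gene), references)
  groups <- setdiff(unique(plate$group), baseline_group)
  genes <- c(targets, references)
  e <- eff_vector(efficiencies, genes)

  base_cq <- plate %>%
    filter(.data$group == baseline_group, .data$gene %in% genes) %>%
    group_by(.data$gene) %>%
    summarise(cq0 = mean(.data$cq), .groups = "drop")
  cq0 <- setNames(base_cq$cq0, base_cq$gene)

  per_animal <- plate %>%
    filter(.data$group %in% groups, .data$gene %in% genes) %>%
    group_by(.data$group, .data$animal, .data$gene) %>%
    summarise(cq = mean(.data$cq), .groups = "drop") %>%
    mutate(
      dcq = cq0[.data$gene] - .data$cq,
      factor = (1 + e[.data$gene])^.data$dcq
    )

  ref_norm <- per_animal %>%
    filter(.data$gene %in% references) %>%
    group_by(.data$group, .data$animal) %>%
    summarise(norm = exp(mean(log(.data$factor))), .groups = "drop")

  res <- per_animal %>%
    filter(.data$gene %in% targets) %>%
    left_join(ref_norm, by = c("group", "animal")) %>%
    mutate(ratio = .data$factor / .data$norm) %>%
    group_by(.data$gene, .data$group) %>%
    summarise(ratio_vs_control = mean(.data$ratio), sd = sd(.data$ratio),
              n = n(), .groups = "drop") %>%
    mutate(is_reference = FALSE)

  refs <- tidyr::expand_grid(gene = references, group = groups) %>%
    mutate(ratio_vs_control = 1, sd = NA_real_,
           n = length(unique(plate$animal[plate$group %in% groups])),
           is_reference = TRUE)
  out <- bind_rows(res, refs) %>% arrange(.data$group, .data$gene)
  class(out) <- c("knockdown_table", class(out))
  out
}

#' qPCR route to relative transcript abundance
#'
#' Estimates per-gene abundance relative to a reference gene directly from
#' control-group Cq values: each gene's quantity is back-calculated as
#' `(1+E)^(cq_at_unit - Cq)` and expressed relative to the reference. This
#' mirrors comparing quantification-cycle numbers across assays on one
#' instrument and assumes a shared single-threshold calibration constant
#' `cq_at_unit` (the Cq of one quantity unit), which must match the plate's
#' acquisition settings.
#'
#' @param plate Tibble `gene`, `group`, `cq`.
#' @param efficiencies Named vector or tibble of fractional efficiencies.
#' @param reference Reference gene (default `"actin"`).
#' @param group Group to use (default `"control"`).
#' @param cq_at_unit Instrument calibration constant (default 36, the plate
#'   simulator's default).
#' @return Tibble `gene`, `rel_to_reference`.
#' @export
qpcr_abundance <- function(plate, efficiencies = qpcr_efficiencies(),
                           reference = "actin", group = "control",
                           cq_at_unit = 36) {
  sub <- plate %>% filter(.data$group == !!group)
  genes <- unique(sub$gene)
  e <- eff_vector(efficiencies, genes)
  q <- sub %>%
    group_by(.data$gene) %>%
    summarise(cq = mean(.data$cq), .groups = "drop") %>%
    mutate(quantity = (1 + e[.data$gene])^(cq_at_unit - .data$cq))
  if (!reference %in% q$gene) abort("reference gene missing")
  q %>%
    mutate(rel_to_reference = .data$quantity / .data$quantity[.data$gene == reference]) %>%
    select("gene", "rel_to_reference")
}
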