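#' RNAi knockdown scenarios
#'
#' An `rnai_scenario` describes how a dsRNA injection changes per-gene mRNA
#' levels relative to untreated controls: residual fractions for silenced
#' genes (the target and any co-silenced close paralog), multiplicative
#' off-target factors for cross-upregulated genes, and the range of the
#' occasional saline-injection inflation. The bundled constructors encode the
#' knockdown outcomes of the emulated study:
#'
#' * [scenario_pgo1()]: green-opsin-1 dsRNA silences both green paralogs
#'   (residuals 0.012 and 0.0013) and leaves the UV opsin essentially
#'   untouched (1.06).
#' * [scenario_ptrp()]: TRP dsRNA leaves pTRP at 0.16 of control while pTRPL
#'   rises to 1.51 (compensatory cross-upregulation).
#' * [scenario_ptrpl()]: TRPL dsRNA leaves pTRPL at 0.09 while pTRP rises to
#'   1.7.
#' * [scenario_combined()]: both channel dsRNAs together; residuals depend on
#'   the sampling day (day 7: pTRP 0.084, pTRPL 0.063; day 16: pTRP 0.057,
#'   pTRPL 0.028).
#'
#' @param target_genes Character vector of genes the dsRNA targets.
#' @param knockdown Named numeric vector of residual mRNA fractions in (0, 1]
#'   for silenced genes (targets and co-silenced paralogs).
#' @param off_target Named numeric vector of multiplicative factors (> 0) for
#'   non-targeted genes; genes not listed are unchanged.
#' @param sham_range Length-2 numeric range of the multiplicative inflation a
#'   saline sham injection can cause; each animal x gene draws from this range
#'   with probability `sham_prob`, otherwise 1.
#' @param sham_prob Probability a saline-injected animal x gene shows the
#'   inflation at all ("sometimes, not consistently").
#' @param day Days post-injection the scenario describes.
#' @param label Scenario name used in reports.
#' @return An object of class `rnai_scenario`.
#' @examples
#' scenario_pgo1()
#' @name rnai_scenario
NULL

#' @rdname rnai_scenario
#' @export
rnai_scenario <- function(target_genes, knockdown, off_target = numeric(),
                          sham_range = c(1, 2), sham_prob = 0.5,
                          day = 21L, label = paste(target_genes, collapse = "+")) {
  if (any(knockdown <= 0) || any(knockdown > 1))
    abort("knockdown residual fractions must lie in (0, 1]")
  if (length(off_target) && any(off_target <= 0))
    abort("off-target factors must be > 0")
  if (any(sham_range <= 0) || sham_prob < 0 || sham_prob > 1)
    abort("invalid sham settings")
  structure(
    list(target_genes = target_genes, knockdown = knockdown,
         off_target = off_target, sham_range = sham_range,
         sham_prob = sham_prob, day = as.integer(day), label = label),
    class = "rnai_scenario"
  )
}

#' @rdname rnai_scenario
#' @export
scenario_pgo1 <- function(day = 21L) {
  rnai_scenario("pGO1",
                knockdown = c(pGO1 = 0.012, pGO2 = 0.0013),
                off_target = c(pUVO = 1.06),
                day = day, label = "pGO1")
}

#' @rdname rnai_scenario
#' @export
scenario_ptrp <- function(day = 21L) {
  rnai_scenario("pTRP",
                knockdown = c(pTRP = 0.16),
                off_target = c(pTRPL = 1.51),
                day = day, label = "pTRP")
}

#' @rdname rnai_scenario
#' @export
scenario_ptrpl <- function(day = 21L) {
  rnai_scenario("pTRPL",
                knockdown = c(pTRPL = 0.09),
                off_target = c(pTRP = 1.7),
                day = day, label = "pTRPL")
}

#' @rdname rnai_scenario
#' @export
scenario_combined <- function(day = 16L) {
  kd <- if (day <= 11) c(pTRP = 0.084, pTRPL = 0.063) else c(pTRP = 0.057, pTRPL = 0.028)
  rnai_scenario(c("pTRP", "pTRPL"), knockdown = kd, day = day, label = "pTRP+pTRPL")
}

#' @rdname rnai_scenario
#' @export
scenario_identity <- function(day = 21L) {
  rnai_scenario(character(0), knockdown = setNames(numeric(0), character(0)),
                sham_prob = 0, day = day, label = "identity")
}

#' Default scenario set mirroring the emulated study design
#' @return Named list of [rnai_scenario] objects.
#' @export
default_scenarios <- function() {
  list(
    pGO1 = scenario_pgo1(),
    pTRP = scenario_ptrp(),
    pTRPL = scenario_ptrpl(),
    combined_day16 = scenario_combined(day = 16L)
  )
}

# multiplicative truth factor the scenario applies to each gene (treated group)
scenario_factors <- function(scenario, genes) {
  f <- setNames(rep(1, length(genes)), genes)
  kd <- scenario$knockdown[names(scenario$knockdown) %in% genes]
  ot <- scenario$off_target[names(scenario$off_target) %in% genes]
  f[names(kd)] <- kd
  f[names(ot)] <- ot
  f
}

#' @export
print.rnai_scenario <- function(x, ...) {
  cat("<rnai_scenario> ", x$label, " (day ", x$day, ")\n", sep = "")
  if (length(x$knockdown)) {
    cat("  residual:", paste0(names(x$knockdown), "=", x$knockdown, collapse = ", "), "\n")
  }
  if (length(x$off_target)) {
    cat("  off-target:", paste0(names(x$off_target), "=", x$off_target, collapse = ", "), "\n")
  }
  invisible(x)
}
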