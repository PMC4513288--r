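#' Flash-response amplitude of an ERG trace
#'
#' Amplitude measured relative to the initial baseline: the absolute
#' difference between the mean voltage during the flash window and the mean
#' voltage during the pre-flash baseline window.
#'
#' @param trace Tibble `time_s`, `voltage_mv` (e.g. [simulate_erg_trace()]),
#'   or a plain numeric voltage vector with `time_s` implied by `sample_rate_hz`.
#' @param baseline_window,flash_window Length-2 numeric `[from, to)` windows
#'   in seconds; must not overlap and must contain at least one sample each.
#' @param sample_rate_hz Sampling rate, used only for vector input.
#' @return Amplitude in mV (non-negative scalar).
#' @examples
#' erg_amplitude(simulate_erg_trace(5, seed = 1))
#' @export
erg_amplitude <- function(trace, baseline_window = c(0, 0.5),
                          flash_window = c(0.5, 1.5), sample_rate_hz = 100) {
  if (is.numeric(trace)) {
    trace <- tibble(time_s = (seq_along(trace) - 1) / sample_rate_hz,
                    voltage_mv = trace)
  }
  if (max(baseline_window[1], flash_window[1]) < min(baseline_window[2], flash_window[2]))
    abort("baseline and flash windows overlap")
  in_win <- function(w) trace$time_s >= w[1] & trace$time_s < w[2]
  b <- trace$voltage_mv[in_win(baseline_window)]
  f <- trace$voltage_mv[in_win(flash_window)]
  if (!length(b) || !length(f)) abort("empty baseline or flash window")
  abs(mean(f) - mean(b))
}

# exact null counts of the U statistic: number of arrangements of n1 + n2
# ranks with U = 0..n1*n2 (recursion on whether the largest rank is an x)
u_null_counts <- function(n1, n2, memo = new.env(parent = emptyenv())) {
  key <- paste(n1, n2)
  if (!is.null(memo[[key]])) return(memo[[key]])
  res <- if (n1 == 0 || n2 == 0) {
    1
  } else {
    a <- u_null_counts(n1 - 1L, n2, memo)  # largest rank is an x: adds n2 to U
    b <- u_null_counts(n1, n2 - 1L, memo)  # largest rank is a y
    total <- n1 * n2
    av <- numeric(total + 1); av[seq_along(a) + n2] <- a
    bv <- numeric(total + 1); bv[seq_along(b)] <- b
    av + bv
  }
  memo[[key]] <- res
  res
}

#' Mann-Whitney U test (two-tailed)
#'
#' Rank-based comparison of two independent samples. The statistic is
#' `U = #\{(i,j): x_i > y_j\}` (ties counted 1/2). For tie-free samples with
#' `n1 + n2 <= 20` the two-tailed p-value is exact:
#' `P(|U - n1 n2 / 2| >= |u - n1 n2 / 2|)` under the permutation null,
#' computed from the full null distribution. Otherwise a tie-corrected
#' normal approximation with continuity correction is used.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact branch;
#'   default `NULL` chooses by the rule above. Exact with ties is an error.
#' @return Object of class `mwu_test`: `u`, `p`, `n1`, `n2`, `method`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney_u <- function(x, y, exact = NULL) {
  if (!length(x) || !length(y)) abort("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # = #(x > y) + ties/2
  has_ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- if (is.null(exact)) (n1 + n2 <= 20 && !has_ties) else exact
  if (use_exact && has_ties) abort("exact p-value is not defined with ties")
  if (use_exact) {
    counts <- u_null_counts(n1, n2)
    us <- 0:(n1 * n2)
    m <- n1 * n2 / 2
    p <- sum(counts[abs(us - m) >= abs(u - m) - 1e-9]) / sum(counts)
    method <- "exact"
  } else {
    m <- n1 * n2 / 2
    nt <- table(c(x, y))
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(nt^3 - nt) / (n * (n - 1)))
    z <- u - m
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approx"
  }
  structure(list(u = u, p = p, n1 = n1, n2 = n2, method = method),
            class = "mwu_test")
}

#' @export
print.mwu_test <- function(x, ...) {
  cat("Mann-Whitney U = ", x$u, " (n1 = ", x$n1, ", n2 = ", x$n2,
      "), two-tailed p = ", signif(x$p, 4), " [", x$method, "]\n", sep = "")
  invisible(x)
}

#' @rdname mann_whitney_u
#' @param x An `mwu_test` (for `tidy`).
#' @param ... Unused.
#' @export
tidy.mwu_test <- function(x, ...) {
  tibble(u_statistic = x$u, p_two_tailed = x$p, n1 = x$n1, n2 = x$n2,
         method = x$method)
}

p_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "")
}

#' RNAi attenuation time course with nonparametric tests
#'
#' Summarizes flash-response amplitudes per treatment day and recording
#' position — eyes pooled within treatment, position 2 (the small-signal eye
#' center) excluded by default — and tests each treated day against the
#' pooled control recordings with the two-tailed Mann-Whitney test.
#' Significance stars follow the usual convention (* p < 0.05, ** p < 0.01,
#' *** p < 0.001); no multiple-testing correction is applied by default, with
#' Holm adjustment available via `adjust`.
#'
#' @param data Recording tibble `group`, `animal`, `eye`, `position`, `day`,
#'   `amplitude_mv` (e.g. [simulate_erg_cohort()]).
#' @param control_group Name of the control group (default `"control"`).
#' @param positions Recording positions analysed (default `c(1, 3)`).
#' @param pool_positions Also emit rows with `position = "pooled"` combining
#'   the analysed positions (default `TRUE`).
#' @param adjust P-value adjustment across day x position tests: `"none"`
#'   (default) or any [stats::p.adjust] method.
#' @return Tibble of class `erg_timecourse`: `group`, `day`, `position`,
#'   `n`, `n_control`, `mean_mv`, `se_mv`, `sd_mv`, `pct_of_control`,
#'   `u_statistic`, `p_two_tailed`, `stars`. Control means per position are
#'   attached as attribute `control`.
#' @examples
#' erg <- simulate_erg_cohort(scenario_pgo1(), days = c(2, 7), seed = 1)
#' attenuation_timecourse(erg)
#' @export
attenuation_timecourse <- function(data, control_group = "control",
                                   positions = c(1, 3), pool_positions = TRUE,
                                   adjust = "none") {
  if (!control_group %in% data$group) abort("control group not present")
  d <- data %>% filter(.data$position %in% positions)
  ctrl <- d %>% filter(.data$group == control_group)
  trt <- d %>% filter(.data$group != control_group)
  if (nrow(trt) == 0) abort("no treated recordings")

  pos_sets <- c(as.list(positions), if (pool_positions) list(positions))
  pos_labels <- c(as.character(positions), if (pool_positions) "pooled")

  rows <- list()
  combos <- trt %>% distinct(.data$group, .data$day)
  for (i in seq_len(nrow(combos))) {
    g <- combos$group[i]; dy <- combos$day[i]
    for (j in seq_along(pos_sets)) {
      tv <- trt$amplitude_mv[trt$group == g & trt$day == dy &
                               trt$position %in% pos_sets[[j]]]
      cv <- ctrl$amplitude_mv[ctrl$position %in% pos_sets[[j]]]
      if (!length(tv)) next
      test <- mann_whitney_u(tv, cv)
      rows[[length(rows) + 1L]] <- tibble(
        group = g, day = dy, position = pos_labels[j],
        n = length(tv), n_control = length(cv),
        mean_mv = mean(tv), se_mv = sd(tv) / sqrt(length(tv)), sd_mv = sd(tv),
        pct_of_control = 100 * mean(tv) / mean(cv),
        u_statistic = test$u, p_two_tailed = test$p
      )
    }
  }
  out <- bind_rows(rows) %>% arrange(.data$group, .data$position, .data$day)
  if (adjust != "none") {
    out$p_two_tailed <- p.adjust(out$p_two_tailed, method = adjust)
  }
  out$stars <- p_stars(out$p_two_tailed)
  ctrl_sum <- ctrl %>%
    group_by(.data$position) %>%
    summarise(n = n(), mean_mv = mean(.data$amplitude_mv),
              se_mv = sd(.data$amplitude_mv) / sqrt(n()), .groups = "drop")
  class(out) <- c("erg_timecourse", class(out))
  attr(out, "control") <- ctrl_sum
  attr(out, "control_group") <- control_group
  out
}
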