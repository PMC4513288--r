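test_that("flash amplitude is measured relative to the initial baseline", {
  trace <- tibble::tibble(time_s = seq(0, 1.49, by = 0.01),
                          voltage_mv = c(rep(0, 50), rep(-5, 100)))
  expect_equal(erg_amplitude(trace), 5)
  flat <- tibble::tibble(time_s = seq(0, 1.49, by = 0.01), voltage_mv = rep(2, 150))
  expect_equal(erg_amplitude(flat), 0)
  expect_error(erg_amplitude(trace, baseline_window = c(0, 1), flash_window = c(0.5, 1.5)),
               "overlap")
  expect_error(erg_amplitude(trace, baseline_window = c(-2, -1)), "empty")

  # noisy step + sweep averaging: estimate within a CLT-scaled band of truth
  cfg <- erg_cohort_config(noise_sd = 0.3, n_sweeps = 10)
  amps <- vapply(1:50, function(i)
    erg_amplitude(simulate_erg_trace(4, cfg, seed = i)), numeric(1))
  se <- 0.3 / sqrt(10) * sqrt(1 / 50 + 1 / 100)
  expect_lt(abs(mean(amps) - 4), 4 * se / sqrt(50))
})

test_that("Mann-Whitney exact branch equals full enumeration", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u, 0)
  expect_equal(r$p, 0.1)
  expect_equal(r$method, "exact")

  # central case: U = n1 n2 / 2 gives p = 1
  rc <- mann_whitney_u(c(1, 4), c(2, 3))
  expect_equal(rc$u, 2)
  expect_equal(rc$p, 1)

  # exhaustive: all tie-free rank arrangements for n1 + n2 <= 8
  for (n in 2:8) {
    for (n1 in 1:(n - 1)) {
      combos <- utils::combn(n, n1)
      us <- apply(combos, 2, function(ix) sum(ix) - n1 * (n1 + 1) / 2)
      m <- n1 * (n - n1) / 2
      for (ci in seq_len(ncol(combos))) {
        x <- combos[, ci]; y <- setdiff(seq_len(n), x)
        got <- mann_whitney_u(x, y)
        p_want <- mean(abs(us - m) >= abs(us[ci] - m) - 1e-9)
        expect_equal(got$u, us[ci])
        expect_equal(got$p, p_want, info = paste(n1, n - n1, us[ci]))
      }
    }
  }
})

test_that("Mann-Whitney agrees with the classical implementation", {
  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(sample(3:9, 1)); y <- rnorm(sample(3:9, 1))
    got <- mann_whitney_u(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE))
    expect_equal(got$u, unname(ref$statistic))
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
  # tie-corrected normal approximation
  for (i in 1:10) {
    x <- sample(1:6, 15, TRUE); y <- sample(1:6, 18, TRUE)
    got <- mann_whitney_u(x, y)
    expect_equal(got$method, "normal_approx")
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(got$p, ref$p.value, tolerance = 1e-9)
  }
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
  expect_error(mann_whitney_u(c(1, 1, 2), c(1, 3), exact = TRUE), "ties")
})

test_that("type-I error of the test is calibrated at the 5% level", {
  set.seed(2024)
  rej <- mean(vapply(1:4000, function(i) {
    mann_whitney_u(rnorm(15), rnorm(15))$p < 0.05
  }, logical(1)))
  expect_gt(rej, 0.035)
  expect_lt(rej, 0.065)
})

test_that("attenuation time course pools eyes, excludes position 2, stars match p", {
  sc <- scenario_identity()
  cohort <- simulate_erg_cohort(sc, days = c(7, 21), seed = 6)
  tc <- attenuation_timecourse(cohort)
  expect_false("2" %in% tc$position)
  expect_true(all(abs(tc$pct_of_control - 100) < 15))
  expect_true(all(tc$stars[tc$p_two_tailed >= 0.05] == ""))

  # duplicating every recording leaves percent-of-control unchanged
  dup <- rbind(cohort, dplyr::mutate(cohort, animal = paste0(animal, "_dup")))
  tc_dup <- attenuation_timecourse(dup)
  expect_equal(tc_dup$pct_of_control, tc$pct_of_control, tolerance = 1e-12)

  # deeper configured functional knockdown gives lower percent-of-control
  kin0 <- tibble::tibble(gene = "g", half_life_days = 0, lag_days = 0)
  cfg <- erg_cohort_config(nonresponder_prob = 0, animal_cv = 0, noise_sd = 0)
  pct <- vapply(c(0.8, 0.5, 0.2), function(f) {
    co <- simulate_erg_cohort(rnai_scenario("g", knockdown = c(g = f)), cfg,
                              days = 10, kinetics = kin0, seed = 8)
    tcx <- attenuation_timecourse(co)
    tcx$pct_of_control[tcx$position == "pooled"]
  }, numeric(1))
  expect_true(all(diff(pct) < 0))
  expect_equal(pct, c(80, 50, 20), tolerance = 1e-9)

  expect_error(attenuation_timecourse(dplyr::filter(cohort, group == "control")),
               "no treated")
  # Holm adjustment is available and never lowers a p-value
  tc_h <- attenuation_timecourse(cohort, adjust = "holm")
  expect_true(all(tc_h$p_two_tailed >= tc$p_two_tailed - 1e-12))
})
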