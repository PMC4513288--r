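test_that("standard-curve fit inverts slope to efficiency", {
  # perfect doubling: 3.32193 cycles per 10-fold dilution
  d <- tibble::tibble(log10_dilution = 0:-4,
                      cq = 18 - (0:-4) * 3.32193)
  sc <- fit_standard_curve(d)
  expect_equal(100 * sc$efficiency, 100, tolerance = 1e-3)

  d2 <- tibble::tibble(log10_dilution = 0:-4, cq = 20 - (0:-4) * 3.7233)
  sc2 <- fit_standard_curve(d2)
  expect_equal(100 * sc2$efficiency, 85.6, tolerance = 0.05)
  expect_equal(sc2$r2, 1, tolerance = 1e-9)
  expect_equal(10^(-1 / sc2$slope) - 1, sc2$efficiency, tolerance = 1e-9)

  expect_error(fit_standard_curve(tibble::tibble(log10_dilution = c(0, 0, 0),
                                                 cq = c(1, 2, 3))), "distinct")
  g <- glance(sc2)
  expect_equal(g$efficiency_pct, 85.6, tolerance = 0.05)
})

test_that("noiseless dilution series round-trips every assay efficiency to 1e-6", {
  for (i in seq_len(nrow(qpcr_efficiencies()))) {
    e <- qpcr_efficiencies()$efficiency[i]
    sc <- fit_standard_curve(simulate_dilution_series(e))
    expect_equal(sc$efficiency, e, tolerance = 1e-6)
  }
})

test_that("comparative-Cq ratio matches hand-computed closed forms", {
  plate <- tibble::tibble(
    gene = rep(c("t", "r1", "r2"), each = 2),
    group = rep(c("control", "treated"), 3),
    cq = c(20, 23, 20, 20, 25, 25))
  effs <- c(t = 1, r1 = 1, r2 = 1)
  expect_equal(relative_quantity(plate, "t", c("r1", "r2"), effs, "treated"), 0.125)
  effs2 <- c(t = 0.875, r1 = 1, r2 = 1)
  expect_equal(relative_quantity(plate, "t", c("r1", "r2"), effs2, "treated"),
               1.875^-3, tolerance = 1e-12)

  # references shifted equally with the target: normalization cancels
  plate_shift <- plate
  plate_shift$cq[plate_shift$group == "treated"] <-
    plate_shift$cq[plate_shift$group == "control"] + 2
  expect_equal(relative_quantity(plate_shift, "t", c("r1", "r2"), effs, "treated"), 1)

  # adding any constant to all Cq values of one group changes nothing
  r0 <- relative_quantity(plate, "t", c("r1", "r2"), effs2, "treated")
  plate_c <- plate
  plate_c$cq[plate_c$group == "treated"] <- plate_c$cq[plate_c$group == "treated"] + 7.3
  r1 <- relative_quantity(plate_c, "t", c("r1", "r2"), effs2, "treated")
  expect_equal(r1 / r0, 1.875^-7.3 / (2^-7.3), tolerance = 1e-9)

  expect_error(relative_quantity(plate, "t", "r1", c(t = 1), "treated"), "efficiency")
  expect_error(relative_quantity(plate, "t", "r1", effs, "absent"), "lacks genes")
})

test_that("reference aggregation is geometric, not arithmetic", {
  # references move in opposite directions by unequal amounts
  plate <- tibble::tibble(
    gene = rep(c("t", "r1", "r2"), each = 2),
    group = rep(c("control", "treated"), 3),
    cq = c(20, 20, 20, 18, 20, 23))
  effs <- c(t = 1, r1 = 1, r2 = 1)
  got <- relative_quantity(plate, "t", c("r1", "r2"), effs, "treated")
  geo <- 1 / sqrt(2^2 * 2^-3)      # geometric mean of reference factors
  ari <- 1 / mean(c(2^2, 2^-3))    # arithmetic would differ
  expect_equal(got, geo, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(got, ari, tolerance = 1e-3)))
})

test_that("knockdown table recovers configured residual fractions", {
  tx <- fixture_tx()
  # identity scenario, no noise of any kind: every ratio exactly 1
  plate0 <- simulate_qpcr_plate(tx$truth, scenario_identity(), noise_sd = 0,
                                animal_sd_log2 = 0, seed = 1)
  kd0 <- knockdown_table(plate0)
  expect_equal(kd0$ratio_vs_control, rep(1, nrow(kd0)), tolerance = 1e-9)

  # noiseless round trip across knockdown depths and efficiencies
  for (f in c(0.9, 0.3, 0.05, 0.012)) {
    for (e_t in c(0.7, 0.875, 1.0)) {
      truth <- tibble::tibble(gene = c("t", "actin", "GAPDH"), copy_number = c(5, 50, 20))
      sc <- rnai_scenario("t", knockdown = c(t = f), sham_prob = 0)
      effs <- c(t = e_t, actin = 0.856, GAPDH = 0.8951)
      plate <- simulate_qpcr_plate(truth, sc, effs, noise_sd = 0,
                                   animal_sd_log2 = 0, seed = 2)
      kd <- knockdown_table(plate, effs)
      expect_equal(kd$ratio_vs_control[kd$gene == "t" & kd$group == "treated"], f,
                   tolerance = 1e-9)
    }
  }

  # with realistic plate noise the estimator is nearly unbiased in log2
  est <- vapply(1:40, function(i) {
    plate <- simulate_qpcr_plate(tx$truth, scenario_ptrpl(), noise_sd = 0.2,
                                 animal_sd_log2 = 0.2, seed = 1000 + i)
    kd <- knockdown_table(plate)
    kd$ratio_vs_control[kd$gene == "pTRPL" & kd$group == "treated"]
  }, numeric(1))
  expect_lt(abs(mean(log2(est)) - log2(0.09)), 0.2)
})

test_that("reference genes report unit ratio and saline is carried alongside", {
  tx <- fixture_tx()
  plate <- simulate_qpcr_plate(tx$truth, scenario_pgo1(), seed = 12)
  kd <- knockdown_table(plate)
  expect_setequal(unique(kd$group), c("saline", "treated"))
  refs <- kd[kd$is_reference, ]
  expect_true(all(refs$ratio_vs_control == 1))
  expect_setequal(unique(refs$gene), c("actin", "GAPDH"))
})
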