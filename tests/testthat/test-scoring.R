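test_that("G value is 100 N / E_dep", {
  expect_equal(g_value(0, 100), 0)
  expect_equal(g_value(1561, 6.242e4), 2.50, tolerance = 1e-3)
  expect_equal(g_value(50, 2e4), 2 * g_value(50, 4e4))
  expect_error(g_value(10, 0), "E_dep")
})

test_that("relative G normalizes to the reference dose rate", {
  g <- c("0.02" = 2.0, "5" = 1.6, "500" = 0.24)
  r <- relative_g(g, 0.02)
  expect_equal(unname(r["0.02"]), 1)
  expect_equal(unname(r["500"]), 0.12)
  expect_error(relative_g(g, 7), "not present")
  expect_error(relative_g(c("0.02" = 0, "500" = 1), 0.02), "zero")
})

test_that("depletion fit recovers exact linear slopes and rejects degenerate series", {
  ser <- data.frame(dose_gy = c(0.5, 1, 2, 5, 10, 20))
  ser$o2_uM <- 239.4 - 0.5 * ser$dose_gy
  fit <- o2_depletion_rate(ser)
  expect_equal(fit$uM_per_gy, 0.5, tolerance = 1e-12)
  expect_equal(fit$pct_per_gy, uM_to_pO2(0.5), tolerance = 1e-12)
  flat <- data.frame(dose_gy = c(1, 5, 10), o2_uM = 200)
  expect_equal(o2_depletion_rate(flat)$uM_per_gy, 0, tolerance = 1e-12)
  expect_error(o2_depletion_rate(data.frame(dose_gy = c(5, 5), o2_uM = c(1, 2))),
               "constant dose")
  expect_error(o2_depletion_rate(ser[1, ]), "at least 2")
})

test_that("dose to full depletion extrapolates linearly", {
  expect_equal(dose_to_depletion(0.028, 25), 892.9, tolerance = 1e-3)
  expect_equal(dose_to_depletion(0.028, 0), 0)
  expect_equal(dose_to_depletion(0.014, 25), 2 * dose_to_depletion(0.028, 25))
  expect_error(dose_to_depletion(0, 25), "rate")
})

test_that("ensemble statistics are the unbiased mean and SD", {
  st <- ensemble_stats(c(2.4, 2.5, 2.6))
  expect_equal(st$mean, 2.5)
  expect_equal(st$sd, 0.1)
  expect_equal(st$rel_sd_pct, 4)
  expect_identical(ensemble_stats(rep(1.7, 5))$sd, 0)
  expect_error(ensemble_stats(2.5), "at least 2")
})

test_that("per-scenario G extraction matches the stored curve and flags off-grid times", {
  cfg <- scenario_config(500, pO2_percent = 0, horizon_s = 1e-6)
  r <- run_scenario(cfg, seed = 31)
  g <- scenario_g(r, "e_aq", 1e-6)
  sub <- subset(r$gcurve, species == "e_aq" & time_s == 1e-6)
  expect_equal(g, sub$g_value)
  expect_equal(g, g_value(sub$count, r$o2$edep_eV[r$o2$time_s == 1e-6]))
  expect_error(scenario_g(r, "e_aq", 7e-7), "not on the output grid")
})

test_that("intertrack fraction tags events by origin tracks", {
  ev <- data.frame(reaction = "R3", time_s = c(1, 2, 3) * 1e-6,
                   track_a = c(1L, 1L, 2L), track_b = c(1L, 2L, -1L),
                   intertrack = c(FALSE, TRUE, FALSE))
  expect_equal(intertrack_fraction(ev), 0.5)   # pfo event excluded
  expect_equal(intertrack_fraction(ev, until_s = 1.5e-6), 0)
  expect_true(is.na(intertrack_fraction(ev[ev$track_b < 0, ])))
})
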