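test_that("escape kernel is monotone toward the boundary and averaged correctly", {
  m <- spur_model()
  centre <- escape_fraction(m, 1, 1)
  edge <- escape_fraction(m, 0.5, 1)
  corner <- escape_fraction(m, 0.5, 0.5)
  expect_lt(centre, edge)
  expect_equal(edge, m$escape_f0)
  expect_equal(corner, m$escape_f0)
  # analytic face average agrees with Monte-Carlo
  set.seed(1)
  xy <- matrix(runif(2e4, 0.5, 1.5), ncol = 2)
  mc <- mean(escape_fraction(m, xy[, 1], xy[, 2]))
  expect_equal(mean_escape_fraction(m), mc, tolerance = 0.02)
})

test_that("initial species counts are Poisson with mean G0 * E / 100", {
  yields <- c(e_aq = 4.8, OH = 5.6)
  expect_identical(initial_species_counts(0, yields),
                   c(e_aq = 0L, OH = 0L))
  expect_error(initial_species_counts(-1, yields), "non-negative")
  set.seed(2)
  draws <- t(replicate(20000, initial_species_counts(100, yields)))
  for (s in names(yields)) {
    se <- sqrt(yields[[s]] / 20000)
    expect_lt(abs(mean(draws[, s]) - yields[[s]]), 3 * se)
  }
})

test_that("tracks deposit the right mean energy and respect geometry", {
  beam <- beam_config(500)
  m <- spur_model()
  set.seed(5)
  trs <- lapply(1:400, function(i)
    generate_track(c(runif(1, 0.5, 1.5), runif(1, 0.5, 1.5)), 0, beam, m,
                   track_id = i))
  e <- vapply(trs, function(tr) tr$energy_eV, numeric(1))
  let_eV <- beam$let_kev_um * 1e3
  expected <- let_eV * (1 - mean_escape_fraction(m))
  expect_equal(mean(e), expected, tolerance = 3 * sd(e) / sqrt(400) / expected)
  # all molecules inside the phantom
  mols <- do.call(rbind, lapply(trs, function(tr) tr$molecules))
  expect_true(all(mols$x_um >= 0 & mols$x_um <= 2))
  expect_true(all(mols$y_um >= 0 & mols$y_um <= 2))
  expect_true(all(mols$z_um >= 0 & mols$z_um <= 2))
  # scored energy equals the non-escaped deposits
  dep <- trs[[1]]$deposits
  expect_equal(sum(dep$energy_eV[!dep$escaped]), trs[[1]]$energy_eV)
})

test_that("corner-entry tracks deposit less than centre tracks; zero spur density is empty", {
  beam <- beam_config(500)
  m <- spur_model()
  set.seed(6)
  ec <- replicate(300, generate_track(c(1, 1), 0, beam, m)$energy_eV)
  set.seed(6)
  eg <- replicate(300, generate_track(c(0.52, 0.52), 0, beam, m)$energy_eV)
  expect_lt(mean(eg), mean(ec) * 0.5)
  degenerate <- spur_model(mean_spur_energy_eV = 1e12)  # ~zero spur density
  set.seed(7)
  tr <- generate_track(c(1, 1), 0, beam, degenerate)
  expect_equal(nrow(tr$deposits), 0)
  expect_equal(nrow(tr$molecules), 0)
})

test_that("track generation is deterministic under a seed and dose is linear in track count", {
  beam <- beam_config(500)
  m <- spur_model()
  t1 <- generate_track(c(1, 1), 0, beam, m, seed = 11)
  t2 <- generate_track(c(1, 1), 0, beam, m, seed = 11)
  expect_identical(t1, t2)
  set.seed(8)
  e1 <- replicate(500, generate_track(c(1, 1), 0, beam, m)$energy_eV)
  # N identical centre tracks score N times the single-track expectation
  sums <- colSums(matrix(e1[1:480], nrow = 4))
  se <- sd(sums) / sqrt(length(sums))
  expect_lt(abs(mean(sums) - 4 * mean(e1)), 3 * se + 1e-9)
})

test_that("escape-length calibration hits a requested mean track count", {
  beam <- beam_config(500)
  len <- calibrate_escape_length(71, beam, spur_model())
  expect_equal(len, spur_model()$escape_length_um, tolerance = 0.05)
  m <- spur_model(escape_length_um = len)
  model <- track_energy_model(m, beam)
  set.seed(9)
  n <- replicate(250, nrow(sample_schedule(beam, model)))
  expect_equal(mean(n), 71, tolerance = 0.04)
})
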