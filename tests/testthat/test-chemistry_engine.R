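test_that("step schedule resets, grows by decade, saturates, and truncates at arrivals", {
  sch <- step_schedule(1e-12, 0.1)
  expect_equal(next_dt(0, sch), 1e-12)
  expect_equal(next_dt(5e-12, sch), 1e-12)
  expect_equal(next_dt(5e-11, sch), 1e-11)
  expect_equal(next_dt(2e-3, sch), 1e-3)
  expect_equal(next_dt(1e6, sch), 0.1)   # far beyond the last breakpoint
  expect_equal(next_dt(2e-3, sch, time_to_next_arrival_s = 0.3e-3), 0.3e-3)
  expect_error(step_schedule(breakpoints = data.frame(elapsed_s = numeric(0),
                                                      dt_s = numeric(0))))
})

test_that("reflect mirror-folds coordinates into the box", {
  expect_equal(reflect(-0.1), 0.1)
  expect_equal(reflect(2.3), 1.7)
  expect_equal(reflect(4.3), 0.3)
  expect_equal(reflect(0.7), 0.7)          # idempotent interior
  # iterative-fold oracle: reflect repeatedly across whichever wall is crossed
  fold1 <- function(x, L = 2) {
    while (x < 0 || x > L) x <- ifelse(x < 0, -x, 2 * L - x)
    x
  }
  set.seed(1)
  xs <- runif(200, -15, 15)
  expect_equal(reflect(xs), vapply(xs, fold1, numeric(1)))
})

test_that("diffusion is null for dt=0 or D=0 and has MSD 6 D dt", {
  set.seed(2)
  p <- matrix(runif(300, 0, 2), ncol = 3)
  expect_identical(diffuse(p, 2.2e-9, 0), p)
  expect_equal(diffuse(p, 0, 1e-3), p)
  n <- 1e5
  centre <- matrix(1, n, 3)  # far from walls for a tiny step
  D <- 2.2e-9; dt <- 1e-6
  set.seed(3)
  q <- diffuse(centre, D, dt)
  msd_um2 <- mean(rowSums((q - centre)^2))
  expected <- 6 * D * 1e12 * dt
  se <- sd(rowSums((q - centre)^2)) / sqrt(n)
  expect_lt(abs(msd_um2 - expected), 3 * se)
})

test_that("GFDE pair probability has the closed form and matches a Brownian absorption oracle", {
  expect_equal(pair_reaction_probability(1, 1, 1e-9, 1e-9), 1)
  expect_equal(pair_reaction_probability(0.5, 1, 1e-9, 1e-9), 1) # inside contact
  expect_lt(pair_reaction_probability(50, 1, 1e-9, 1e-12), 1e-10)
  # r = 2R: at D dt = (r-R)^2 the erfc argument is 1/2, giving
  # 0.5 * erfc(0.5) ~ 0.2398; at 4 D dt = (r-R)^2 it is 1, giving
  # 0.5 * erfc(1) ~ 0.0786
  R <- 1; r <- 2; D <- 1e-9
  dt <- ((r - R) * 1e-9)^2 / D
  expect_equal(pair_reaction_probability(r, R, D, dt), 0.2398,
               tolerance = 1e-3)
  expect_equal(pair_reaction_probability(r, R, D, dt / 4), 0.5 * 2 *
                 pnorm(-sqrt(2)), tolerance = 1e-6)
  # brute-force isolated-pair oracle: relative-coordinate random walk with
  # absorption at contact, including the Brownian-bridge crossing
  # probability between substep endpoints
  nw <- 6000; nsub <- 1000
  dsub <- dt / nsub
  sig <- sqrt(2 * D * 1e18 * dsub)   # nm per axis per substep
  set.seed(4)
  pos <- cbind(rep(r, nw), 0, 0)
  hit <- rep(FALSE, nw)
  d0 <- rep(r, nw)
  for (s in seq_len(nsub)) {
    pos <- pos + matrix(rnorm(3 * nw, 0, sig), nw, 3)
    d1 <- sqrt(rowSums(pos^2))
    pb <- exp(-pmax(d0 - R, 0) * pmax(d1 - R, 0) / (D * 1e18 * dsub))
    hit <- hit | d1 <= R | (runif(nw) < pb)
    pos[hit, ] <- 1e6  # park absorbed walkers away
    d0 <- d1
    d0[hit] <- 1e6
  }
  expect_lt(abs(mean(hit) - 0.2398), 0.02)
  expect_error(pair_reaction_probability(0, 1, 1e-9, 1e-9), "r must be")
})

test_that("pseudo-first-order probability follows 1 - exp(-k C dt)", {
  expect_equal(scavenging_probability(1e10, 0, 1e-9), 0)
  expect_equal(scavenging_probability(1.48e10, 239.4, 1e-9),
               3.537e-3, tolerance = 1e-3)
})

test_that("oxygen bookkeeping converts molecule counts to concentration and clamps at zero", {
  f <- continuum_field(25)
  expect_equal(f$pO2_uM, 239.4)
  expect_identical(update_oxygen(f, 5, 5)$pO2_uM, f$pO2_uM)
  expect_identical(update_oxygen(f, 0, 0)$pO2_uM, f$pO2_uM)
  f2 <- update_oxygen(f, 0, 602)
  expect_equal(f$pO2_uM - f2$pO2_uM, 1.0, tolerance = 1e-3)
  f3 <- continuum_field(0)
  expect_equal(update_oxygen(f3, 0, 100)$pO2_uM, 0)  # clamped
})

test_that("reference second-order step handles contact pairs and empty neighbourhoods", {
  chem <- ab_chemistry()
  far <- data.frame(species = c("A", "B"), x_um = c(0.2, 1.8),
                    y_um = c(0.2, 1.8), z_um = c(0.2, 1.8))
  set.seed(5)
  out <- apply_second_order(far, chem, 1e-9)
  expect_equal(sum(out$events$count), 0)
  expect_equal(nrow(out$molecules), 2)
  contact <- data.frame(species = c("A", "B"), x_um = c(1, 1 + 1e-6),
                        y_um = 1, z_um = 1)
  set.seed(6)
  out2 <- apply_second_order(contact, chem, 1e-9)
  expect_equal(sum(out2$events$count), 1)
  expect_identical(out2$molecules$species, "C")
})

test_that("reference pseudo-first-order step consumes nothing at zero concentration", {
  chem <- scavenge_chemistry()
  mol <- data.frame(species = rep("A", 50), x_um = 1, y_um = 1, z_um = 1)
  set.seed(7)
  out <- apply_pseudo_first_order(mol, continuum_field(0), chem, 1e-6)
  expect_equal(out$n_consumed, 0)
  expect_equal(nrow(out$molecules), 50)
  set.seed(8)
  out2 <- apply_pseudo_first_order(mol, continuum_field(25), chem, 1e-4)
  expect_gt(out2$n_consumed, 0)
  expect_equal(sum(out2$molecules$species == "P"), out2$n_consumed)
})

test_that("with reactions disabled molecule count is conserved and positions stay inside the phantom", {
  chem <- inert_chemistry()
  mol <- make_fixture("uniform_nonreacting", seed = 10, n = 2000)
  mol$species <- "A"
  res <- run_engine(chem, mol, t_end = 1, dt = 1e-3,
                    out_times = c(0.25, 0.5, 1), seed = 11)
  expect_true(all(res$out_counts[, "A"] == 2000))
  expect_true(all(res$final$x_um >= 0 & res$final$x_um <= 2))
  expect_true(all(res$final$y_um >= 0 & res$final$y_um <= 2))
  expect_true(all(res$final$z_um >= 0 & res$final$z_um <= 2))
})

test_that("a uniform non-reacting population stays uniform under reflective diffusion", {
  chem <- inert_chemistry(D = 5e-9)
  mol <- make_fixture("uniform_nonreacting", seed = 12)
  mol$species <- "A"
  res <- run_engine(chem, mol, t_end = 1e-3, dt = 1e-6, seed = 13)
  cut <- seq(0, 2, length.out = 9)
  bin <- function(v) findInterval(v, cut, rightmost.closed = TRUE)
  cell <- bin(res$final$x_um) + 8 * (bin(res$final$y_um) - 1) +
    64 * (bin(res$final$z_um) - 1)
  obs <- tabulate(cell, nbins = 512)
  chi <- sum((obs - mean(obs))^2 / mean(obs))
  pval <- stats::pchisq(chi, df = 511, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("pure scavenging survival equals exp(-k C t) for arbitrary step partitions", {
  chem <- scavenge_chemistry()
  n <- 20000
  mol <- data.frame(species = rep("A", n), x_um = 1, y_um = 1, z_um = 1)
  C <- 239.4; k <- 1.48e10; Tt <- 1e-6
  surv_expected <- exp(-k * C * 1e-6 * Tt)
  for (dts in list(1e-7, 2.3e-8)) {
    res <- run_engine(chem, mol, t_end = Tt, dt = dts, pO2_uM = C,
                      seed = 14, avg_volume_um3 = 1e9)
    surv <- res$out_counts[, "A"] / n
    se <- sqrt(surv_expected * (1 - surv_expected) / n)
    expect_lt(abs(surv - surv_expected), 4 * se)
  }
  # and through the irregular reset-and-grow ladder as well
  res <- run_engine(chem, mol, t_end = Tt, schedule = step_schedule(),
                    pO2_uM = C, seed = 15, avg_volume_um3 = 1e9)
  surv <- res$out_counts[, "A"] / n
  se <- sqrt(surv_expected * (1 - surv_expected) / n)
  expect_lt(abs(surv - surv_expected), 4 * se)
})

test_that("dilute well-mixed bimolecular decay recovers the table rate constant within 5%", {
  chem <- ab_chemistry(k = 1e10, D = 5e-9)
  lamconv <- 8 / 1.66053906717e-9   # counts<->concentration in the 8 um^3 box
  khat <- vapply(1:6, function(s) {
    mol <- make_fixture("well_mixed_AB", seed = s, n = 1500)
    res <- run_engine(chem, mol, t_end = 1e-3, dt = 2.5e-8, seed = 100 + s)
    (1 / res$out_counts[, "A"] - 1 / 1500) / 1e-3 * lamconv
  }, numeric(1))
  expect_lt(abs(mean(khat) - 1e10) / 1e10, 0.05)
})

test_that("identical scenario configuration and seed give identical event logs", {
  cfg <- scenario_config(500, pO2_percent = 25, horizon_s = 1e-5)
  r1 <- run_scenario(cfg, seed = 99)
  r2 <- run_scenario(cfg, seed = 99)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$counts, r2$counts)
  expect_identical(r1$schedule, r2$schedule)
  r3 <- run_scenario(cfg, seed = 100)
  expect_false(identical(r1$counts, r3$counts))
})

test_that("scored dose at the end of irradiation reaches the stopping threshold", {
  cfg <- scenario_config(500, pO2_percent = 0, horizon_s = 1e-6)
  r <- run_scenario(cfg, seed = 21)
  expect_gte(sum(attr(r$schedule, "dose_gy")), 10)
})
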