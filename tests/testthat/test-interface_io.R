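test_that("config parsing fills defaults, derives quantities, and validates", {
  cfg <- parse_config("beam: {dose_rate_gy_per_s: 500}")
  expect_equal(cfg$derived$t_p_s, 0.02)
  expect_equal(cfg$chemistry$pO2_percent, 25)
  expect_equal(cfg$derived$pO2_uM, 239.4)
  cfg2 <- parse_config("chemistry: {pO2_percent: 0}")
  expect_equal(cfg2$derived$pO2_uM, 0)
  expect_error(parse_config("beam: {dose_rate_gy_per_s: -5}"),
               "beam.dose_rate_gy_per_s")
  expect_error(parse_config("beam: {dose_rate: 5}"), "unknown configuration key")
  expect_error(parse_config("laser: {power: 5}"), "unknown configuration block")
})

test_that("a parsed config builds a runnable scenario configuration", {
  cfg <- parse_config("beam: {dose_rate_gy_per_s: [0.02, 500]}\nchemistry: {horizon_s: 1.0e-5}")
  sc <- config_scenario(cfg, 500)
  expect_s3_class(sc, "run_config")
  expect_equal(sc$beam$t_p_s, 0.02)
  expect_equal(sc$horizon_s, 1e-5)
  r <- run_scenario(sc, seed = 1)
  expect_s3_class(r, "scenario_result")
})

test_that("output writers produce the documented deterministic file set", {
  dir1 <- file.path(tempdir(), "uhdr_out_a")
  dir2 <- file.path(tempdir(), "uhdr_out_b")
  unlink(c(dir1, dir2), recursive = TRUE)
  cfg <- scenario_config(500, pO2_percent = 25, horizon_s = 1e-6,
                         snapshot_times_s = c(1e-7, 1e-6))
  res <- lapply(c(41, 42), function(s) run_scenario(cfg, s))
  write_outputs(res, cfg, dir1, eval_times_s = 1e-6)
  write_outputs(res, cfg, dir2, eval_times_s = 1e-6)
  for (f in c("gcurves.csv", "depletion.csv", "summary.json", "config.yaml",
              "run.log")) {
    expect_true(file.exists(file.path(dir1, f)))
  }
  # byte-identical CSV/JSON on re-run
  for (f in c("gcurves.csv", "depletion.csv", "summary.json")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  # round-trip: the written curves equal the in-memory ones
  gc <- read_gcurves(file.path(dir1, "gcurves.csv"))
  g1 <- subset(gc, scenario_id == 1)
  expect_equal(g1$count, res[[1]]$gcurve$count)
  expect_equal(g1$g_value, res[[1]]$gcurve$g_value, tolerance = 1e-9)
  # summary.json holds hydrated-electron entries at 1 us
  summ <- jsonlite::read_json(file.path(dir1, "summary.json"),
                              simplifyVector = TRUE)
  expect_true(any(summ$species == "e_aq" & summ$eval_time_s == 1e-6))
  # one xyz frame per requested snapshot time
  xyz <- readLines(file.path(dir1, "snapshots", "scenario_001.xyz"))
  natoms <- as.integer(xyz[1])
  expect_equal(xyz[2], sprintf("time_s=%.9e", res[[1]]$snapshots[[1]]$time_s))
  frame2_start <- 2 + natoms + 1
  expect_equal(length(res[[1]]$snapshots), 2)
  expect_match(xyz[frame2_start + 1], "^time_s=")
})

test_that("fixtures have the documented structure and unknown kinds error", {
  u <- make_fixture("uniform_nonreacting", seed = 1)
  expect_equal(nrow(u), 10000)
  expect_true(all(u$x_um >= 0 & u$x_um <= 2))
  ab <- make_fixture("well_mixed_AB", seed = 2, n = 123)
  expect_equal(as.vector(table(ab$species)), c(123, 123))
  st <- make_fixture("single_track", seed = 3)
  expect_length(st, 1)
  expect_s3_class(st[[1]], "track_deposit")
  expect_error(make_fixture("nope"), "unknown fixture kind")
})

test_that("track fixtures round-trip through CSV + JSON sidecar", {
  dir <- file.path(tempdir(), "uhdr_fix")
  unlink(dir, recursive = TRUE)
  tr <- make_fixture("two_close_tracks", seed = 4, dir = dir)
  back <- read_track_fixture(file.path(dir, "fixture.csv"),
                             file.path(dir, "fixture.json"))
  expect_length(back, 2)
  expect_equal(back[[1]]$energy_eV, tr[[1]]$energy_eV)
  expect_equal(nrow(back[[2]]$molecules), nrow(tr[[2]]$molecules))
  expect_equal(sort(back[[1]]$molecules$x_um), sort(tr[[1]]$molecules$x_um))
})

test_that("two parallel close tracks react across tracks within a microsecond", {
  trs <- make_fixture("two_close_tracks", seed = 5)
  set.seed(6)
  res <- uhdrchem:::run_chemistry_engine(default_chemistry(), tracks = trs,
                                         pO2_uM = 0, t_start = 0,
                                         t_end = 1e-6, out_times = 1e-6)
  ev <- res$events
  expect_gt(sum(ev$intertrack), 0)
})
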