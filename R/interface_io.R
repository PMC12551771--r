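# Configuration parsing, writers/readers, and fixture generation: the
# reproducibility shell around the engine.

.config_defaults <- function() {
  list(
    beam = list(dose_rate_gy_per_s = c(500), target_dose_gy = 10,
                let_kev_per_um = 1.169, area_um2 = 1, rho_g_cm3 = 1),
    chemistry = list(pO2_percent = 25, horizon_s = 1000,
                     dt_min_s = 1e-12, dt_cap_s = 0.1,
                     o2_averaging_volume_um3 = 1,
                     species_table = NULL, reaction_table = NULL),
    surrogate = list(mean_spur_energy_ev = 47,
                     spur_sigma_nm = formals(spur_model)$spur_sigma_nm,
                     escape_f0 = 1,
                     escape_length_um = formals(spur_model)$escape_length_um,
                     initial_yields = as.list(eval(formals(spur_model)$initial_yields))),
    ensemble = list(n_scenarios = 10, root_seed = 1),
    output = list(directory = "uhdrchem_out",
                  snapshot_times_s = numeric(0),
                  eval_times_s = c(1e-6, 1e-3, 1e-2, 1e-1))
  )
}

#' Parse and validate a run configuration
#'
#' Reads a YAML document with blocks `beam`, `chemistry`, `surrogate`,
#' `ensemble`, `output` (all optional; defaults filled in), validates every
#' key, and rejects unknown keys naming the offending path. Units are part
#' of the key names.
#'
#' @param path path to a YAML file, or a YAML string.
#' @return object of class `run_config_file`: the resolved configuration
#'   with derived quantities (`t_p_s` per dose rate, `pO2_uM`).
#' @export
#' @examples
#' cfg <- parse_config("beam: {dose_rate_gy_per_s: 500}")
#' cfg$derived$t_p_s # 0.02
parse_config <- function(path) {
  user <- if (file.exists(path)) yaml::read_yaml(path)
          else yaml::yaml.load(path)
  if (is.null(user)) user <- list()
  defs <- .config_defaults()
  unknown_block <- setdiff(names(user), names(defs))
  if (length(unknown_block) > 0)
    stop(sprintf("unknown configuration block '%s'", unknown_block[1]))
  cfg <- defs
  for (blk in names(user)) {
    extra <- setdiff(names(user[[blk]]), names(defs[[blk]]))
    if (length(extra) > 0)
      stop(sprintf("unknown configuration key '%s.%s'", blk, extra[1]))
    for (k in names(user[[blk]])) cfg[[blk]][[k]] <- user[[blk]][[k]]
  }
  cfg$surrogate$spur_sigma_nm <- as.numeric(cfg$surrogate$spur_sigma_nm)
  cfg$surrogate$escape_length_um <- as.numeric(cfg$surrogate$escape_length_um)
  # YAML sequences arrive as lists; flatten the numeric vector fields
  cfg$beam$dose_rate_gy_per_s <- as.numeric(unlist(cfg$beam$dose_rate_gy_per_s))
  cfg$output$snapshot_times_s <- as.numeric(unlist(cfg$output$snapshot_times_s))
  cfg$output$eval_times_s <- as.numeric(unlist(cfg$output$eval_times_s))

  chk <- function(ok, key) if (!ok) stop(sprintf(
    "configuration value out of range at '%s'", key))
  chk(all(cfg$beam$dose_rate_gy_per_s > 0), "beam.dose_rate_gy_per_s")
  chk(cfg$beam$target_dose_gy > 0, "beam.target_dose_gy")
  chk(cfg$beam$let_kev_per_um > 0, "beam.let_kev_per_um")
  chk(cfg$chemistry$pO2_percent >= 0, "chemistry.pO2_percent")
  chk(cfg$chemistry$horizon_s > 0, "chemistry.horizon_s")
  chk(cfg$chemistry$dt_min_s > 0 &&
        cfg$chemistry$dt_cap_s >= cfg$chemistry$dt_min_s, "chemistry.dt_cap_s")
  chk(cfg$chemistry$o2_averaging_volume_um3 > 0,
      "chemistry.o2_averaging_volume_um3")
  chk(cfg$surrogate$mean_spur_energy_ev > 0, "surrogate.mean_spur_energy_ev")
  chk(cfg$surrogate$spur_sigma_nm > 0, "surrogate.spur_sigma_nm")
  chk(cfg$ensemble$n_scenarios >= 1, "ensemble.n_scenarios")

  cfg$derived <- list(
    t_p_s = pulse_duration(cfg$beam$target_dose_gy,
                           cfg$beam$dose_rate_gy_per_s),
    pO2_uM = pO2_to_uM(cfg$chemistry$pO2_percent)
  )
  class(cfg) <- "run_config_file"
  cfg
}

#' Build a scenario configuration from a parsed config file
#'
#' @param cfg a [parse_config()] result.
#' @param dose_rate_gy_s one dose rate from the configured list.
#' @return a [scenario_config()].
#' @export
config_scenario <- function(cfg, dose_rate_gy_s = cfg$beam$dose_rate_gy_per_s[1]) {
  stopifnot(inherits(cfg, "run_config_file"))
  chem <- if (!is.null(cfg$chemistry$species_table)) {
    chemistry_system(read.csv(cfg$chemistry$species_table,
                              stringsAsFactors = FALSE),
                     read.csv(cfg$chemistry$reaction_table,
                              stringsAsFactors = FALSE))
  } else default_chemistry()
  spur <- spur_model(
    mean_spur_energy_eV = cfg$surrogate$mean_spur_energy_ev,
    spur_sigma_nm = cfg$surrogate$spur_sigma_nm,
    escape_f0 = cfg$surrogate$escape_f0,
    escape_length_um = cfg$surrogate$escape_length_um,
    initial_yields = unlist(cfg$surrogate$initial_yields)
  )
  beam <- beam_config(dose_rate_gy_s, cfg$beam$target_dose_gy,
                      cfg$beam$let_kev_per_um, cfg$beam$area_um2,
                      cfg$beam$rho_g_cm3)
  scenario_config(
    dose_rate_gy_s, cfg$beam$target_dose_gy,
    pO2_percent = cfg$chemistry$pO2_percent,
    horizon_s = cfg$chemistry$horizon_s,
    chem = chem, spur = spur, beam = beam,
    schedule = step_schedule(cfg$chemistry$dt_min_s, cfg$chemistry$dt_cap_s),
    out_times_s = log_time_grid(1e-12, cfg$chemistry$horizon_s,
                                eval_times_s = cfg$output$eval_times_s),
    snapshot_times_s = cfg$output$snapshot_times_s,
    avg_volume_um3 = cfg$chemistry$o2_averaging_volume_um3
  )
}

#' Write extended-XYZ snapshot frames
#'
#' One frame per snapshot: the atom count, a comment line carrying the time
#' in seconds, then one row per alive molecule (species label and x, y, z in
#' nm).
#'
#' @param snapshots list of snapshots from a `scenario_result` (fields
#'   `time_s`, `sp`, `x_um`, `y_um`, `z_um`).
#' @param path output file.
#' @param species_names species label lookup (0-based ids to names).
#' @return invisibly `path`.
#' @export
write_xyz <- function(snapshots, path,
                      species_names = default_species()$name) {
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in snapshots) {
    n <- length(fr$sp)
    writeLines(as.character(n), con)
    writeLines(sprintf("time_s=%.9e", fr$time_s), con)
    if (n > 0) {
      writeLines(sprintf("%s %.4f %.4f %.4f",
                         species_names[fr$sp + 1L],
                         fr$x_um * 1e3, fr$y_um * 1e3, fr$z_um * 1e3), con)
    }
  }
  invisible(path)
}

#' Write the standard output file set for a batch of scenario results
#'
#' Produces `gcurves.csv` (per-scenario species time courses),
#' `depletion.csv` (per-scenario dose and end-of-run oxygen),
#' `summary.json` (ensemble means/SDs at the configured evaluation times),
#' `snapshots/scenario_<i>.xyz` when snapshots were recorded, `config.yaml`
#' (the resolved configuration echo) and `run.log`. Re-running with the same
#' config and seeds reproduces the CSV/JSON byte-identically.
#'
#' @param results list of `scenario_result`s.
#' @param config the `run_config` used.
#' @param dir output directory (created if needed).
#' @param eval_times_s evaluation times for `summary.json`.
#' @return invisibly the directory.
#' @export
write_outputs <- function(results, config, dir,
                          eval_times_s = c(1e-6, 1e-3, 1e-2, 1e-1)) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop(sprintf("cannot create directory '%s'", dir))
  }
  gc <- do.call(rbind, lapply(seq_along(results), function(i) {
    g <- results[[i]]$gcurve
    g$scenario_id <- i
    g
  }))
  write.csv(gc, file.path(dir, "gcurves.csv"), row.names = FALSE)

  dep <- do.call(rbind, lapply(seq_along(results), function(i) {
    data.frame(scenario_id = i,
               dose_gy = dose_from_energy(results[[i]]$edep_eV),
               o2_uM = results[[i]]$o2_uM_final)
  }))
  write.csv(dep, file.path(dir, "depletion.csv"), row.names = FALSE)

  eval_times_s <- eval_times_s[eval_times_s <= config$horizon_s]
  eval_times_s <- unique(c(eval_times_s, config$horizon_s))
  point_sp <- config$chem$species$name[
    config$chem$species$representation == "point_tracked"]
  summ <- list()
  for (tt in eval_times_s) {
    for (sp in point_sp) {
      vals <- tryCatch(ensemble_g(results, sp, tt), error = function(e) NULL)
      if (is.null(vals)) next
      st <- if (length(vals) >= 2) ensemble_stats(vals)
            else list(mean = mean(vals), sd = NA_real_,
                      rel_sd_pct = NA_real_, n = length(vals))
      summ[[length(summ) + 1]] <- list(
        dose_rate_gy_s = config$beam$dose_rate_gy_s, species = sp,
        eval_time_s = tt, mean_G = st$mean, sd_G = st$sd, n = st$n)
    }
  }
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  has_snaps <- any(vapply(results, function(r) length(r$snapshots) > 0,
                          logical(1)))
  if (has_snaps) {
    dir.create(file.path(dir, "snapshots"), showWarnings = FALSE)
    for (i in seq_along(results)) {
      if (length(results[[i]]$snapshots) > 0)
        write_xyz(results[[i]]$snapshots,
                  file.path(dir, "snapshots", sprintf("scenario_%03d.xyz", i)),
                  species_names = config$chem$species$name)
    }
  }

  yaml::write_yaml(list(
    beam = list(dose_rate_gy_per_s = config$beam$dose_rate_gy_s,
                target_dose_gy = config$beam$target_dose_gy,
                let_kev_per_um = config$beam$let_kev_um),
    chemistry = list(pO2_percent = config$pO2_percent,
                     horizon_s = config$horizon_s,
                     o2_averaging_volume_um3 = config$avg_volume_um3),
    surrogate = list(mean_spur_energy_ev = config$spur$mean_spur_energy_eV,
                     spur_sigma_nm = config$spur$spur_sigma_nm,
                     escape_f0 = config$spur$escape_f0,
                     escape_length_um = config$spur$escape_length_um),
    seeds = vapply(results, function(r) r$seed, numeric(1))
  ), file.path(dir, "config.yaml"))

  writeLines(c(
    sprintf("uhdrchem %s", as.character(utils::packageVersion("uhdrchem"))),
    sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("scenarios: %d", length(results)),
    sprintf("seeds: %s", paste(vapply(results, function(r) r$seed,
                                      numeric(1)), collapse = ",")),
    sprintf("wall_time: %s", format(Sys.time()))
  ), file.path(dir, "run.log"))
  invisible(dir)
}

#' Read a batch gcurves.csv back into a data.frame
#' @param path file written by [write_outputs()].
#' @return data.frame.
#' @export
read_gcurves <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Deterministic test fixtures
#'
#' Canned inputs with documented statistical structure so the chemistry
#' engine can be exercised without the physics surrogate:
#' \describe{
#'   \item{single_track}{one spur-surrogate track through the face centre,
#'     arrival at t = 0.}
#'   \item{two_close_tracks}{two parallel 1-ps species columns 50 nm apart
#'     through the volume centre (distinct track ids), for intertrack
#'     reaction tests.}
#'   \item{well_mixed_AB}{equal counts of two species `A` and `B`, uniform
#'     in the phantom.}
#'   \item{uniform_nonreacting}{`n` molecules of one species uniform in the
#'     phantom.}
#' }
#'
#' @param kind fixture kind (see above).
#' @param seed integer seed.
#' @param n molecule count per species (defaults per kind).
#' @param dir optional directory; when given, the fixture is also written as
#'   `fixture.csv` (track_id, species, x_um, y_um, z_um) plus a JSON sidecar
#'   `fixture.json` (arrival times, scored energy).
#' @return for track kinds a list of `track_deposit`s; for molecule kinds a
#'   data.frame `(species, x_um, y_um, z_um, track)`.
#' @export
make_fixture <- function(kind, seed = 1, n = NULL, dir = NULL) {
  set.seed(seed)
  beam <- beam_config(500)
  out <- switch(
    kind,
    single_track = {
      list(generate_track(c(1, 1), 0, beam, spur_model(), track_id = 1L))
    },
    two_close_tracks = {
      t1 <- generate_track(c(0.975, 1), 0, beam, spur_model(), track_id = 1L)
      t2 <- generate_track(c(1.025, 1), 0, beam, spur_model(), track_id = 2L)
      list(t1, t2)
    },
    well_mixed_AB = {
      if (is.null(n)) n <- 300
      data.frame(
        species = rep(c("A", "B"), each = n),
        x_um = runif(2 * n, 0, .BOX_L), y_um = runif(2 * n, 0, .BOX_L),
        z_um = runif(2 * n, 0, .BOX_L), track = rep(c(1L, 2L), each = n),
        stringsAsFactors = FALSE)
    },
    uniform_nonreacting = {
      if (is.null(n)) n <- 10000
      data.frame(
        species = rep("A", n),
        x_um = runif(n, 0, .BOX_L), y_um = runif(n, 0, .BOX_L),
        z_um = runif(n, 0, .BOX_L), track = rep(1L, n),
        stringsAsFactors = FALSE)
    },
    stop(sprintf("unknown fixture kind '%s'", kind))
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (is.data.frame(out)) {
      write.csv(cbind(track_id = out$track, out[, 1:4]),
                file.path(dir, "fixture.csv"), row.names = FALSE)
      jsonlite::write_json(list(kind = kind, seed = seed),
                           file.path(dir, "fixture.json"), auto_unbox = TRUE,
                           digits = NA)
    } else {
      rows <- do.call(rbind, lapply(out, function(tr) {
        if (nrow(tr$molecules) == 0) return(NULL)
        cbind(track_id = tr$track_id, tr$molecules)
      }))
      write.csv(rows, file.path(dir, "fixture.csv"), row.names = FALSE)
      jsonlite::write_json(
        list(kind = kind, seed = seed,
             arrival_time_s = vapply(out, function(tr) tr$arrival_time,
                                     numeric(1)),
             energy_eV = vapply(out, function(tr) tr$energy_eV, numeric(1))),
        file.path(dir, "fixture.json"), auto_unbox = TRUE, digits = NA)
    }
  }
  out
}

#' Read a track fixture written by [make_fixture()]
#'
#' @param csv_path fixture.csv path.
#' @param json_path fixture.json sidecar path.
#' @return list of `track_deposit`s consumable by the chemistry engine.
#' @export
read_track_fixture <- function(csv_path, json_path) {
  rows <- read.csv(csv_path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  ids <- sort(unique(rows$track_id))
  lapply(seq_along(ids), function(i) {
    sub <- rows[rows$track_id == ids[i], , drop = FALSE]
    structure(list(
      track_id = ids[i],
      arrival_time = meta$arrival_time_s[i],
      deposits = NULL,
      molecules = sub[, c("species", "x_um", "y_um", "z_um")],
      energy_eV = meta$energy_eV[i]
    ), class = "track_deposit")
  })
}
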