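# Scenario orchestration: configuration, seed splitting, and the full
# sequential-irradiation simulation (schedule -> track injection -> SBS
# chemistry loop -> scored time series).

#' Deterministic seed splitting
#'
#' Expands one root seed into independent substream seeds (schedule/tracks,
#' chemistry, ensemble members) with a counter-based linear-congruential
#' rule. All results stay below 2^31.
#'
#' @param root integer root seed.
#' @param counter integer substream index (>= 0).
#' @return integer seed.
#' @export
derive_seed <- function(root, counter) {
  a <- (as.double(root) %% 2147483647) + 1
  s <- (a * 48271 + as.double(counter) * 1103515245 + 12345) %% 2147483647
  as.integer(s)
}

#' Logarithmic output-time grid
#'
#' @param t_min_s,t_max_s grid bounds in s.
#' @param per_decade points per decade.
#' @param eval_times_s extra times always included (clipped to the bounds).
#' @return sorted unique numeric vector.
#' @export
log_time_grid <- function(t_min_s = 1e-12, t_max_s = 1000, per_decade = 8,
                          eval_times_s = c(1e-6, 1e-3, 1e-2, 1e-1)) {
  g <- 10^seq(log10(t_min_s), log10(t_max_s), by = 1 / per_decade)
  extra <- eval_times_s[eval_times_s >= t_min_s & eval_times_s <= t_max_s]
  sort(unique(c(g, extra, t_max_s)))
}

#' Configuration of one irradiation + chemistry scenario
#'
#' Bundles the beam, chemistry system, spur surrogate, oxygenation, stepping
#' and output settings that define a run. Output times are relative to the
#' first proton arrival.
#'
#' @param dose_rate_gy_s dose rate, Gy/s.
#' @param target_dose_gy stopping dose, Gy (default 10).
#' @param pO2_percent dissolved oxygen, percent of atmosphere (25 oxygenated,
#'   0 deoxygenated).
#' @param horizon_s chemistry tracking horizon after the first arrival, s
#'   (default 1000).
#' @param chem a [chemistry_system()].
#' @param spur a [spur_model()].
#' @param beam optional [beam_config()]; built from the dose rate otherwise.
#' @param schedule a [step_schedule()].
#' @param out_times_s output grid relative to the first arrival; default
#'   log-spaced from 1 ps to the horizon with the standard evaluation times
#'   (1 us, 1/10/100 ms) included.
#' @param snapshot_times_s times (relative) at which full spatial snapshots
#'   are recorded.
#' @param avg_volume_um3 oxygen averaging volume, um^3 (1 = irradiation
#'   volume; 8 = whole phantom).
#' @param box_L phantom edge, um.
#' @param wm_frac well-mixed switch: a second-order channel whose candidate
#'   search radius exceeds `wm_frac * box_L` is sampled from the equivalent
#'   mass-action law.
#' @param log_events whether to keep the per-reaction event log.
#' @return object of class `run_config`.
#' @export
scenario_config <- function(dose_rate_gy_s, target_dose_gy = 10,
                            pO2_percent = 25, horizon_s = 1000,
                            chem = default_chemistry(), spur = spur_model(),
                            beam = NULL, schedule = step_schedule(),
                            out_times_s = NULL,
                            snapshot_times_s = numeric(0),
                            avg_volume_um3 = .IV_VOLUME_UM3, box_L = .BOX_L,
                            wm_frac = 0.5, log_events = TRUE) {
  if (is.null(beam)) beam <- beam_config(dose_rate_gy_s, target_dose_gy)
  stopifnot(inherits(chem, "chem_system"), inherits(spur, "spur_model"),
            pO2_percent >= 0, horizon_s > 0, avg_volume_um3 > 0)
  if (is.null(out_times_s))
    out_times_s <- log_time_grid(1e-12, horizon_s)
  out_times_s <- sort(unique(out_times_s[out_times_s <= horizon_s]))
  structure(list(
    beam = beam, chem = chem, spur = spur,
    pO2_percent = pO2_percent, horizon_s = horizon_s,
    schedule = schedule, out_times_s = out_times_s,
    snapshot_times_s = sort(snapshot_times_s),
    avg_volume_um3 = avg_volume_um3, box_L = box_L,
    wm_frac = wm_frac, log_events = log_events
  ), class = "run_config")
}

# Pair-distance distribution of two independent uniform points in a cube of
# edge L: f(r) = (4 pi r^2 / V) * <prod_i (1 - r|u_i|/L)+>_directions,
# evaluated by deterministic spherical quadrature and discretised into bin
# weights. Used by the engine's mixed-regime branch to average the
# free-space GFDE probability over partner distances.
.pair_distance_weights <- function(box_L = .BOX_L, nbins = 240, ndir = 400) {
  # Fibonacci sphere directions (deterministic)
  i <- seq_len(ndir) - 0.5
  phi <- acos(1 - 2 * i / ndir)
  theta <- pi * (1 + sqrt(5)) * i
  u <- abs(cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi)))
  rmax <- sqrt(3) * box_L
  edges <- seq(0, rmax, length.out = nbins + 1)
  r <- (edges[-1] + edges[-(nbins + 1)]) / 2
  cbar <- vapply(r, function(ri) {
    ov <- (1 - ri * u[, 1] / box_L) * (1 - ri * u[, 2] / box_L) *
      (1 - ri * u[, 3] / box_L)
    ok <- ri * u[, 1] < box_L & ri * u[, 2] < box_L & ri * u[, 3] < box_L
    mean(ifelse(ok, ov, 0))
  }, numeric(1))
  w <- r^2 * cbar
  list(r = r, w = w / sum(w))
}

.pd_cache <- new.env(parent = emptyenv())

pair_distance_weights <- function(box_L = .BOX_L) {
  key <- sprintf("%.12g", box_L)
  if (is.null(.pd_cache[[key]]))
    .pd_cache[[key]] <- .pair_distance_weights(box_L)
  .pd_cache[[key]]
}

# Convert the chemistry system + engine inputs into the compiled kernel call.
# `tracks` is a list of track_deposit objects; `molecules` an optional
# initial molecule data.frame (species, x_um, y_um, z_um[, track]).
run_chemistry_engine <- function(chem, molecules = NULL, tracks = list(),
                                 pO2_uM = 0, t_start = 0, t_end,
                                 schedule = step_schedule(),
                                 out_times = numeric(0),
                                 snap_times = numeric(0),
                                 avg_volume_um3 = .IV_VOLUME_UM3,
                                 box_L = .BOX_L, wm_frac = 1,
                                 log_events = TRUE) {
  sp_id <- chem$sp_id
  cont <- chem$species$representation == "continuum"
  if (nrow(chem$pfo) > 0) {
    bad <- chem$pfo$r2 != "O2"
    if (any(bad))
      stop("only dissolved O2 is supported as a continuum scavenger (reaction ",
           chem$pfo$label[bad][1], ")")
  }
  sid <- function(nm) unname(sp_id[nm])
  if (is.null(molecules)) {
    molecules <- data.frame(species = character(0), x_um = numeric(0),
                            y_um = numeric(0), z_um = numeric(0))
  }
  mtrk <- if ("track" %in% names(molecules)) as.integer(molecules$track)
          else rep(0L, nrow(molecules))

  arr_t <- vapply(tracks, function(tr) tr$arrival_time, numeric(1))
  ord <- order(arr_t)
  tracks <- tracks[ord]; arr_t <- arr_t[ord]
  arr_sp <- lapply(tracks, function(tr) as.integer(sid(tr$molecules$species)))
  arr_x <- lapply(tracks, function(tr) tr$molecules$x_um)
  arr_y <- lapply(tracks, function(tr) tr$molecules$y_um)
  arr_z <- lapply(tracks, function(tr) tr$molecules$z_um)
  arr_trk <- vapply(tracks, function(tr) as.integer(tr$track_id), integer(1))
  arr_e <- vapply(tracks, function(tr) tr$energy_eV, numeric(1))

  so <- chem$so
  pd <- pair_distance_weights(box_L)
  res <- cpp_run_chemistry(
    init_sp = as.integer(sid(molecules$species)),
    init_x = molecules$x_um, init_y = molecules$y_um, init_z = molecules$z_um,
    init_trk = mtrk,
    D_um2s = chem$species$D_m2s * 1e12, continuum = cont,
    so_a = as.integer(sid(so$r1)), so_b = as.integer(sid(so$r2)),
    so_R_um = so$R_eff_nm * 1e-3, so_Dmut_um2s = so$D_mutual_m2s * 1e12,
    so_k = so$k_pair, so_prod = chem$so_prod,
    pfo_sp = as.integer(sid(chem$pfo$r1)), pfo_k = chem$pfo$k,
    pfo_prod = chem$pfo_prod,
    o2_uM = pO2_uM, avg_volume_um3 = avg_volume_um3,
    arr_time = arr_t, arr_sp = arr_sp, arr_x = arr_x, arr_y = arr_y,
    arr_z = arr_z, arr_trk = arr_trk, arr_energy_eV = arr_e,
    t_start = t_start, t_end = t_end,
    sched_bp = schedule$breakpoints$elapsed_s,
    sched_dt_s = schedule$breakpoints$dt_s,
    box_L = box_L, wm_frac = wm_frac,
    pd_r = pd$r, pd_w = pd$w,
    out_times = out_times, snap_times = snap_times,
    log_events = log_events, max_molecules = 5e6
  )
  colnames(res$out_counts) <- chem$species$name
  labels <- c(so$label, chem$pfo$label)
  ev <- res$events
  res$events <- data.frame(
    reaction = labels[ev$reaction + 1L],
    time_s = ev$time_s, track_a = ev$track_a, track_b = ev$track_b,
    intertrack = ev$track_b >= 0 & ev$track_a != ev$track_b,
    stringsAsFactors = FALSE
  )
  fin <- res$final
  res$final <- data.frame(
    species = chem$species$name[fin$sp + 1L],
    x_um = fin$x_um, y_um = fin$y_um, z_um = fin$z_um, track = fin$track,
    stringsAsFactors = FALSE
  )
  res
}

#' Run one sequential proton-irradiation scenario
#'
#' Samples the proton arrival schedule (Poisson arrivals, uniform entry
#' positions, stopping when the realized scored dose reaches the target),
#' generates a spur-surrogate track per arrival, and drives the SBS
#' diffusion-reaction loop to `horizon_s` after the first arrival. Fully
#' deterministic given `seed`; schedule/track sampling and chemistry use
#' independent substreams derived from it.
#'
#' @param config a [scenario_config()].
#' @param seed integer root seed.
#' @return object of class `scenario_result` with elements `gcurve`
#'   (long data.frame: time_s relative to first arrival, species, count,
#'   g_value), `counts` (wide matrix), `o2` (data.frame time_s, o2_uM,
#'   dose_gy), `events`, `schedule`, `snapshots`, `final`, `n_tracks`,
#'   `n_tracks_injected`, `edep_eV`, `o2_generated`, `o2_consumed`, `seed`.
#' @export
run_scenario <- function(config, seed) {
  stopifnot(inherits(config, "run_config"))
  beam <- config$beam; spur <- config$spur

  # substream 1: schedule + tracks (cached as the schedule is sampled)
  set.seed(derive_seed(seed, 1))
  cache <- new.env()
  cache$tracks <- list()
  base_model <- track_energy_model(spur, beam)
  model <- function(x_um, y_um) {
    id <- length(cache$tracks) + 1L
    tr <- generate_track(c(x_um, y_um), NA_real_, beam, spur, track_id = id)
    cache$tracks[[id]] <- tr
    tr$energy_eV
  }
  attr(model, "mean_dose_gy") <- attr(base_model, "mean_dose_gy")
  sched <- sample_schedule(beam, model)
  tracks <- cache$tracks
  for (i in seq_along(tracks)) tracks[[i]]$arrival_time <- sched$time_s[i]

  t_first <- sched$time_s[1]
  t_end <- t_first + config$horizon_s
  use <- vapply(tracks, function(tr) tr$arrival_time <= t_end, logical(1))

  # substream 2: chemistry
  set.seed(derive_seed(seed, 2))
  res <- run_chemistry_engine(
    chem = config$chem, tracks = tracks[use],
    pO2_uM = pO2_to_uM(config$pO2_percent),
    t_start = t_first, t_end = t_end,
    schedule = config$schedule,
    out_times = t_first + config$out_times_s,
    snap_times = t_first + config$snapshot_times_s,
    avg_volume_um3 = config$avg_volume_um3,
    box_L = config$box_L, wm_frac = config$wm_frac,
    log_events = config$log_events
  )

  counts <- res$out_counts
  rel_t <- config$out_times_s
  edep <- res$out_edep_eV
  point <- config$chem$species$representation == "point_tracked"
  gc <- data.frame(
    time_s = rep(rel_t, times = sum(point)),
    species = rep(colnames(counts)[point], each = length(rel_t)),
    count = as.vector(counts[, point, drop = FALSE]),
    stringsAsFactors = FALSE
  )
  gc$g_value <- ifelse(rep(edep, sum(point)) > 0,
                       100 * gc$count / rep(edep, sum(point)), NA_real_)
  res$events$time_s <- res$events$time_s - t_first

  structure(list(
    gcurve = gc,
    counts = counts,
    o2 = data.frame(time_s = rel_t, o2_uM = res$out_o2_uM,
                    dose_gy = dose_from_energy(edep), edep_eV = edep),
    events = res$events,
    schedule = sched,
    snapshots = res$snapshots,
    final = res$final,
    n_tracks = nrow(sched),
    n_tracks_injected = res$n_injected_tracks,
    edep_eV = res$edep_eV,
    o2_uM_final = res$o2_uM,
    o2_generated = res$o2_generated,
    o2_consumed = res$o2_consumed,
    t_first_s = t_first,
    seed = seed
  ), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf(
    "<scenario_result> %d tracks (%d injected), %.0f eV scored (%.2f Gy), horizon output %d times\n",
    x$n_tracks, x$n_tracks_injected, x$edep_eV,
    dose_from_energy(x$edep_eV), nrow(x$o2)))
  invisible(x)
}

#' Run an ensemble of independent scenarios
#'
#' @param config a [scenario_config()].
#' @param n number of scenarios.
#' @param root_seed root seed; member i uses `derive_seed(root_seed, 100 + i)`.
#' @param extract optional `function(result)` applied to each scenario
#'   (memory saver); the raw results are returned otherwise.
#' @return list of length n.
#' @export
run_ensemble <- function(config, n, root_seed, extract = NULL) {
  lapply(seq_len(n), function(i) {
    r <- run_scenario(config, derive_seed(root_seed, 100 + i))
    if (is.null(extract)) r else extract(r)
  })
}
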