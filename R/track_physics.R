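# Parametric spur surrogate for the track-structure physics stage: converts
# one proton traversal of the irradiation volume into energy-deposition
# events and radiolysis species placed at 1 ps.

#' Spur-model parameters for the physics surrogate
#'
#' A proton crossing the 1 um irradiation volume deposits its LET as a
#' Poisson sequence of spurs (localized ionisation/excitation clusters) along
#' z. Spur energies are exponential with mean `mean_spur_energy_eV`; species
#' are placed isotropically Gaussian (`spur_sigma_nm`) around each spur
#' centre with per-species 1-ps yields `initial_yields` (species per 100 eV).
#' Tracks entering near the lateral edge of the irradiation volume lose the
#' escape-kernel fraction f(d) = f0 * exp(-d / escape_length_um) of each
#' spur's energy and species, where d is the lateral distance to the nearest
#' face boundary; this emulates secondary electrons leaving the volume.
#'
#' Defaults are calibrated so that (a) the mean number of tracks needed for
#' 10 Gy is ~71 (versus the analytic no-escape value ~54) and (b) the
#' hydrated-electron yield 1 us after a track is ~2.5 per 100 eV; see the
#' methods vignette and [calibrate_escape_length()].
#'
#' @param mean_spur_energy_eV mean spur energy in eV (default 47).
#' @param spur_sigma_nm Gaussian spread of species around a spur centre, nm.
#'   Applies to the species born at the ionisation/excitation core (OH,
#'   H3O+, H, H2).
#' @param electron_sigma_nm placement spread of hydrated electrons, nm.
#'   Electrons thermalise several nm away from their parent ionisation, so
#'   their spread exceeds the core width; both widths are calibrated against
#'   the standard 1-us escape yields of e_aq and OH.
#' @param escape_f0 escape fraction at the boundary itself, in `[0, 1]`.
#' @param escape_length_um decay length of the escape kernel, um.
#' @param initial_yields named vector of 1-ps yields, species per 100 eV.
#' @return object of class `spur_model`.
#' @export
spur_model <- function(mean_spur_energy_eV = 47,
                       spur_sigma_nm = 0.9,
                       electron_sigma_nm = 2.2,
                       escape_f0 = 1,
                       escape_length_um = 0.0705,
                       initial_yields = c("e_aq" = 4.8, "OH" = 5.6,
                                          "H" = 0.62, "H2" = 0.15,
                                          "H3O+" = 4.8)) {
  stopifnot(mean_spur_energy_eV > 0, spur_sigma_nm > 0,
            electron_sigma_nm > 0,
            escape_f0 >= 0, escape_f0 <= 1, escape_length_um > 0,
            all(initial_yields >= 0), !is.null(names(initial_yields)))
  structure(list(
    mean_spur_energy_eV = mean_spur_energy_eV,
    spur_sigma_nm = spur_sigma_nm,
    electron_sigma_nm = electron_sigma_nm,
    escape_f0 = escape_f0,
    escape_length_um = escape_length_um,
    initial_yields = initial_yields
  ), class = "spur_model")
}

#' Escape fraction of a track entering at a given face position
#'
#' @param model a [spur_model()].
#' @param x_um,y_um entry coordinates on the irradiation face (um, phantom
#'   frame; the face spans `[0.5, 1.5]`).
#' @return fraction of spur energy/species escaping, in `[0, 1]`.
#' @export
escape_fraction <- function(model, x_um, y_um) {
  d <- pmax(0, pmin(x_um - .IV_LO, .IV_HI - x_um,
                    y_um - .IV_LO, .IV_HI - y_um))
  pmin(1, model$escape_f0 * exp(-d / model$escape_length_um))
}

#' Mean escape fraction over a uniformly irradiated face
#'
#' Integrates the escape kernel against the distribution of the distance to
#' the nearest face edge for a uniform entry point (density 4(1-2d) on
#' `[0, 1/2]` um).
#'
#' @param model a [spur_model()].
#' @return mean escape fraction.
#' @export
mean_escape_fraction <- function(model) {
  f <- function(d) model$escape_f0 * exp(-d / model$escape_length_um) *
    4 * (1 - 2 * d)
  integrate(f, 0, 0.5, rel.tol = 1e-10)$value
}

#' Per-track deposited-energy model for schedule sampling
#'
#' Returns a callable `function(x_um, y_um)` that samples the total
#' non-escaped energy (eV) deposited by one track entering at the given face
#' position, using the spur statistics only (no chemistry, no species
#' placement). The analytic mean dose per track is attached as attribute
#' `mean_dose_gy` so [sample_schedule()] can fix its Poisson rate without
#' Monte Carlo.
#'
#' @param model a [spur_model()].
#' @param beam a [beam_config()].
#' @return callable with attribute `mean_dose_gy`.
#' @export
track_energy_model <- function(model, beam) {
  let_eV <- beam$let_kev_um * 1e3            # eV per um of path; path = 1 um
  dens <- let_eV / model$mean_spur_energy_eV # spurs per track
  fn <- function(x_um, y_um) {
    n <- rpois(1, dens)
    if (n == 0) return(0)
    e <- rexp(n, 1 / model$mean_spur_energy_eV)
    sum(e) * (1 - escape_fraction(model, x_um, y_um))
  }
  fbar <- mean_escape_fraction(model)
  attr(fn, "mean_dose_gy") <- dose_from_energy(let_eV * (1 - fbar))
  fn
}

#' Poisson 1-ps species counts for a deposited energy
#'
#' Independent Poisson draws with mean G0(s) * E / 100 per species.
#'
#' @param E_eV deposited energy, eV (>= 0).
#' @param yields named vector of 1-ps yields (species per 100 eV).
#' @return named integer vector of counts.
#' @export
initial_species_counts <- function(E_eV, yields) {
  if (length(E_eV) != 1 || !is.finite(E_eV) || E_eV < 0)
    stop("E_eV must be a single non-negative number")
  setNames(rpois(length(yields), yields * E_eV / 100), names(yields))
}

#' Generate one proton track: deposits and 1-ps species placements
#'
#' Spur centres are a Poisson process along z across the irradiation volume
#' with linear density LET / mean spur energy; spur energies are exponential;
#' species counts per spur are Poisson with mean G0(s) * E_kept / 100 where
#' E_kept is the spur energy after the lateral escape kernel; positions are
#' isotropic Gaussians around the spur centre, mirror-folded into the
#' phantom. Escaped energy is recorded as deposits flagged `escaped` and is
#' excluded from the scored energy and from the molecule list.
#'
#' @param entry_xy numeric length-2, entry position (um) on the face.
#' @param arrival_time arrival time in s.
#' @param beam a [beam_config()].
#' @param model a [spur_model()].
#' @param seed optional integer seed.
#' @param track_id integer id stamped on the molecules.
#' @return list of class `track_deposit`: `track_id`, `arrival_time`,
#'   `deposits` (data.frame x_um, y_um, z_um, energy_eV, escaped),
#'   `molecules` (data.frame species, x_um, y_um, z_um), `energy_eV`
#'   (total non-escaped energy).
#' @export
generate_track <- function(entry_xy, arrival_time, beam, model,
                           seed = NULL, track_id = 1L) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(entry_xy) == 2)
  let_eV <- beam$let_kev_um * 1e3
  dens <- let_eV / model$mean_spur_energy_eV
  n <- rpois(1, dens)
  f <- escape_fraction(model, entry_xy[1], entry_xy[2])
  if (n == 0) {
    return(structure(list(
      track_id = track_id, arrival_time = arrival_time,
      deposits = data.frame(x_um = numeric(0), y_um = numeric(0),
                            z_um = numeric(0), energy_eV = numeric(0),
                            escaped = logical(0)),
      molecules = data.frame(species = character(0), x_um = numeric(0),
                             y_um = numeric(0), z_um = numeric(0)),
      energy_eV = 0
    ), class = "track_deposit"))
  }
  z <- runif(n, .IV_LO, .IV_HI)
  e <- rexp(n, 1 / model$mean_spur_energy_eV)
  kept <- e * (1 - f)

  dep <- data.frame(x_um = entry_xy[1], y_um = entry_xy[2], z_um = z,
                    energy_eV = kept, escaped = FALSE)
  if (f > 0) {
    dep <- rbind(dep, data.frame(x_um = entry_xy[1], y_um = entry_xy[2],
                                 z_um = z, energy_eV = e * f, escaped = TRUE))
  }

  yields <- model$initial_yields
  sp_out <- character(0); xo <- numeric(0); yo <- numeric(0); zo <- numeric(0)
  counts <- matrix(rpois(n * length(yields),
                         outer(kept / 100, yields)),
                   nrow = n)
  for (j in seq_along(yields)) {
    tot <- sum(counts[, j])
    if (tot == 0) next
    sig <- if (names(yields)[j] == "e_aq") model$electron_sigma_nm * 1e-3
           else model$spur_sigma_nm * 1e-3
    zc <- rep(z, counts[, j])
    sp_out <- c(sp_out, rep(names(yields)[j], tot))
    xo <- c(xo, reflect(entry_xy[1] + rnorm(tot, 0, sig)))
    yo <- c(yo, reflect(entry_xy[2] + rnorm(tot, 0, sig)))
    zo <- c(zo, reflect(zc + rnorm(tot, 0, sig)))
  }
  structure(list(
    track_id = track_id, arrival_time = arrival_time,
    deposits = dep,
    molecules = data.frame(species = sp_out, x_um = xo, y_um = yo, z_um = zo,
                           stringsAsFactors = FALSE),
    energy_eV = sum(kept)
  ), class = "track_deposit")
}

#' Calibrate the escape-kernel length to a target mean track count
#'
#' Solves for the escape length such that the expected number of tracks
#' needed to accumulate the target dose matches `target_tracks` (the mean
#' arrival count including the stopping-rule overshoot of about half a
#' track), using the analytic mean escape fraction.
#'
#' @param target_tracks desired mean arrivals per scenario (default 71).
#' @param beam a [beam_config()]; default 500 Gy/s, 10 Gy.
#' @param model a [spur_model()] supplying f0 and spur statistics.
#' @return escape length in um.
#' @export
calibrate_escape_length <- function(target_tracks = 71,
                                    beam = beam_config(500),
                                    model = spur_model()) {
  let_eV <- beam$let_kev_um * 1e3
  # E[N] for a renewal process stopped at target: ~ target/mean + 1/2
  need_mean_dose <- beam$target_dose_gy / (target_tracks - 0.5)
  fbar_target <- 1 - need_mean_dose / dose_from_energy(let_eV)
  if (fbar_target <= 0) return(1e-9)
  obj <- function(len) {
    m <- model; m$escape_length_um <- len
    mean_escape_fraction(m) - fbar_target
  }
  stats::uniroot(obj, c(1e-4, 0.5), tol = 1e-8)$root
}
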