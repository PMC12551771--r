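# Beam configuration, dose/fluence accounting, and proton arrival schedules.

#' Beam configuration for sequential proton irradiation
#'
#' Describes one irradiation scenario: dose rate, target dose, proton LET,
#' irradiated face area and medium density. The pulse duration is derived as
#' t_p = D / dose_rate.
#'
#' @param dose_rate_gy_s dose rate in Gy/s (> 0).
#' @param target_dose_gy total absorbed dose in Gy (> 0); default 10.
#' @param let_kev_um proton LET in keV/um; default 1.169 (55 MeV protons).
#' @param area_um2 irradiated face area in um^2; default 1.
#' @param rho_g_cm3 medium density in g/cm^3; default 1.
#' @param t_min_s lower bound of the arrival window in s; default 1 ps.
#' @return object of class `beam_config` with derived field `t_p_s`.
#' @export
#' @examples
#' beam_config(500)$t_p_s # 0.02 s
beam_config <- function(dose_rate_gy_s, target_dose_gy = 10,
                        let_kev_um = 1.169, area_um2 = 1,
                        rho_g_cm3 = 1, t_min_s = 1e-12) {
  for (v in c(dose_rate_gy_s, target_dose_gy, let_kev_um, area_um2, rho_g_cm3))
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("all beam parameters must be positive finite scalars")
  structure(list(
    dose_rate_gy_s = dose_rate_gy_s,
    target_dose_gy = target_dose_gy,
    let_kev_um = let_kev_um,
    area_um2 = area_um2,
    rho_g_cm3 = rho_g_cm3,
    t_min_s = t_min_s,
    t_p_s = pulse_duration(target_dose_gy, dose_rate_gy_s)
  ), class = "beam_config")
}

#' Pulse duration t_p = D / dose rate
#'
#' @param D_gy total absorbed dose, Gy (>= 0).
#' @param dose_rate_gy_s dose rate, Gy/s (> 0).
#' @return duration in seconds.
#' @export
#' @examples
#' pulse_duration(10, 500)  # 0.02 s
#' pulse_duration(10, 0.02) # 500 s
pulse_duration <- function(D_gy, dose_rate_gy_s) {
  stopifnot(is.numeric(D_gy), is.numeric(dose_rate_gy_s))
  if (any(dose_rate_gy_s <= 0)) stop("dose rate must be > 0")
  if (any(D_gy < 0)) stop("dose must be >= 0")
  D_gy / dose_rate_gy_s
}

#' Analytic proton count for a target dose
#'
#' N_p = D * A * rho / LET with units resolved (Gy = J/kg, keV -> J,
#' um -> m). For D = 10 Gy, A = 1 um^2, rho = 1 g/cm^3 and
#' LET = 1.169 keV/um this gives about 53.4, i.e. ~54 protons.
#'
#' @param D_gy dose in Gy.
#' @param area_um2 face area in um^2.
#' @param rho_g_cm3 density in g/cm^3.
#' @param let_kev_um LET in keV/um.
#' @return expected proton count (real-valued).
#' @export
protons_for_dose <- function(D_gy, area_um2 = 1, rho_g_cm3 = 1,
                             let_kev_um = 1.169) {
  for (v in list(D_gy, area_um2, rho_g_cm3, let_kev_um))
    if (any(v <= 0)) stop("all arguments must be > 0")
  A_m2 <- area_um2 * 1e-12
  rho_kg_m3 <- rho_g_cm3 * 1e3
  let_J_m <- let_kev_um * 1e3 * .EV_JOULE / 1e-6
  D_gy * A_m2 * rho_kg_m3 / let_J_m
}

#' Absorbed dose from deposited energy
#'
#' @param E_dep_eV deposited energy in eV (>= 0).
#' @param mass_kg scoring mass in kg (> 0); default the 1 um^3 irradiation
#'   volume of unit-density water (1e-15 kg).
#' @return dose in Gy.
#' @export
#' @examples
#' dose_from_energy(6.242e4) # ~10 Gy
dose_from_energy <- function(E_dep_eV, mass_kg = .IV_MASS_KG) {
  stopifnot(is.numeric(E_dep_eV))
  if (any(E_dep_eV < 0)) stop("deposited energy must be >= 0")
  if (any(mass_kg <= 0)) stop("mass must be > 0")
  E_dep_eV * .EV_JOULE / mass_kg
}

#' Sample a proton arrival schedule
#'
#' Arrival times form a homogeneous Poisson process (exponential
#' inter-arrival times) starting at `t_min`, with rate chosen so the expected
#' cumulative dose over the pulse duration t_p equals the target dose.
#' Sampling continues until the cumulative estimated dose reaches the target
#' (edge tracks deposit less, so schedules typically contain more arrivals
#' than the analytic proton count). Entry positions are i.i.d. uniform on the
#' 1 x 1 um irradiated face.
#'
#' @param beam a [beam_config()].
#' @param dose_per_track_model callable `function(x_um, y_um)` returning a
#'   sampled deposited energy (eV) for a track entering at that position; see
#'   [track_energy_model()]. If it carries a `mean_dose_gy` attribute that
#'   value fixes the Poisson rate, otherwise the mean is estimated from 200
#'   draws.
#' @param seed optional integer seed (set before sampling).
#' @return data.frame `(index, time_s, x_um, y_um)` of class
#'   `irradiation_schedule`, with attributes `dose_gy` (per-track dose) and
#'   `energy_eV`.
#' @export
sample_schedule <- function(beam, dose_per_track_model, seed = NULL) {
  stopifnot(inherits(beam, "beam_config"))
  if (!is.null(seed)) set.seed(seed)
  mean_dose <- attr(dose_per_track_model, "mean_dose_gy")
  if (is.null(mean_dose)) {
    probe <- replicate(200, {
      dose_per_track_model(runif(1, .IV_LO, .IV_HI), runif(1, .IV_LO, .IV_HI))
    })
    mean_dose <- dose_from_energy(mean(probe))
  }
  if (!is.finite(mean_dose) || mean_dose <= 0)
    stop("dose_per_track_model has non-positive mean dose; schedule cannot terminate")
  rate <- beam$target_dose_gy / (mean_dose * beam$t_p_s)

  times <- numeric(0); xs <- numeric(0); ys <- numeric(0); en <- numeric(0)
  t <- beam$t_min_s
  cum <- 0
  while (cum < beam$target_dose_gy) {
    t <- t + rexp(1, rate)
    x <- runif(1, .IV_LO, .IV_HI)
    y <- runif(1, .IV_LO, .IV_HI)
    e <- dose_per_track_model(x, y)
    times <- c(times, t); xs <- c(xs, x); ys <- c(ys, y); en <- c(en, e)
    cum <- cum + dose_from_energy(e)
  }
  out <- data.frame(index = seq_along(times), time_s = times,
                    x_um = xs, y_um = ys)
  attr(out, "energy_eV") <- en
  attr(out, "dose_gy") <- dose_from_energy(en)
  attr(out, "beam") <- beam
  class(out) <- c("irradiation_schedule", "data.frame")
  out
}
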