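# Observables: G values, dose-rate dependence, ensemble statistics and
# oxygen-depletion metrics.

#' Radiation chemical yield (G value)
#'
#' Number of molecules produced or lost per 100 eV of deposited energy:
#' G = 100 N / E_dep.
#'
#' @param N molecule count (>= 0).
#' @param E_dep_eV deposited energy, eV (> 0).
#' @return species per 100 eV.
#' @export
#' @examples
#' g_value(1561, 6.242e4) # ~2.5
g_value <- function(N, E_dep_eV) {
  stopifnot(all(N >= 0))
  if (any(E_dep_eV <= 0)) stop("E_dep must be > 0")
  100 * N / E_dep_eV
}

#' Per-scenario G value of a species at an evaluation time
#'
#' @param result a `scenario_result`.
#' @param species species name.
#' @param time_s evaluation time (relative to the first arrival); must be on
#'   the scenario's output grid.
#' @return G value (species per 100 eV).
#' @export
scenario_g <- function(result, species, time_s) {
  gc <- result$gcurve
  i <- which(gc$species == species &
               abs(gc$time_s - time_s) <= 1e-9 * max(time_s, 1e-12))
  if (length(i) == 0)
    stop(sprintf("time %g s is not on the output grid", time_s))
  gc$g_value[i[1]]
}

#' Ensemble G values at an evaluation time
#'
#' @param results list of `scenario_result`s (or of values returned by an
#'   `extract` that kept `gcurve`).
#' @param species species name.
#' @param time_s evaluation time, s.
#' @return numeric vector of per-scenario G values.
#' @export
ensemble_g <- function(results, species, time_s) {
  vapply(results, scenario_g, numeric(1), species = species, time_s = time_s)
}

#' Ensemble summary statistics of a G value
#'
#' Unbiased mean and SD across independent scenarios, with the relative SD
#' in percent.
#'
#' @param values numeric vector of per-scenario G values (length >= 2 for a
#'   SD).
#' @return list `mean`, `sd`, `rel_sd_pct`, `n`.
#' @export
#' @examples
#' ensemble_stats(c(2.4, 2.5, 2.6)) # mean 2.5, sd 0.1
ensemble_stats <- function(values) {
  n <- length(values)
  if (n < 2) stop("at least 2 scenarios are required for an SD")
  m <- mean(values)
  s <- sd(values)
  list(mean = m, sd = s, rel_sd_pct = 100 * s / m, n = n)
}

#' Relative G values versus dose rate
#'
#' Normalizes the ensemble-mean G value at each dose rate to the value at
#' the reference (lowest) dose rate, at a common evaluation time.
#'
#' @param g_means named numeric vector of ensemble-mean G values; names are
#'   dose rates in Gy/s.
#' @param reference_rate reference dose rate (must be present).
#' @return named numeric vector of ratios (reference maps to 1).
#' @export
relative_g <- function(g_means, reference_rate) {
  ref <- as.character(reference_rate)
  if (!ref %in% names(g_means))
    stop("reference dose rate not present")
  if (!is.finite(g_means[[ref]]) || g_means[[ref]] == 0)
    stop("reference mean G is zero")
  g_means / g_means[[ref]]
}

#' Oxygen depletion rate per unit absorbed dose
#'
#' Ordinary least-squares slope of the spatially averaged oxygen
#' concentration versus absorbed dose, negated; also expressed in percent of
#' atmosphere per Gy via the Henry's-law conversion.
#'
#' @param series data.frame with columns `dose_gy` and `o2_uM` (>= 2 points,
#'   non-constant dose).
#' @return list `uM_per_gy`, `pct_per_gy`, `fit` (the lm object).
#' @export
o2_depletion_rate <- function(series) {
  stopifnot(is.data.frame(series), all(c("dose_gy", "o2_uM") %in% names(series)))
  if (nrow(series) < 2) stop("need at least 2 (dose, concentration) points")
  if (any(series$dose_gy < 0)) stop("doses must be nonnegative")
  if (diff(range(series$dose_gy)) == 0)
    stop("degenerate series: constant dose")
  fit <- lm(o2_uM ~ dose_gy, data = series)
  slope <- -unname(coef(fit)["dose_gy"])
  list(uM_per_gy = slope,
       pct_per_gy = uM_to_pO2(abs(slope)) * sign(slope),
       fit = fit)
}

#' Dose required for complete oxygen depletion (linear extrapolation)
#'
#' @param rate_pct_per_gy depletion rate in percent of atmosphere per Gy
#'   (> 0).
#' @param initial_pO2_percent starting oxygenation, percent.
#' @return dose in Gy.
#' @export
#' @examples
#' dose_to_depletion(0.028, 25) # ~893 Gy
dose_to_depletion <- function(rate_pct_per_gy, initial_pO2_percent) {
  if (length(rate_pct_per_gy) != 1 || rate_pct_per_gy <= 0)
    stop("depletion rate must be > 0")
  stopifnot(initial_pO2_percent >= 0)
  initial_pO2_percent / rate_pct_per_gy
}

#' Fraction of reaction events between species of different tracks
#'
#' @param events event data.frame from a `scenario_result` (pairwise events
#'   only; pseudo-first-order events carry no partner track and are
#'   excluded).
#' @param until_s optional upper time bound (relative to first arrival).
#' @return fraction in `[0, 1]`, or NA if there were no pairwise events.
#' @export
intertrack_fraction <- function(events, until_s = Inf) {
  ev <- events[events$track_b >= 0 & events$time_s <= until_s, , drop = FALSE]
  if (nrow(ev) == 0) return(NA_real_)
  mean(ev$intertrack)
}
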