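# Minimal chemistry systems and engine shortcuts shared across tests.

ab_chemistry <- function(k = 1e10, D = 5e-9) {
  sp <- data.frame(
    name = c("A", "B", "C"), D_m2s = D,
    representation = "point_tracked",
    nH = c(1, 1, 2), nO = 0, charge = 0, stringsAsFactors = FALSE)
  rx <- data.frame(label = "AB", r1 = "A", r2 = "B", p1 = "C", p2 = NA,
                   p3 = NA, k = k, type = "second_order",
                   stringsAsFactors = FALSE)
  chemistry_system(sp, rx)
}

# chemistry with a single species scavenged by continuum O2 only
scavenge_chemistry <- function(k = 1.48e10) {
  sp <- rbind(
    data.frame(name = "A", D_m2s = 4.9e-9, representation = "point_tracked",
               nH = 0, nO = 0, charge = -1),
    data.frame(name = "O2", D_m2s = 2.4e-9, representation = "continuum",
               nH = 0, nO = 2, charge = 0),
    data.frame(name = "P", D_m2s = 1.75e-9, representation = "point_tracked",
               nH = 0, nO = 2, charge = -1))
  rx <- data.frame(label = "scav", r1 = "A", r2 = "O2", p1 = "P", p2 = NA,
                   p3 = NA, k = k, type = "pseudo_first_order",
                   stringsAsFactors = FALSE)
  chemistry_system(sp, rx)
}

# inert single-species system (no reactions)
inert_chemistry <- function(D = 2.2e-9) {
  sp <- data.frame(name = "A", D_m2s = D, representation = "point_tracked",
                   nH = 1, nO = 1, charge = 0, stringsAsFactors = FALSE)
  rx0 <- data.frame(label = character(0), r1 = character(0), r2 = character(0),
                    p1 = character(0), p2 = character(0), p3 = character(0),
                    k = numeric(0), type = character(0),
                    stringsAsFactors = FALSE)
  chemistry_system(sp, rx0)
}

run_engine <- function(chem, molecules, t_end, dt = NULL, out_times = t_end,
                       pO2_uM = 0, schedule = NULL, seed = 1, ...) {
  if (is.null(schedule)) {
    schedule <- if (is.null(dt)) step_schedule()
                else step_schedule(breakpoints = data.frame(elapsed_s = 0,
                                                            dt_s = dt))
  }
  set.seed(seed)
  uhdrchem:::run_chemistry_engine(chem, molecules = molecules, pO2_uM = pO2_uM,
                                  t_start = 0, t_end = t_end,
                                  schedule = schedule, out_times = out_times,
                                  ...)
}
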