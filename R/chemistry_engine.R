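# R-level surface of the SBS diffusion-reaction engine: the elementary
# operations (documented, testable reference implementations) and the
# scenario orchestrator that drives the compiled kernel.

#' Time-step schedule (reset-then-grow ladder)
#'
#' After every proton arrival the step size is reset to `dt_min` to resolve
#' the fast intratrack chemistry, then grows geometrically with the time
#' elapsed since that arrival: one decade of elapsed time per step-size
#' decade, capped at `dt_cap`. A custom table of `(elapsed_s, dt_s)`
#' breakpoints may be supplied instead.
#'
#' @param dt_min_s smallest step, s (default 1 ps).
#' @param dt_cap_s largest step, s (default 0.1).
#' @param breakpoints optional data.frame `(elapsed_s, dt_s)`; first row must
#'   have `elapsed_s == 0`, `dt_s` positive and nondecreasing.
#' @return object of class `step_schedule`.
#' @export
step_schedule <- function(dt_min_s = 1e-12, dt_cap_s = 0.1,
                          breakpoints = NULL) {
  if (is.null(breakpoints)) {
    stopifnot(dt_min_s > 0, dt_cap_s >= dt_min_s)
    ks <- seq(ceiling(log10(dt_min_s * 10)), floor(log10(dt_cap_s)))
    breakpoints <- data.frame(
      elapsed_s = c(0, 10^ks),
      dt_s = c(dt_min_s, pmin(dt_cap_s, 10^ks))
    )
  }
  stopifnot(nrow(breakpoints) >= 1, breakpoints$elapsed_s[1] == 0,
            all(breakpoints$dt_s > 0), !is.unsorted(breakpoints$elapsed_s),
            !is.unsorted(breakpoints$dt_s))
  structure(list(breakpoints = breakpoints), class = "step_schedule")
}

#' Step size for a given elapsed time since the last proton arrival
#'
#' Returns the schedule's step for the elapsed-time bin, truncated so that
#' the step never crosses the next arrival.
#'
#' @param elapsed_s time since the last arrival, s (>= 0).
#' @param schedule a [step_schedule()].
#' @param time_to_next_arrival_s optional time until the next arrival, s.
#' @return step size in s.
#' @export
next_dt <- function(elapsed_s, schedule, time_to_next_arrival_s = NULL) {
  stopifnot(inherits(schedule, "step_schedule"), elapsed_s >= 0)
  bp <- schedule$breakpoints
  if (nrow(bp) == 0) stop("empty step schedule")
  dt <- bp$dt_s[findInterval(elapsed_s, bp$elapsed_s)]
  if (!is.null(time_to_next_arrival_s))
    dt <- min(dt, time_to_next_arrival_s)
  dt
}

#' Mirror-fold positions into the phantom (reflective boundary)
#'
#' Each coordinate is folded into `[0, L]` with period `2L` (method of
#' images), applied independently per axis. Interior points are unchanged.
#'
#' @param position numeric vector/matrix of coordinates (um).
#' @param box_L box edge length, um (default 2).
#' @return folded coordinates, same shape.
#' @export
#' @examples
#' reflect(c(-0.1, 2.3, 4.3)) # 0.1 1.7 0.3
reflect <- function(position, box_L = .BOX_L) {
  stopifnot(all(is.finite(position)))
  v <- position %% (2 * box_L)
  out <- ifelse(v > box_L, 2 * box_L - v, v)
  if (is.matrix(position)) dim(out) <- dim(position)
  out
}

#' One Brownian propagation step
#'
#' Displaces each molecule by an isotropic Gaussian with per-axis variance
#' 2 D dt, then mirror-folds back into the phantom.
#'
#' @param positions n x 3 matrix of positions (um).
#' @param D_m2s diffusion coefficient(s), m^2/s (length 1 or n).
#' @param dt_s step length, s (>= 0).
#' @param box_L box edge, um.
#' @return displaced n x 3 matrix.
#' @export
diffuse <- function(positions, D_m2s, dt_s, box_L = .BOX_L) {
  stopifnot(is.matrix(positions), ncol(positions) == 3, dt_s >= 0,
            all(D_m2s >= 0))
  n <- nrow(positions)
  sig_um <- sqrt(2 * D_m2s * 1e12 * dt_s)
  reflect(positions + matrix(rnorm(3 * n, 0, sig_um), n, 3), box_L)
}

#' GFDE pair reaction probability within one time step
#'
#' Probability that an isolated pair at separation r with encounter radius
#' R_eff and mutual diffusion coefficient D_mutual reacts within dt: 1 at or
#' inside contact, otherwise (R/r) * erfc((r - R) / (2 sqrt(D' dt))) - the
#' absorbing-boundary Green's-function solution.
#'
#' @param r_nm pair separation, nm (> 0).
#' @param R_eff_nm encounter radius, nm (>= 0).
#' @param D_mutual_m2s mutual diffusion coefficient, m^2/s (> 0).
#' @param dt_s time step, s (> 0).
#' @return reaction probability in `[0, 1]`.
#' @export
pair_reaction_probability <- function(r_nm, R_eff_nm, D_mutual_m2s, dt_s) {
  if (any(r_nm <= 0)) stop("pair separation r must be > 0")
  stopifnot(all(R_eff_nm >= 0), D_mutual_m2s > 0, dt_s > 0)
  s <- sqrt(D_mutual_m2s * dt_s) * 1e9  # diffusion length in nm
  erfc <- function(q) 2 * stats::pnorm(-q * sqrt(2))
  ifelse(r_nm <= R_eff_nm, 1,
         (R_eff_nm / r_nm) * erfc((r_nm - R_eff_nm) / (2 * s)))
}

#' Survival probability under pseudo-first-order scavenging
#'
#' @param k rate constant, M^-1 s^-1.
#' @param C_uM scavenger concentration, uM.
#' @param dt_s time step, s.
#' @return reaction probability 1 - exp(-k C dt).
#' @export
scavenging_probability <- function(k, C_uM, dt_s) {
  stopifnot(all(k >= 0), all(C_uM >= 0), all(dt_s >= 0))
  -expm1(-k * C_uM * 1e-6 * dt_s)
}

#' Continuum oxygen field
#'
#' @param pO2_percent initial dissolved oxygen as percent of atmosphere.
#' @param avg_volume_um3 averaging volume for concentration updates, um^3
#'   (default the 1 um^3 irradiation volume).
#' @return object of class `continuum_field` with fields `pO2_percent`,
#'   `pO2_uM`, `avg_volume_um3`, `n_generated`, `n_consumed`.
#' @export
continuum_field <- function(pO2_percent = 25, avg_volume_um3 = .IV_VOLUME_UM3) {
  stopifnot(pO2_percent >= 0, avg_volume_um3 > 0)
  structure(list(pO2_percent = pO2_percent,
                 pO2_uM = pO2_to_uM(pO2_percent),
                 avg_volume_um3 = avg_volume_um3,
                 n_generated = 0, n_consumed = 0),
            class = "continuum_field")
}

#' Update the spatially averaged oxygen concentration
#'
#' Applies the net molecule balance of one step:
#' delta [O2] = (n_generated - n_consumed) / (N_A V), clamped at zero.
#'
#' @param field a [continuum_field()].
#' @param n_generated,n_consumed event counts (>= 0).
#' @return updated field.
#' @export
update_oxygen <- function(field, n_generated, n_consumed) {
  stopifnot(inherits(field, "continuum_field"),
            n_generated >= 0, n_consumed >= 0)
  d_uM <- (n_generated - n_consumed) * .MOLEC_PER_UM3_UM / field$avg_volume_um3
  field$pO2_uM <- max(0, field$pO2_uM + d_uM)
  field$pO2_percent <- uM_to_pO2(field$pO2_uM)
  field$n_generated <- field$n_generated + n_generated
  field$n_consumed <- field$n_consumed + n_consumed
  field
}

#' Apply second-order reactions to a molecule set (reference implementation)
#'
#' Plain-R counterpart of the compiled kernel's spatial pass, used for
#' small-system testing and cross-validation: candidate pairs within
#' R_eff + 4 sqrt(2 D' dt) react with the GFDE probability; a molecule
#' participates in at most one reaction per step (candidates applied in
#' random order, pairs with a consumed partner skipped); products appear at
#' the diffusion-weighted point between the reactants.
#'
#' @param molecules data.frame `(species, x_um, y_um, z_um)`.
#' @param chem a [chemistry_system()].
#' @param dt_s time step, s.
#' @param box_L box edge, um.
#' @return list `molecules` (updated), `events` (data.frame reaction label,
#'   count).
#' @export
apply_second_order <- function(molecules, chem, dt_s, box_L = .BOX_L) {
  stopifnot(inherits(chem, "chem_system"), dt_s > 0)
  n <- nrow(molecules)
  alive <- rep(TRUE, n)
  so <- chem$so
  cand <- list()
  for (r in seq_len(nrow(so))) {
    ia <- which(molecules$species == so$r1[r])
    ib <- which(molecules$species == so$r2[r])
    same <- so$r1[r] == so$r2[r]
    if (length(ia) == 0 || length(ib) == 0) next
    R_um <- so$R_eff_nm[r] * 1e-3
    Dm_um2 <- so$D_mutual_m2s[r] * 1e12
    cutoff <- R_um + 4 * sqrt(2 * Dm_um2 * dt_s)
    for (i in ia) {
      js <- ib[if (same) ib > i else TRUE]
      if (length(js) == 0) next
      dx <- molecules$x_um[js] - molecules$x_um[i]
      dy <- molecules$y_um[js] - molecules$y_um[i]
      dz <- molecules$z_um[js] - molecules$z_um[i]
      rr <- sqrt(dx^2 + dy^2 + dz^2)
      sel <- rr <= cutoff
      if (!any(sel)) next
      p <- pair_reaction_probability(pmax(rr[sel], 1e-12) * 1e3,
                                     so$R_eff_nm[r],
                                     so$D_mutual_m2s[r], dt_s)
      hit <- runif(sum(sel)) < p
      for (j in js[sel][hit]) cand[[length(cand) + 1]] <- c(r, i, j)
    }
  }
  events <- integer(nrow(so))
  if (length(cand) > 0) {
    for (k in sample(seq_along(cand))) {
      v <- cand[[k]]
      r <- v[1]; i <- v[2]; j <- v[3]
      if (!alive[i] || !alive[j]) next
      alive[i] <- FALSE; alive[j] <- FALSE
      events[r] <- events[r] + 1L
      prods <- stats::na.omit(unlist(so[r, c("p1", "p2", "p3")]))
      prods <- prods[!(prods %in%
                         chem$species$name[chem$species$representation ==
                                             "continuum"])]
      if (length(prods) > 0) {
        Di <- chem$species$D_m2s[match(molecules$species[i], chem$species$name)]
        Dj <- chem$species$D_m2s[match(molecules$species[j], chem$species$name)]
        w <- sqrt(c(Dj, Di)); w <- w / sum(w)
        anchor <- c(w[1] * molecules$x_um[i] + w[2] * molecules$x_um[j],
                    w[1] * molecules$y_um[i] + w[2] * molecules$y_um[j],
                    w[1] * molecules$z_um[i] + w[2] * molecules$z_um[j])
        at <- rbind(anchor,
                    unlist(molecules[i, c("x_um", "y_um", "z_um")]),
                    unlist(molecules[j, c("x_um", "y_um", "z_um")]))
        for (q in seq_along(prods)) {
          molecules <- rbind(molecules,
                             data.frame(species = prods[q],
                                        x_um = at[q, 1], y_um = at[q, 2],
                                        z_um = at[q, 3]))
          alive <- c(alive, TRUE)
        }
      }
    }
  }
  list(molecules = molecules[alive, , drop = FALSE],
       events = data.frame(label = so$label, count = events))
}

#' Apply pseudo-first-order scavenging (reference implementation)
#'
#' Each eligible molecule reacts with probability 1 - exp(-k C dt); reacted
#' molecules are replaced by their point products in place; consumption
#' counts are returned for the oxygen update.
#'
#' @param molecules data.frame `(species, x_um, y_um, z_um)`.
#' @param field a [continuum_field()].
#' @param chem a [chemistry_system()].
#' @param dt_s time step, s.
#' @return list `molecules`, `n_consumed`, `n_generated`.
#' @export
apply_pseudo_first_order <- function(molecules, field, chem, dt_s) {
  stopifnot(inherits(field, "continuum_field"))
  pfo <- chem$pfo
  cont <- chem$species$name[chem$species$representation == "continuum"]
  n_cons <- 0L; n_gen <- 0L
  keep <- rep(TRUE, nrow(molecules))
  newrows <- list()
  for (r in seq_len(nrow(pfo))) {
    p <- scavenging_probability(pfo$k[r], field$pO2_uM, dt_s)
    idx <- which(molecules$species == pfo$r1[r] & keep)
    if (length(idx) == 0 || p <= 0) next
    hit <- idx[runif(length(idx)) < p]
    if (length(hit) == 0) next
    keep[hit] <- FALSE
    n_cons <- n_cons + length(hit)
    prods <- stats::na.omit(unlist(pfo[r, c("p1", "p2", "p3")]))
    n_gen <- n_gen + length(hit) * sum(prods %in% cont)
    prods <- setdiff(prods, cont)
    for (pn in prods) {
      nr <- molecules[hit, , drop = FALSE]
      nr$species <- pn
      newrows[[length(newrows) + 1]] <- nr
    }
  }
  out <- molecules[keep, , drop = FALSE]
  if (length(newrows) > 0) out <- rbind(out, do.call(rbind, newrows))
  list(molecules = out, n_consumed = n_cons, n_generated = n_gen)
}
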