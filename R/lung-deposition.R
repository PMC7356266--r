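# Stochastic whole-lung Monte Carlo deposition simulator. Particles sampled
# from a mass-weighted aerodynamic size distribution pass an empirical
# extrathoracic filter, then advance generation by generation through a
# randomly perturbed Weibel-type tree; deposition per tube combines
# inertial impaction, gravitational sedimentation and Brownian diffusion.
# A breath hold applies zero-flow sedimentation + diffusion in the resting
# generation; exhalation retraces the path with flow-dependent
# probabilities. Undeposited particles are exhaled.
#
# CGS units internally: cm, s, g; aerodynamic diameters enter in um.

# Physical constants (body conditions)
.mu_air <- 1.81e-4       # dynamic viscosity of air, poise (g cm^-1 s^-1)
.rho_ae <- 1.0           # aerodynamic-equivalent particle density, g cm^-3
.g_cgs <- 981            # gravitational acceleration, cm s^-2
.kT_310 <- 1.38e-16 * 310  # Boltzmann constant x body temperature, erg
.mfp_um <- 0.066         # mean free path of air, um

#' Cunningham slip correction factor
#'
#' @param d_um Particle diameter(s), um.
#' @return Dimensionless slip correction, >= 1.
#' @export
cunningham <- function(d_um) {
  kn <- 2 * .mfp_um / d_um
  1 + kn * (1.257 + 0.4 * exp(-1.1 / kn))
}

#' Terminal settling velocity of an aerodynamic-diameter particle
#'
#' Stokes settling at unit density (the aerodynamic diameter convention
#' already folds density and shape into the diameter).
#'
#' @param d_um Aerodynamic diameter(s), um.
#' @return Settling velocity, cm/s.
#' @export
settling_velocity <- function(d_um) {
  d_cm <- d_um * 1e-4
  .rho_ae * d_cm^2 * .g_cgs * cunningham(d_um) / (18 * .mu_air)
}

#' Brownian diffusion coefficient
#'
#' @param d_um Aerodynamic diameter(s), um.
#' @return Diffusion coefficient, cm^2/s.
#' @export
brownian_diffusivity <- function(d_um) {
  d_cm <- d_um * 1e-4
  .kT_310 * cunningham(d_um) / (3 * pi * .mu_air * d_cm)
}

#' Extrathoracic (mouth-throat) deposition efficiency
#'
#' Empirical impaction-driven capture efficiency for mouth breathing,
#' monotone increasing in the impaction parameter `d_ae^2 Q`:
#' `eta = 1 - exp(-a (d^2 Q)^b)` with `d` in um and `Q` in L/min. The
#' default constants `a = 2.78e-4`, `b = 1.152` reproduce the steep rise of
#' measured mouth-throat deposition between ~3 and ~10 um at DPI flows; the
#' diffusive ultrafine term is negligible at aerosol-drug sizes, so the
#' small-particle limit of the efficiency is ~0.
#'
#' @param d_um Aerodynamic diameter(s), um.
#' @param flow_l_min Inspiratory flow, L/min.
#' @param a,b Empirical constants of the fit.
#' @return Deposition probability in `[0, 1]`.
#' @export
#' @examples
#' extrathoracic_efficiency(4, 31.9)
extrathoracic_efficiency <- function(d_um, flow_l_min, a = 2.78e-4,
                                     b = 1.152) {
  if (any(d_um <= 0) || flow_l_min <= 0) {
    stop("diameter and flow must be positive", call. = FALSE)
  }
  1 - exp(-a * (d_um^2 * flow_l_min)^b)
}

# Inertial impaction in a bent tube (Stokes-number form). x = theta * Stk
# with theta the branching angle in radians; full capture at x >= 1.
eta_impaction <- function(stk, branch_angle_rad) {
  x <- pmin(branch_angle_rad * stk, 1)
  eta <- 1 - (2 / pi) * acos(x) + (1 / pi) * sin(2 * acos(x))
  pmin(pmax(eta, 0), 1)
}

# Gravitational sedimentation in an inclined tube over residence time t:
# eta = 1 - exp(-2 v_s t cos(phi) / (pi R)). Valid for flow transit
# (t = L/U) and for a zero-flow hold (t = hold time).
eta_sedimentation <- function(v_s, t_s, cos_gravity, radius_cm) {
  1 - exp(-2 * v_s * t_s * cos_gravity / (pi * radius_cm))
}

# Brownian diffusion, Gormley-Kennedy laminar-flow solution with
# delta = D L / (4 R^2 U) = D t / (4 R^2).
eta_diffusion_flow <- function(d_coef, t_s, radius_cm) {
  delta <- d_coef * t_s / (4 * radius_cm^2)
  small <- delta < 0.02
  eta <- numeric(length(delta))
  eta[small] <- 2.56 * delta[small]^(2 / 3) - 1.2 * delta[small] -
    0.1767 * delta[small]^(4 / 3)
  eta[!small] <- 1 - 0.8191 * exp(-7.314 * delta[!small]) -
    0.0975 * exp(-44.61 * delta[!small]) -
    0.0325 * exp(-113.9 * delta[!small])
  pmin(pmax(eta, 0), 1)
}

# Diffusion to the wall of a closed tube during a hold (first radial mode
# of the diffusion equation in a cylinder, 2.405^2 ~ 5.784).
eta_diffusion_hold <- function(d_coef, t_s, radius_cm) {
  1 - exp(-5.784 * d_coef * t_s / radius_cm^2)
}

#' Single-tube deposition probability by mechanism
#'
#' Combines inertial impaction, gravitational sedimentation and Brownian
#' diffusion for one airway tube by the independent-probability complement
#' product `1 - (1-eta_imp)(1-eta_sed)(1-eta_diff)`. With zero velocity
#' (breath hold) the impaction term vanishes and the zero-flow diffusion
#' solution is used.
#'
#' @param d_um Aerodynamic diameter(s), um.
#' @param diam_cm Tube diameter, cm.
#' @param velocity_cm_s Mean air velocity in the tube, cm/s (0 for a hold).
#' @param residence_s Residence time in the tube, s.
#' @param branch_angle_deg Branching (bend) angle, degrees.
#' @param gravity_angle_deg Angle between tube axis and gravity horizontal;
#'   `cos` of this angle weights sedimentation.
#' @return List with `eta_imp`, `eta_sed`, `eta_diff`, `p` (combined).
#' @export
generation_deposition_prob <- function(d_um, diam_cm, velocity_cm_s,
                                       residence_s, branch_angle_deg = 35,
                                       gravity_angle_deg = 45) {
  if (any(diam_cm <= 0)) stop("tube diameter must be positive", call. = FALSE)
  if (any(velocity_cm_s < 0) || any(residence_s < 0)) {
    stop("velocity and residence time must be non-negative", call. = FALSE)
  }
  r <- diam_cm / 2
  v_s <- settling_velocity(d_um)
  dc <- brownian_diffusivity(d_um)
  cosg <- cos(gravity_angle_deg * pi / 180)
  stk <- v_s * velocity_cm_s / (.g_cgs * diam_cm)
  ei <- ifelse(velocity_cm_s > 0,
               eta_impaction(stk, branch_angle_deg * pi / 180), 0)
  es <- eta_sedimentation(v_s, residence_s, cosg, r)
  ed <- ifelse(velocity_cm_s > 0, eta_diffusion_flow(dc, residence_s, r),
               eta_diffusion_hold(dc, residence_s, r))
  list(eta_imp = ei, eta_sed = es, eta_diff = ed,
       p = 1 - (1 - ei) * (1 - es) * (1 - ed))
}

#' Sample aerodynamic diameters from a mass-weighted APSD
#'
#' Mass-weighted draws from the lognormal distribution with mass median
#' aerodynamic diameter `mmad_um` and geometric standard deviation `gsd`;
#' each sampled particle then carries equal mass in the simulator.
#'
#' @param mmad_um Mass median aerodynamic diameter, um (> 0).
#' @param gsd Geometric standard deviation (>= 1).
#' @param n Number of draws.
#' @param seed Optional integer seed (set only if non-NULL).
#' @return Numeric vector of `n` diameters, um.
#' @export
sample_apsd <- function(mmad_um, gsd, n, seed = NULL) {
  if (!is.numeric(mmad_um) || mmad_um <= 0 || !is.numeric(gsd) || gsd < 1) {
    stop("need mmad_um > 0 and gsd >= 1", call. = FALSE)
  }
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  stats::rlnorm(n, meanlog = log(mmad_um), sdlog = log(gsd))
}

#' Monte Carlo whole-lung deposition simulation
#'
#' Tracks `n` particles drawn from the APSD through inhalation, breath hold
#' and exhalation, and tallies extrathoracic (ET), per-generation lung, and
#' exhaled (EXH) fractions on the emitted-dose basis (everything entering
#' the mouth). Per particle and per generation the tube length and diameter
#' are perturbed by lognormal multipliers (coefficient of variation
#' `geometry_cv`) and the tube's gravity angle is drawn uniformly,
#' emulating inter-subject/inter-path morphometric variability. The depth a
#' particle reaches is set by the volume of air inhaled after its entry
#' versus the cumulative tree volume; the breath hold applies zero-flow
#' sedimentation and diffusion in the resting generation.
#'
#' The random-number stream is consumed in fixed-length blocks per phase,
#' so two runs with the same `seed` and `n` differing only in breath-hold
#' duration share all random draws (common random numbers): breath-hold
#' comparisons are then monotone by construction of the physics, not by
#' chance.
#'
#' @param mmad_um,gsd Lognormal APSD parameters (see [sample_apsd()]), or
#'   supply `diameters_um` directly.
#' @param profile A [breathing_profile()].
#' @param n Number of particles (>= 100).
#' @param seed Integer seed; recorded in the result.
#' @param diameters_um Optional explicit diameters (overrides the APSD
#'   parameters; length `n`).
#' @param geometry An [airway_geometry()].
#' @param geometry_cv Lognormal CV of per-tube length/diameter
#'   perturbations (default 0.1).
#' @param branch_angle_deg Fixed branching angle, degrees (default 35).
#' @param et_a,et_b Extrathoracic efficiency constants, see
#'   [extrathoracic_efficiency()].
#' @return Object of class `deposition_result`: `et_pct`, `lung_pct`,
#'   `bronchial_pct`, `acinar_pct`, `exh_pct`, `per_generation_pct`
#'   (length 24), `n_particles`, `seed`. ET + LUNG + EXH = 100 exactly.
#' @export
#' @examples
#' res <- simulate_deposition(3.41, 1.8, copd_profile(5), n = 2000, seed = 1)
#' res$lung_pct
simulate_deposition <- function(mmad_um = NULL, gsd = NULL, profile,
                                n = 1e5, seed = 1, diameters_um = NULL,
                                geometry = airway_geometry(),
                                geometry_cv = 0.1, branch_angle_deg = 35,
                                et_a = 2.78e-4, et_b = 1.152) {
  stopifnot(inherits(profile, "breathing_profile"),
            inherits(geometry, "airway_geometry"))
  if (n < 100) stop("n must be at least 100", call. = FALSE)
  n <- as.integer(n)
  set.seed(seed)

  if (is.null(diameters_um)) {
    d <- sample_apsd(mmad_um, gsd, n)
  } else {
    if (length(diameters_um) != n) {
      stop("'diameters_um' must have length n", call. = FALSE)
    }
    d <- diameters_um
  }

  q_in_cgs <- profile$inhaled_volume_l / profile$inhalation_time_s * 1000
  q_ex_cgs <- profile$inhaled_volume_l / profile$exhalation_time_s * 1000
  v_inh_ml <- profile$inhaled_volume_l * 1000
  sdlog <- sqrt(log(1 + geometry_cv^2))
  branch_rad <- branch_angle_deg * pi / 180
  v_s <- settling_velocity(d)
  dc <- brownian_diffusivity(d)
  n_gen <- nrow(geometry)

  # Penetration depth: air inhaled after the particle's (uniform) entry
  # time fills the tree to this volumetric depth.
  u_entry <- stats::runif(n)
  pen_vol <- (1 - u_entry) * v_inh_ml
  g_max <- findInterval(pen_vol, geometry$cum_volume_ml)   # 0..24
  g_max <- pmin(g_max, n_gen - 1L)                          # rest gen index

  # Extrathoracic filter on inhalation (pass-through on exhalation).
  p_et <- extrathoracic_efficiency(d, profile$flow_l_min, et_a, et_b)
  u_et <- stats::runif(n)
  state <- rep.int(0L, n)            # 0 airborne, 1 ET, 2 lung, 3 exhaled
  dep_gen <- rep.int(NA_integer_, n)
  state[u_et < p_et] <- 1L

  transit_phase <- function(gens, q_cgs, state, dep_gen) {
    for (g in gens) {
      # fixed-size draws keep the RNG stream aligned across configurations
      len_mult <- stats::rlnorm(n, -sdlog^2 / 2, sdlog)
      dia_mult <- stats::rlnorm(n, -sdlog^2 / 2, sdlog)
      grav <- stats::runif(n, 0, 90)
      u <- stats::runif(n)
      active <- state == 0L & g_max >= g
      if (!any(active)) next
      len <- geometry$length_cm[g + 1L] * len_mult[active]
      dia <- geometry$diam_cm[g + 1L] * dia_mult[active]
      r <- dia / 2
      vel <- q_cgs / (geometry$multiplicity[g + 1L] * pi * r^2)
      t_res <- len / vel
      stk <- v_s[active] * vel / (.g_cgs * dia)
      ei <- eta_impaction(stk, branch_rad)
      es <- eta_sedimentation(v_s[active], t_res,
                              cos(grav[active] * pi / 180), r)
      ed <- eta_diffusion_flow(dc[active], t_res, r)
      p <- 1 - (1 - ei) * (1 - es) * (1 - ed)
      hit <- active
      hit[active] <- u[active] < p
      state[hit] <- 2L
      dep_gen[hit] <- g
    }
    list(state = state, dep_gen = dep_gen)
  }

  # Inhalation: proximal to distal.
  ph <- transit_phase(0:(n_gen - 1L), q_in_cgs, state, dep_gen)
  state <- ph$state; dep_gen <- ph$dep_gen

  # Breath hold at the resting generation: sedimentation + diffusion at
  # zero flow for the hold duration.
  dia_mult <- stats::rlnorm(n, -sdlog^2 / 2, sdlog)
  grav <- stats::runif(n, 0, 90)
  u <- stats::runif(n)
  if (profile$breath_hold_s > 0) {
    active <- state == 0L
    if (any(active)) {
      r <- geometry$diam_cm[g_max[active] + 1L] * dia_mult[active] / 2
      es <- eta_sedimentation(v_s[active], profile$breath_hold_s,
                              cos(grav[active] * pi / 180), r)
      ed <- eta_diffusion_hold(dc[active], profile$breath_hold_s, r)
      p <- 1 - (1 - es) * (1 - ed)
      hit <- active
      hit[active] <- u[active] < p
      state[hit] <- 2L
      dep_gen[hit] <- g_max[hit]
    }
  }

  # Exhalation: distal to proximal along the same path; ET is pass-through.
  ph <- transit_phase((n_gen - 1L):0, q_ex_cgs, state, dep_gen)
  state <- ph$state; dep_gen <- ph$dep_gen
  state[state == 0L] <- 3L

  per_gen <- tabulate(dep_gen + 1L, nbins = n_gen)
  bronchial <- sum(per_gen[geometry$region == "bronchial"])
  acinar <- sum(per_gen[geometry$region == "acinar"])
  structure(
    list(et_pct = 100 * sum(state == 1L) / n,
         lung_pct = 100 * (bronchial + acinar) / n,
         bronchial_pct = 100 * bronchial / n,
         acinar_pct = 100 * acinar / n,
         exh_pct = 100 * sum(state == 3L) / n,
         per_generation_pct = 100 * per_gen / n,
         n_particles = n, seed = seed),
    class = "deposition_result"
  )
}

#' @export
print.deposition_result <- function(x, ...) {
  cat(sprintf(
    "<deposition_result> n = %d (seed %s)\n  ET %.2f%%  LUNG %.2f%% (bronchial %.2f%% + acinar %.2f%%)  EXH %.2f%%\n",
    x$n_particles, format(x$seed), x$et_pct, x$lung_pct, x$bronchial_pct,
    x$acinar_pct, x$exh_pct))
  invisible(x)
}
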