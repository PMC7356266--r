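# Surface energetics: two-liquid Wu harmonic-mean inversion and the
# interparticle-interaction metrics derived from it (work of cohesion and
# adhesion, Derjaguin adhesion force, spreading coefficient).
#
# Unit contract: surface energies / tensions / works in mN/m, diameters in
# micrometres, forces in mN.

#' Probe liquid for contact-angle goniometry
#'
#' A probe liquid is characterised by the dispersive and polar parts of its
#' surface tension. Two liquids of well-separated polarity (classically
#' distilled water and diiodomethane) are needed to resolve the two unknown
#' solid-surface components.
#'
#' @param name Liquid name (used as the key when matching contact angles).
#' @param gamma_d Dispersive part of the surface tension, mN/m. Must be > 0.
#' @param gamma_p Polar part of the surface tension, mN/m. Must be >= 0.
#'
#' @return An object of class `probe_liquid` with fields `name`, `gamma_d`,
#'   `gamma_p` and `gamma_total` (= `gamma_d + gamma_p`).
#' @seealso [default_probe_liquids()], [solve_wu()]
#' @export
#' @examples
#' water <- probe_liquid("water", gamma_d = 22.6, gamma_p = 50.2)
#' water$gamma_total
probe_liquid <- function(name, gamma_d, gamma_p) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(gamma_d) || length(gamma_d) != 1L || !is.finite(gamma_d) ||
      gamma_d <= 0) {
    stop("'gamma_d' must be a single positive number (mN/m)", call. = FALSE)
  }
  if (!is.numeric(gamma_p) || length(gamma_p) != 1L || !is.finite(gamma_p) ||
      gamma_p < 0) {
    stop("'gamma_p' must be a single non-negative number (mN/m)", call. = FALSE)
  }
  structure(
    list(name = name, gamma_d = as.numeric(gamma_d),
         gamma_p = as.numeric(gamma_p),
         gamma_total = as.numeric(gamma_d + gamma_p)),
    class = "probe_liquid"
  )
}

#' Default probe-liquid constants
#'
#' Literature surface-tension components for the classical polar/dispersive
#' probe pair: distilled water (22.6 dispersive / 50.2 polar mN/m) and
#' diiodomethane (49 / 1.8 mN/m). Override by constructing your own
#' [probe_liquid()] objects.
#'
#' @return Named list of two `probe_liquid` objects, `water` and
#'   `diiodomethane`.
#' @export
default_probe_liquids <- function() {
  list(
    water         = probe_liquid("water",         22.6, 50.2),
    diiodomethane = probe_liquid("diiodomethane", 49.0,  1.8)
  )
}

#' Contact-angle measurement set for one material
#'
#' @param material Material name.
#' @param theta_deg Named numeric vector of contact angles in degrees, one per
#'   probe liquid; names must match the probe-liquid names passed to
#'   [solve_wu()]. Angles must lie in `[0, 180)`.
#'
#' @return Object of class `contact_angle_set`.
#' @export
#' @examples
#' contact_angle_set("drug", c(water = 25.13, diiodomethane = 23.53))
contact_angle_set <- function(material, theta_deg) {
  stopifnot(is.character(material), length(material) == 1L)
  if (!is.numeric(theta_deg) || is.null(names(theta_deg)) ||
      any(!nzchar(names(theta_deg)))) {
    stop("'theta_deg' must be a named numeric vector of angles in degrees",
         call. = FALSE)
  }
  if (any(!is.finite(theta_deg)) || any(theta_deg < 0) || any(theta_deg >= 180)) {
    stop("contact angles must lie in [0, 180) degrees", call. = FALSE)
  }
  structure(list(material = material, theta_deg = theta_deg),
            class = "contact_angle_set")
}

# Wu harmonic-mean right-hand side: the work of adhesion between the solid
# (x = dispersive, y = polar component) and a probe liquid.
wu_rhs <- function(x, y, liq) {
  4 * x * liq$gamma_d / (x + liq$gamma_d) +
    4 * y * liq$gamma_p / (y + liq$gamma_p)
}

# Owens-Wendt (geometric-mean) closed form used as the Newton initial guess.
# (1 + cos t) * gamma_l = 2 sqrt(gsd gld) + 2 sqrt(gsp glp) is linear in
# (sqrt(gsd), sqrt(gsp)).
owens_wendt_guess <- function(targets, liquids) {
  A <- rbind(
    2 * sqrt(c(liquids[[1]]$gamma_d, liquids[[1]]$gamma_p)),
    2 * sqrt(c(liquids[[2]]$gamma_d, liquids[[2]]$gamma_p))
  )
  sol <- tryCatch(solve(A, targets), error = function(e) NULL)
  if (is.null(sol) || any(!is.finite(sol))) return(c(30, 30))
  pmax(sol, 0.5)^2
}

#' Solve the two-liquid Wu harmonic-mean system for surface energy
#'
#' Inverts a pair of contact angles, one per probe liquid, to the dispersive
#' and polar surface-energy components of the solid. The governing relation
#' per liquid is
#' \deqn{(1+\cos\Theta)\,\gamma_l = \frac{4\,\gamma_s^d\gamma_l^d}{\gamma_s^d+\gamma_l^d}
#'       + \frac{4\,\gamma_s^p\gamma_l^p}{\gamma_s^p+\gamma_l^p}}
#' Each right-hand side is strictly increasing in both unknowns, so the root
#' is unique in the positive quadrant; a damped Newton iteration with
#' analytic Jacobian (started from the Owens-Wendt geometric-mean closed
#' form) is used, with a bounded nested-bisection fallback.
#'
#' @param angles A [contact_angle_set()] holding exactly the two angles.
#' @param liquids List of exactly two [probe_liquid()] objects; defaults to
#'   [default_probe_liquids()]. Angle names must match liquid names.
#'
#' @return An object of class `surface_energy`: list with `material`,
#'   `gamma_sd`, `gamma_sp`, `gamma_s`, `polarity_pct` (100 gsp/gs) and
#'   `cohesion_work` (2 gs), all energies in mN/m.
#' @export
#' @examples
#' se <- solve_wu(contact_angle_set("drug", c(water = 25.13,
#'                                            diiodomethane = 23.53)))
#' round(c(se$gamma_sd, se$gamma_sp, se$gamma_s), 2)  # 42.07 33.18 75.25
solve_wu <- function(angles, liquids = default_probe_liquids()) {
  stopifnot(inherits(angles, "contact_angle_set"))
  if (length(liquids) != 2L) {
    stop("exactly two probe liquids are required for the Wu solve",
         call. = FALSE)
  }
  liquids <- lapply(liquids, function(l) {
    if (!inherits(l, "probe_liquid")) stop("liquids must be probe_liquid objects",
                                           call. = FALSE)
    l
  })
  lnames <- vapply(liquids, `[[`, "", "name")
  if (anyDuplicated(lnames)) stop("probe liquids must be distinct", call. = FALSE)
  missing <- setdiff(lnames, names(angles$theta_deg))
  if (length(missing)) {
    stop("missing contact angle for liquid(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  # colinear probes in (gamma_d, gamma_p) cannot separate the components
  det2 <- liquids[[1]]$gamma_d * liquids[[2]]$gamma_p -
    liquids[[2]]$gamma_d * liquids[[1]]$gamma_p
  if (abs(det2) < 1e-8) {
    stop("probe liquids are colinear in (gamma_d, gamma_p); cannot invert",
         call. = FALSE)
  }

  theta <- angles$theta_deg[lnames] * pi / 180
  targets <- vapply(seq_len(2L), function(i) {
    (1 + cos(theta[i])) * liquids[[i]]$gamma_total
  }, numeric(1))

  resid <- function(p) {
    c(wu_rhs(p[1], p[2], liquids[[1]]) - targets[1],
      wu_rhs(p[1], p[2], liquids[[2]]) - targets[2])
  }
  jac <- function(p) {
    matrix(c(4 * liquids[[1]]$gamma_d^2 / (p[1] + liquids[[1]]$gamma_d)^2,
             4 * liquids[[1]]$gamma_p^2 / (p[2] + liquids[[1]]$gamma_p)^2,
             4 * liquids[[2]]$gamma_d^2 / (p[1] + liquids[[2]]$gamma_d)^2,
             4 * liquids[[2]]$gamma_p^2 / (p[2] + liquids[[2]]$gamma_p)^2),
           2L, 2L, byrow = TRUE)
  }

  lo <- 1e-6; hi <- 500
  p <- pmin(pmax(owens_wendt_guess(targets, liquids), lo), hi)
  converged <- FALSE
  for (it in seq_len(200L)) {
    f <- resid(p)
    if (max(abs(f)) < 1e-10) { converged <- TRUE; break }
    step <- tryCatch(solve(jac(p), f), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {                                   # damping: require residual decrease
      cand <- pmin(pmax(p - lambda * step, lo), hi)
      if (sum(resid(cand)^2) < sum(f^2) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    p <- cand
  }

  if (!converged) p <- wu_bisection_fallback(resid, liquids, targets, lo, hi)
  f <- resid(p)
  if (max(abs(f)) > 1e-8) {
    stop("non-physical angle set: no positive Wu root within bounds ",
         "(max residual ", format(max(abs(f))), " mN/m)", call. = FALSE)
  }

  gamma_s <- p[1] + p[2]
  structure(
    list(material = angles$material,
         gamma_sd = p[1], gamma_sp = p[2], gamma_s = gamma_s,
         polarity_pct = 100 * p[2] / gamma_s,
         cohesion_work = 2 * gamma_s),
    class = "surface_energy"
  )
}

# Nested bisection: the outer variable is the dispersive component; for each
# trial x the first equation (strictly increasing in y) is solved for y by
# uniroot, then the second equation's residual drives the outer bisection.
wu_bisection_fallback <- function(resid, liquids, targets, lo, hi) {
  solve_y <- function(x) {
    g <- function(y) wu_rhs(x, y, liquids[[1]]) - targets[1]
    if (g(lo) > 0) return(lo)
    if (g(hi) < 0) return(hi)
    stats::uniroot(g, c(lo, hi), tol = 1e-13)$root
  }
  outer <- function(x) {
    y <- solve_y(x)
    wu_rhs(x, y, liquids[[2]]) - targets[2]
  }
  flo <- outer(lo); fhi <- outer(hi)
  if (flo * fhi > 0) {
    stop("non-physical angle set: no positive Wu root within bounds",
         call. = FALSE)
  }
  x <- stats::uniroot(outer, c(lo, hi), tol = 1e-13)$root
  c(x, solve_y(x))
}

#' Construct a surface-energy object from known components
#'
#' Useful when components are taken from the literature rather than solved
#' from angles.
#'
#' @param material Material name.
#' @param gamma_sd Dispersive component, mN/m (> 0).
#' @param gamma_sp Polar component, mN/m (>= 0).
#' @return Object of class `surface_energy`.
#' @export
surface_energy <- function(material, gamma_sd, gamma_sp) {
  stopifnot(is.character(material), length(material) == 1L)
  if (!is.finite(gamma_sd) || gamma_sd <= 0 || !is.finite(gamma_sp) ||
      gamma_sp < 0) {
    stop("surface-energy components must be positive (dispersive) and ",
         "non-negative (polar)", call. = FALSE)
  }
  gamma_s <- gamma_sd + gamma_sp
  structure(
    list(material = material, gamma_sd = as.numeric(gamma_sd),
         gamma_sp = as.numeric(gamma_sp), gamma_s = as.numeric(gamma_s),
         polarity_pct = 100 * gamma_sp / gamma_s,
         cohesion_work = 2 * gamma_s),
    class = "surface_energy"
  )
}

#' @export
print.surface_energy <- function(x, ...) {
  cat(sprintf(
    "<surface_energy> %s\n  gamma_sd %.2f  gamma_sp %.2f  gamma_s %.2f mN/m\n  polarity %.2f %%   W_c %.2f mN/m\n",
    x$material, x$gamma_sd, x$gamma_sp, x$gamma_s, x$polarity_pct,
    x$cohesion_work))
  invisible(x)
}

#' Work of cohesion
#'
#' Reversible work to separate a column of one material into two surfaces:
#' twice its total surface free energy.
#'
#' @param e A `surface_energy` object, or a total surface energy in mN/m.
#' @return Work of cohesion, mN/m.
#' @export
cohesion_work <- function(e) {
  gs <- if (inherits(e, "surface_energy")) e$gamma_s else e
  if (!is.numeric(gs) || any(gs < 0)) {
    stop("total surface energy must be non-negative", call. = FALSE)
  }
  2 * gs
}

#' Harmonic-mean work of adhesion between two materials
#'
#' \deqn{W_{adh} = 4\left[\frac{\gamma_1^d\gamma_2^d}{\gamma_1^d+\gamma_2^d} +
#'   \frac{\gamma_1^p\gamma_2^p}{\gamma_1^p+\gamma_2^p}\right]}
#' Symmetric in its arguments; for identical materials it equals the work of
#' cohesion.
#'
#' @param e1,e2 `surface_energy` objects.
#' @return Work of adhesion, mN/m.
#' @export
work_of_adhesion <- function(e1, e2) {
  stopifnot(inherits(e1, "surface_energy"), inherits(e2, "surface_energy"))
  if (e1$gamma_sd + e2$gamma_sd <= 0) {
    stop("degenerate input: both dispersive components are zero", call. = FALSE)
  }
  disp <- if (e1$gamma_sd + e2$gamma_sd > 0)
    e1$gamma_sd * e2$gamma_sd / (e1$gamma_sd + e2$gamma_sd) else 0
  pol <- if (e1$gamma_sp + e2$gamma_sp > 0)
    e1$gamma_sp * e2$gamma_sp / (e1$gamma_sp + e2$gamma_sp) else 0
  4 * (disp + pol)
}

#' Derjaguin sphere-sphere adhesion force
#'
#' \deqn{F_{adh} = 2\pi \frac{R_A R_B}{R_A + R_B} W_{adh}} with radii taken
#' as half the laser-diffraction median diameters D(0.5). With radii in
#' metres and the work of adhesion in mN/m (= mJ/m^2) the force comes out in
#' micronewtons of... concretely: `F[mN] = 2 pi R_red[m] W[mN/m]`, i.e. a
#' factor 1e-6 appears when the reduced radius is expressed in micrometres.
#'
#' @param w_adh Work of adhesion, mN/m (> 0).
#' @param d50_1,d50_2 Median particle diameters D(0.5) of the two particles,
#'   micrometres (> 0).
#' @return Adhesion force, mN.
#' @export
#' @examples
#' adhesion_force(104.98, 3.602, 215.00) # 1.168e-3 mN
adhesion_force <- function(w_adh, d50_1, d50_2) {
  if (!is.numeric(w_adh) || any(w_adh <= 0)) {
    stop("work of adhesion must be positive", call. = FALSE)
  }
  if (any(c(d50_1, d50_2) <= 0)) {
    stop("particle diameters must be positive", call. = FALSE)
  }
  r_a <- d50_1 / 2 * 1e-6  # um -> m
  r_b <- d50_2 / 2 * 1e-6
  2 * pi * (r_a * r_b / (r_a + r_b)) * w_adh
}

#' Spreading coefficient of material 1 over material 2
#'
#' Work of adhesion of the pair minus the work of cohesion of the spreading
#' material (material 1, conventionally the drug spreading over the
#' carrier). Positive values favour film spreading of the drug on the
#' carrier surface.
#'
#' @param e1 `surface_energy` of the spreading material (drug).
#' @param e2 `surface_energy` of the substrate (carrier).
#' @return Spreading coefficient (mN/m scale, reported dimensionless).
#' @export
spreading_coefficient <- function(e1, e2) {
  work_of_adhesion(e1, e2) - cohesion_work(e1)
}

#' Full interaction metrics for a drug-carrier pair
#'
#' Bundles the Eq.-style adhesion work, Derjaguin force and spreading
#' coefficient for one ordered pair. `w_adh_override` lets a
#' separately-reported work of adhesion drive the force computation (the
#' harmonic-mean value from the components is always also returned).
#'
#' @param e1 `surface_energy` of the drug (spreading material).
#' @param e2 `surface_energy` of the carrier.
#' @param d50_1,d50_2 Median diameters, micrometres.
#' @param w_adh_override Optional externally supplied work of adhesion,
#'   mN/m, used for the force only.
#' @return Object of class `interaction_pair` with fields `w_adh`
#'   (harmonic-mean value), `w_adh_used`, `f_adh` (mN), `s21`.
#' @export
interaction_pair <- function(e1, e2, d50_1, d50_2, w_adh_override = NULL) {
  w <- work_of_adhesion(e1, e2)
  w_used <- if (is.null(w_adh_override)) w else w_adh_override
  structure(
    list(material_1 = e1$material, material_2 = e2$material,
         d50_1 = d50_1, d50_2 = d50_2,
         w_adh = w, w_adh_used = w_used,
         f_adh = adhesion_force(w_used, d50_1, d50_2),
         s21 = w - cohesion_work(e1)),
    class = "interaction_pair"
  )
}

#' @export
print.interaction_pair <- function(x, ...) {
  cat(sprintf(
    "<interaction_pair> %s on %s\n  W_adh %.2f mN/m (used %.2f)  F_adh %.3e mN  S21 %.2f\n",
    x$material_1, x$material_2, x$w_adh, x$w_adh_used, x$f_adh, x$s21))
  invisible(x)
}

#' Forward contact angle from known surface-energy components
#'
#' Solves the Wu relation for the contact angle of one probe liquid on a
#' solid of known components; the inverse of [solve_wu()] and the basis of
#' the synthetic contact-angle generator.
#'
#' @param gamma_sd,gamma_sp Solid components, mN/m.
#' @param liquid A [probe_liquid()].
#' @return Contact angle, degrees.
#' @export
forward_contact_angle <- function(gamma_sd, gamma_sp, liquid) {
  stopifnot(inherits(liquid, "probe_liquid"))
  cost <- wu_rhs(gamma_sd, gamma_sp, liquid) / liquid$gamma_total - 1
  if (cost > 1 || cost < -1) {
    stop("components outside the solvable range for liquid '", liquid$name,
         "' (cos theta = ", format(cost), ")", call. = FALSE)
  }
  acos(cost) * 180 / pi
}
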