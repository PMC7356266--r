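# Andersen Cascade Impactor (ACI) data reduction: emitted fraction, fine
# particle fractions, and MMAD/GSD via log-probit regression of the
# cumulative percentage undersize against the stage effective cut-off
# diameters (ECD).

#' Standard ACI stage cut-off diameters
#'
#' Effective cut-off diameters (micrometres) of stages 0-7 of the Andersen
#' cascade impactor at its calibration flow of 28.3 L/min. Cut-offs are
#' flow-rate calibrated constants; override via the `stage_ecd_um` argument
#' of [impactor_run()] for other flows.
#'
#' @param flow_l_min Flow rate, L/min. Only the 28.3 L/min calibration set
#'   is built in.
#' @return Numeric vector of 8 strictly decreasing cut-offs, um.
#' @export
aci_cutoffs <- function(flow_l_min = 28.3) {
  if (abs(flow_l_min - 28.3) > 1.5) {
    stop("built-in cut-offs are calibrated for 28.3 L/min; supply ",
         "'stage_ecd_um' explicitly for flow ", flow_l_min, " L/min",
         call. = FALSE)
  }
  c(9.0, 5.8, 4.7, 3.3, 2.1, 1.1, 0.7, 0.4)
}

#' One cascade-impactor run
#'
#' Drug mass recovered at each sampling location of an ACI run, with the
#' stage cut-off diameters in effect at the stated flow rate.
#'
#' @param stage_masses Drug mass on stages 0..7 (same order as
#'   `stage_ecd_um`), ug.
#' @param filter_mass Drug mass on the terminal filter, ug.
#' @param device_mass,capsule_mass Drug retained in the inhaler device and
#'   capsule shells, ug.
#' @param induction_port_mass,mouthpiece_mass Drug in the induction port
#'   (throat) and mouthpiece adapter, ug.
#' @param flow_l_min Flow rate, L/min.
#' @param stage_ecd_um Strictly decreasing stage cut-offs, um; default the
#'   28.3 L/min ACI set.
#' @return Object of class `impactor_run`.
#' @export
impactor_run <- function(stage_masses, filter_mass,
                         device_mass = 0, capsule_mass = 0,
                         induction_port_mass = 0, mouthpiece_mass = 0,
                         flow_l_min = 28.3,
                         stage_ecd_um = aci_cutoffs(flow_l_min)) {
  masses <- c(stage_masses, filter_mass, device_mass, capsule_mass,
              induction_port_mass, mouthpiece_mass)
  if (any(!is.finite(masses)) || any(masses < 0)) {
    stop("all masses must be non-negative", call. = FALSE)
  }
  if (length(stage_masses) != length(stage_ecd_um)) {
    stop("need one stage mass per cut-off diameter", call. = FALSE)
  }
  if (any(diff(stage_ecd_um) >= 0)) {
    stop("stage cut-offs must be strictly decreasing", call. = FALSE)
  }
  structure(
    list(flow_l_min = flow_l_min,
         device_mass = device_mass, capsule_mass = capsule_mass,
         induction_port_mass = induction_port_mass,
         mouthpiece_mass = mouthpiece_mass,
         stage_masses = as.numeric(stage_masses),
         filter_mass = filter_mass,
         stage_ecd_um = as.numeric(stage_ecd_um)),
    class = "impactor_run"
  )
}

#' Total recovered, emitted and sized mass of a run (ug)
#'
#' Sized mass is the mass that reached the size-classifying stages and
#' filter; induction-port and mouthpiece deposits count toward emitted but
#' not sized mass.
#'
#' @param run An [impactor_run()].
#' @return Named list `total`, `emitted`, `sized`.
#' @export
run_masses <- function(run) {
  stopifnot(inherits(run, "impactor_run"))
  sized <- sum(run$stage_masses) + run$filter_mass
  emitted <- sized + run$induction_port_mass + run$mouthpiece_mass
  list(total = emitted + run$device_mass + run$capsule_mass,
       emitted = emitted, sized = sized)
}

#' Emitted fraction of a run
#'
#' Percentage of the total recovered drug that left the device and capsule.
#'
#' @param run An [impactor_run()].
#' @return EF, percent.
#' @export
emitted_fraction <- function(run) {
  m <- run_masses(run)
  if (m$total <= 0) stop("zero total recovered mass", call. = FALSE)
  100 * m$emitted / m$total
}

#' Cumulative percentage undersize at each stage cut-off
#'
#' For each stage cut-off diameter, the percentage of the sized mass
#' (stages + filter) collected on all stages with smaller cut-offs plus the
#' filter, i.e. the mass fraction finer than that ECD.
#'
#' @param run An [impactor_run()].
#' @return Data frame with columns `ecd_um` (increasing) and `cum_pct`.
#' @export
cumulative_undersize <- function(run) {
  m <- run_masses(run)
  if (m$sized <= 0) stop("zero sized mass on stages and filter", call. = FALSE)
  k <- length(run$stage_masses)
  # cut-offs are decreasing: mass below cut-off i = stages (i+1)..k + filter
  below <- rev(cumsum(rev(c(run$stage_masses[-1L], run$filter_mass))))
  out <- data.frame(ecd_um = run$stage_ecd_um,
                    cum_pct = 100 * below / m$sized)
  out[order(out$ecd_um), , drop = FALSE]
}

#' Log-probit fit of a cumulative undersize curve
#'
#' Ordinary least squares of the probit (inverse standard normal CDF) of
#' the cumulative fraction on the natural log of the cut-off diameter.
#' Points at exactly 0% or 100% are excluded (infinite probit). For a
#' lognormal mass distribution the fit is exact with
#' `MMAD = exp(-intercept/slope)` and `GSD = exp(1/slope)`.
#'
#' @param cum Data frame from [cumulative_undersize()] (columns `ecd_um`,
#'   `cum_pct`).
#' @return List `mmad_um`, `gsd`, `r_squared`, `slope`, `intercept`,
#'   `n_points`.
#' @export
fit_log_probit <- function(cum) {
  stopifnot(is.data.frame(cum), all(c("ecd_um", "cum_pct") %in% names(cum)))
  usable <- cum$cum_pct > 0 & cum$cum_pct < 100
  if (sum(usable) < 2L) {
    stop("degenerate distribution: fewer than 2 usable cumulative points ",
         "strictly between 0% and 100%", call. = FALSE)
  }
  x <- log(cum$ecd_um[usable])
  y <- stats::qnorm(cum$cum_pct[usable] / 100)
  fit <- stats::lm.fit(cbind(1, x), y)
  a <- unname(fit$coefficients[1L]); b <- unname(fit$coefficients[2L])
  if (!is.finite(b) || b <= 0) {
    stop("degenerate distribution: non-increasing undersize curve",
         call. = FALSE)
  }
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  list(mmad_um = exp(-a / b), gsd = exp(1 / b), r_squared = r2,
       slope = b, intercept = a, n_points = sum(usable))
}

#' Fine particle fractions below 5 and 3 micrometres
#'
#' Evaluated from the fitted log-probit line (fraction of sized mass finer
#' than the cut point), rescaled to the chosen denominator. With
#' `method = "interpolate"` a piecewise-linear interpolation in
#' probit-log space of the raw cumulative points is used instead.
#'
#' @param run An [impactor_run()].
#' @param fit Result of [fit_log_probit()]; computed from `run` if omitted.
#' @param basis Denominator for the percentages: `"emitted"` (default,
#'   consistent with EF excluding device and capsule), `"recovered"` or
#'   `"sized"`.
#' @param method `"fit"` (default) or `"interpolate"`.
#' @return Named list `fpf5_pct`, `fpf3_pct`.
#' @export
fine_particle_fractions <- function(run, fit = NULL,
                                    basis = c("emitted", "recovered", "sized"),
                                    method = c("fit", "interpolate")) {
  basis <- match.arg(basis)
  method <- match.arg(method)
  m <- run_masses(run)
  basis_mass <- switch(basis, emitted = m$emitted, recovered = m$total,
                       sized = m$sized)
  if (basis_mass <= 0) stop("zero basis mass", call. = FALSE)
  frac_below <- function(d_um) {
    if (method == "fit") {
      if (is.null(fit)) fit <<- fit_log_probit(cumulative_undersize(run))
      stats::pnorm(fit$intercept + fit$slope * log(d_um))
    } else {
      cum <- cumulative_undersize(run)
      usable <- cum$cum_pct > 0 & cum$cum_pct < 100
      x <- log(cum$ecd_um[usable]); y <- stats::qnorm(cum$cum_pct[usable] / 100)
      stats::pnorm(stats::approx(x, y, xout = log(d_um), rule = 2)$y)
    }
  }
  scale <- m$sized / basis_mass
  list(fpf5_pct = 100 * scale * frac_below(5),
       fpf3_pct = 100 * scale * frac_below(3))
}

#' Reduce one impactor run to its aerodynamic summary
#'
#' @param run An [impactor_run()].
#' @param basis FPF denominator, see [fine_particle_fractions()].
#' @param method FPF evaluation method, see [fine_particle_fractions()].
#' @return Object of class `apsd_result`: `ef_pct`, `fpf5_pct`, `fpf3_pct`,
#'   `mmad_um`, `gsd`, `r_squared`, `basis`.
#' @export
#' @examples
#' run <- gen_impactor_run(mmad_um = 3.41, gsd = 1.8, total_ug = 1300,
#'                         seed = 1)
#' reduce_impactor_run(run)
reduce_impactor_run <- function(run, basis = "emitted", method = "fit") {
  fit <- fit_log_probit(cumulative_undersize(run))
  fpf <- fine_particle_fractions(run, fit, basis = basis, method = method)
  structure(
    list(ef_pct = emitted_fraction(run),
         fpf5_pct = fpf$fpf5_pct, fpf3_pct = fpf$fpf3_pct,
         mmad_um = fit$mmad_um, gsd = fit$gsd, r_squared = fit$r_squared,
         basis = basis),
    class = "apsd_result"
  )
}

#' @export
print.apsd_result <- function(x, ...) {
  cat(sprintf(
    "<apsd_result> EF %.2f%%  FPF<5um %.2f%%  FPF<3um %.2f%% (per %s dose)\n  MMAD %.2f um  GSD %.2f  R^2 %.4f\n",
    x$ef_pct, x$fpf5_pct, x$fpf3_pct, x$basis, x$mmad_um, x$gsd,
    x$r_squared))
  invisible(x)
}
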