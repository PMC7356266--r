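# Seeded synthetic-data generators for every pipeline input. Each generator
# is deterministic under a fixed seed and, at zero noise, is exactly
# inverted by the pipeline stage that consumes its output.

#' Default synthetic truth parameters
#'
#' A complete "stated world" for end-to-end runs: surface-energy components,
#' median diameters, blend masses and APSD parameters on the scales printed
#' for a micronised-drug / spray-dried-drug / lactose-carrier DPI study.
#'
#' @return Nested list with elements `surface_energy` (per-material
#'   dispersive/polar components, mN/m), `d50_um`, `blends`, `apsd`
#'   (per-formulation MMAD um / GSD), `retention` (device and capsule mass
#'   fractions), and `noise` (angle SD deg, impactor CV, content SD %).
#' @export
synthetic_truth <- function() {
  list(
    surface_energy = list(
      uMXP      = c(gamma_sd = 42.07, gamma_sp = 33.18),
      MXPspd    = c(gamma_sd = 39.93, gamma_sp = 33.44),
      IH70      = c(gamma_sd = 45.58, gamma_sp = 36.88),
      IH70_MgSt = c(gamma_sd = 26.07, gamma_sp = 19.22),
      MgSt      = c(gamma_sd = 24.33, gamma_sp = 2.64)
    ),
    d50_um = c(uMXP = 3.602, MXPspd = 2.109, IH70 = 215.00),
    blends = list(
      "uMXP + IH70"        = c(uMXP = 0.2, IH70 = 2.0),
      "uMXP + IH70_MgSt"   = c(uMXP = 0.2, IH70 = 1.956, MgSt = 0.044),
      "MXPspd + IH70"      = c(MXPspd = 0.2, IH70 = 2.0),
      "MXPspd + IH70_MgSt" = c(MXPspd = 0.2, IH70 = 1.956, MgSt = 0.044)
    ),
    dose_mg = 1.3,
    apsd = list(
      "uMXP"               = c(mmad_um = 6.54, gsd = 1.8),
      "uMXP + IH70"        = c(mmad_um = 7.18, gsd = 1.8),
      "uMXP + IH70_MgSt"   = c(mmad_um = 7.43, gsd = 1.8),
      "MXPspd"             = c(mmad_um = 3.41, gsd = 1.8),
      "MXPspd + IH70"      = c(mmad_um = 3.82, gsd = 1.8),
      "MXPspd + IH70_MgSt" = c(mmad_um = 3.11, gsd = 1.8)
    ),
    retention = c(device = 0.08, capsule = 0.05),
    noise = c(angle_sd_deg = 0.5, impactor_cv = 0.05, content_sd_pct = 3)
  )
}

#' Generate replicate contact angles consistent with known components
#'
#' Forward-solves the Wu relation for the exact contact angle of each probe
#' liquid on a solid of known components, then adds Gaussian replicate
#' noise in degrees (emulating triplicate goniometry).
#'
#' @param gamma_sd,gamma_sp True solid components, mN/m.
#' @param liquids List of [probe_liquid()] objects.
#' @param n_replicates Replicates per liquid.
#' @param noise_sd_deg Gaussian SD of angle noise, degrees (>= 0).
#' @param seed Optional integer seed.
#' @param material Material label.
#' @return Data frame with columns `material`, `liquid`, `replicate`,
#'   `theta_deg`.
#' @export
#' @examples
#' gen_contact_angles(42.07, 33.18, noise_sd_deg = 0, n_replicates = 1)
gen_contact_angles <- function(gamma_sd, gamma_sp,
                               liquids = default_probe_liquids(),
                               n_replicates = 3, noise_sd_deg = 0.5,
                               seed = NULL, material = "synthetic") {
  if (noise_sd_deg < 0) stop("noise SD must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(liquids, function(liq) {
    theta <- forward_contact_angle(gamma_sd, gamma_sp, liq)
    data.frame(material = material, liquid = liq$name,
               replicate = seq_len(n_replicates),
               theta_deg = pmin(pmax(
                 theta + stats::rnorm(n_replicates, 0, noise_sd_deg), 0),
                 179.9),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Average replicate angles into a contact-angle set
#'
#' @param angle_df Data frame as produced by [gen_contact_angles()] (or
#'   read from CSV): columns `material`, `liquid`, `theta_deg`.
#' @param material Which material to extract (default: the only one).
#' @return A [contact_angle_set()] of per-liquid mean angles, with the
#'   per-liquid SD in attribute `"sd_deg"`.
#' @export
mean_contact_angles <- function(angle_df, material = NULL) {
  stopifnot(all(c("material", "liquid", "theta_deg") %in% names(angle_df)))
  if (is.null(material)) {
    material <- unique(angle_df$material)
    if (length(material) != 1L) {
      stop("multiple materials present; specify one", call. = FALSE)
    }
  }
  df <- angle_df[angle_df$material == material, , drop = FALSE]
  if (!nrow(df)) stop("material '", material, "' not found", call. = FALSE)
  means <- tapply(df$theta_deg, df$liquid, mean)
  sds <- tapply(df$theta_deg, df$liquid, stats::sd)
  out <- contact_angle_set(material, stats::setNames(as.numeric(means),
                                                     names(means)))
  attr(out, "sd_deg") <- stats::setNames(as.numeric(sds), names(sds))
  out
}

#' Generate a synthetic impactor run from a lognormal APSD truth
#'
#' Partitions the emitted sized mass onto the impactor stages by the
#' lognormal CDF differences at the stage cut-offs: stage 0 collects all
#' mass coarser than its cut-off, stage i the mass between cut-offs i-1
#' and i, and the filter the tail finer than the last cut-off. Optional
#' multiplicative lognormal noise of coefficient of variation `cv` is
#' applied per location, and device/capsule retention is set aside before
#' the partition.
#'
#' @param mmad_um,gsd True lognormal APSD parameters.
#' @param total_ug Total recovered drug mass, ug.
#' @param retention Named vector `c(device=, capsule=)` of mass fractions
#'   in `[0, 1)`.
#' @param induction_port_frac Fraction of the emitted mass lost in the
#'   induction port (not size-classified).
#' @param cv Multiplicative lognormal noise CV (>= 0; 0 = exact partition).
#' @param seed Optional integer seed.
#' @param flow_l_min Flow rate; sets the default cut-offs.
#' @param stage_ecd_um Stage cut-offs, um.
#' @return An [impactor_run()].
#' @export
gen_impactor_run <- function(mmad_um, gsd, total_ug = 1300,
                             retention = c(device = 0.08, capsule = 0.05),
                             induction_port_frac = 0.1, cv = 0.05,
                             seed = NULL, flow_l_min = 28.3,
                             stage_ecd_um = aci_cutoffs(flow_l_min)) {
  if (mmad_um <= 0 || gsd < 1) stop("invalid APSD truth", call. = FALSE)
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  ret <- retention[c("device", "capsule")]
  if (any(is.na(ret)) || any(ret < 0) || sum(ret) >= 1) {
    stop("retention must name device and capsule fractions summing < 1",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  device <- total_ug * ret[["device"]]
  capsule <- total_ug * ret[["capsule"]]
  emitted <- total_ug - device - capsule
  port <- emitted * induction_port_frac
  sized <- emitted - port
  # undersize fractions at the (decreasing) cut-offs
  under <- stats::plnorm(stage_ecd_um, log(mmad_um), log(gsd))
  stage_frac <- c(1, under[-length(under)]) - under  # stage 0 takes coarse tail
  filter_frac <- under[length(under)]
  masses <- sized * c(stage_frac, filter_frac)
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    masses <- masses * stats::rlnorm(length(masses), -sdlog^2 / 2, sdlog)
  }
  impactor_run(stage_masses = masses[seq_along(stage_ecd_um)],
               filter_mass = masses[length(masses)],
               device_mass = device, capsule_mass = capsule,
               induction_port_mass = port, flow_l_min = flow_l_min,
               stage_ecd_um = stage_ecd_um)
}

#' Generate content-uniformity samples around a label claim
#'
#' @param label_claim_pct Nominal content (default 100%).
#' @param bias_pct Systematic offset, percentage points.
#' @param sd_pct Gaussian SD, percentage points (>= 0).
#' @param n Number of dosage units (>= 2).
#' @param seed Optional integer seed.
#' @return Numeric vector of unit contents, % of label claim (floored at 0).
#' @export
gen_uniformity_samples <- function(label_claim_pct = 100, bias_pct = 0,
                                   sd_pct = 3, n = 10, seed = NULL) {
  if (n < 2) stop("need n >= 2", call. = FALSE)
  if (sd_pct < 0) stop("sd must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  pmax(label_claim_pct + bias_pct + stats::rnorm(n, 0, sd_pct), 0)
}
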