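# Shared readers/writers, pipeline configuration and the umbrella pipeline
# run tying energetics -> blend -> impactor -> lung simulation together.
# Plain CSV/JSON only; all tables carry unit-suffixed column names.

#' Read contact angles from CSV
#'
#' Expected columns: `material`, `liquid`, `theta_deg` (replicates allowed:
#' they are averaged by [mean_contact_angles()] downstream).
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_angles_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("material", "liquid", "theta_deg")
  if (!all(need %in% names(df))) {
    stop("angles CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Read probe liquids from CSV
#'
#' Expected columns: `liquid`, `gamma_d_mN_m`, `gamma_p_mN_m`.
#'
#' @param path CSV path.
#' @return Named list of [probe_liquid()] objects.
#' @export
read_liquids_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("liquid", "gamma_d_mN_m", "gamma_p_mN_m")
  if (!all(need %in% names(df))) {
    stop("liquids CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(
    lapply(seq_len(nrow(df)), function(i) {
      probe_liquid(df$liquid[i], df$gamma_d_mN_m[i], df$gamma_p_mN_m[i])
    }),
    df$liquid
  )
}

#' Read an impactor run from a long-format CSV
#'
#' Expected columns: `location`, `mass_ug`. Locations: `device`, `capsule`,
#' `induction_port`, optional `mouthpiece`, `stage0`..`stageN`, `filter`.
#'
#' @param path CSV path.
#' @param flow_l_min Flow rate, L/min.
#' @param stage_ecd_um Stage cut-offs, um (default from [aci_cutoffs()]).
#' @return An [impactor_run()].
#' @export
read_impactor_csv <- function(path, flow_l_min = 28.3,
                              stage_ecd_um = aci_cutoffs(flow_l_min)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("location", "mass_ug") %in% names(df))) {
    stop("impactor CSV must have columns: location, mass_ug", call. = FALSE)
  }
  get1 <- function(loc, default = NA_real_) {
    v <- df$mass_ug[df$location == loc]
    if (!length(v)) default else sum(v)
  }
  stage_names <- paste0("stage", seq_along(stage_ecd_um) - 1L)
  stages <- vapply(stage_names, get1, numeric(1))
  if (any(is.na(stages))) {
    stop("missing stage rows: ",
         paste(stage_names[is.na(stages)], collapse = ", "), call. = FALSE)
  }
  filt <- get1("filter")
  if (is.na(filt)) stop("missing 'filter' row", call. = FALSE)
  impactor_run(stage_masses = stages, filter_mass = filt,
               device_mass = get1("device", 0),
               capsule_mass = get1("capsule", 0),
               induction_port_mass = get1("induction_port", 0),
               mouthpiece_mass = get1("mouthpiece", 0),
               flow_l_min = flow_l_min, stage_ecd_um = stage_ecd_um)
}

#' Pipeline configuration
#'
#' Validated bundle of every knob the pipeline uses. Unknown keys are
#' rejected so typos fail loudly.
#'
#' @param truth Synthetic truth list, see [synthetic_truth()].
#' @param seed Integer master seed.
#' @param n_particles Monte Carlo particles per simulated formulation.
#' @param breath_holds_s Breath-hold durations to simulate, s.
#' @param fpf_basis FPF denominator, see [fine_particle_fractions()].
#' @param flow_l_min Impactor flow, L/min.
#' @param frc_ml Lung functional residual capacity, mL.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(truth = synthetic_truth(), seed = 1,
                            n_particles = 2e4, breath_holds_s = c(5, 10),
                            fpf_basis = "emitted", flow_l_min = 28.3,
                            frc_ml = 3300) {
  cfg <- list(truth = truth, seed = as.integer(seed),
              n_particles = as.integer(n_particles),
              breath_holds_s = breath_holds_s, fpf_basis = fpf_basis,
              flow_l_min = flow_l_min, frc_ml = frc_ml)
  stopifnot(cfg$seed >= 0, cfg$n_particles >= 100,
            all(cfg$breath_holds_s >= 0),
            fpf_basis %in% c("emitted", "recovered", "sized"))
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic pipeline
#'
#' Generates synthetic inputs from the configured truth, then executes
#' surface energetics, blend/dose arithmetic, impactor reduction and the
#' lung deposition simulation in order. Deterministic for a fixed config:
#' every stage derives its seed from the master seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, writes
#'   `surface_energy.csv`, `interactions.csv`, `blends.csv`,
#'   `aerodynamics.csv`, `deposition.csv` and `config.json` there.
#' @return List with data frames `surface_energy`, `interactions`,
#'   `blends`, `aerodynamics`, `deposition`, plus the echoed `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- config$truth
  seed <- config$seed

  # --- surface energetics --------------------------------------------------
  materials <- names(truth$surface_energy)
  solved <- list()
  se_rows <- vector("list", length(materials))
  for (i in seq_along(materials)) {
    m <- materials[i]
    comp <- truth$surface_energy[[m]]
    ang <- gen_contact_angles(comp[["gamma_sd"]], comp[["gamma_sp"]],
                              n_replicates = 3,
                              noise_sd_deg = truth$noise[["angle_sd_deg"]],
                              seed = seed + 101 + i, material = m)
    cas <- mean_contact_angles(ang)
    se <- solve_wu(cas)
    solved[[m]] <- se
    se_rows[[i]] <- data.frame(
      material = m,
      theta_water_deg = cas$theta_deg[["water"]],
      theta_diiodomethane_deg = cas$theta_deg[["diiodomethane"]],
      gamma_sd_mN_m = se$gamma_sd, gamma_sp_mN_m = se$gamma_sp,
      gamma_s_mN_m = se$gamma_s, polarity_pct = se$polarity_pct,
      cohesion_work_mN_m = se$cohesion_work, stringsAsFactors = FALSE)
  }
  surface_energy_df <- do.call(rbind, se_rows)

  # --- interaction pairs ---------------------------------------------------
  pair_rows <- lapply(names(truth$blends), function(bn) {
    comps <- names(truth$blends[[bn]])
    drug <- comps[comps %in% c("uMXP", "MXPspd")][1]
    carrier <- if ("MgSt" %in% comps) paste0("IH70_MgSt") else "IH70"
    ip <- interaction_pair(solved[[drug]], solved[[carrier]],
                           d50_1 = truth$d50_um[[drug]],
                           d50_2 = truth$d50_um[["IH70"]])
    data.frame(pair = bn, w_adh_mN_m = ip$w_adh, f_adh_mN = ip$f_adh,
               s21 = ip$s21, stringsAsFactors = FALSE)
  })
  interactions_df <- do.call(rbind, pair_rows)

  # --- blends, fill mass, uniformity --------------------------------------
  blend_rows <- lapply(names(truth$blends), function(bn) {
    comps <- truth$blends[[bn]]
    drug <- names(comps)[names(comps) %in% c("uMXP", "MXPspd")][1]
    bl <- blend_composition(comps, drug)
    fr <- drug_fraction(bl)
    contents <- gen_uniformity_samples(
      sd_pct = truth$noise[["content_sd_pct"]], n = 10,
      seed = seed + 211 + match(bn, names(truth$blends)))
    u <- assess_uniformity(contents)
    data.frame(blend = bn, drug_fraction = fr,
               fill_mass_mg = fill_mass(truth$dose_mg, fr),
               content_mean_pct = u$mean_pct, content_rsd_pct = u$rsd_pct,
               pass_pharmacopeia = u$pass_pharmacopeia,
               pass_industry = u$pass_industry, stringsAsFactors = FALSE)
  })
  blends_df <- do.call(rbind, blend_rows)

  # --- impactor reduction --------------------------------------------------
  aero_rows <- lapply(names(truth$apsd), function(fn) {
    ap <- truth$apsd[[fn]]
    run <- gen_impactor_run(ap[["mmad_um"]], ap[["gsd"]],
                            retention = truth$retention,
                            cv = truth$noise[["impactor_cv"]],
                            seed = seed + 307 + match(fn, names(truth$apsd)),
                            flow_l_min = config$flow_l_min)
    res <- reduce_impactor_run(run, basis = config$fpf_basis)
    data.frame(formulation = fn, ef_pct = res$ef_pct,
               fpf5_pct = res$fpf5_pct, fpf3_pct = res$fpf3_pct,
               mmad_um = res$mmad_um, gsd = res$gsd,
               r_squared = res$r_squared, stringsAsFactors = FALSE)
  })
  aerodynamics_df <- do.call(rbind, aero_rows)

  # --- lung deposition -----------------------------------------------------
  geometry <- airway_geometry(config$frc_ml)
  dep_rows <- list()
  for (fn in names(truth$apsd)) {
    for (bh in config$breath_holds_s) {
      ap <- truth$apsd[[fn]]
      res <- simulate_deposition(
        ap[["mmad_um"]], ap[["gsd"]], copd_profile(bh),
        n = config$n_particles,
        seed = seed + 401 + match(fn, names(truth$apsd)),
        geometry = geometry)
      dep_rows[[length(dep_rows) + 1L]] <- data.frame(
        formulation = fn, breath_hold_s = bh, et_pct = res$et_pct,
        lung_pct = res$lung_pct, bronchial_pct = res$bronchial_pct,
        acinar_pct = res$acinar_pct, exh_pct = res$exh_pct,
        stringsAsFactors = FALSE)
    }
  }
  deposition_df <- do.call(rbind, dep_rows)

  out <- list(surface_energy = surface_energy_df,
              interactions = interactions_df, blends = blends_df,
              aerodynamics = aerodynamics_df, deposition = deposition_df,
              config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("surface_energy", "interactions", "blends",
                 "aerodynamics", "deposition")) {
      utils::write.csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(unclass(config),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
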