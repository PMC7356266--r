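# Shared fixtures: the published contact-angle / surface-energy /
# interaction reference rows used across the energetics tests, and small
# builders for synthetic runs.

# Per-material water/diiodomethane contact angles with the expected Wu
# solution (energies mN/m, polarity %, cohesion work mN/m).
ref_materials <- list(
  uMXP = list(theta = c(water = 25.13, diiodomethane = 23.53),
              gamma_sd = 42.07, gamma_sp = 33.18, gamma_s = 75.25,
              polarity = 44.09, wc = 150.50),
  MXPspd = list(theta = c(water = 26.40, diiodomethane = 29.90),
                gamma_sd = 39.93, gamma_sp = 33.44, gamma_s = 73.37,
                polarity = 45.58, wc = 146.74),
  IH70 = list(theta = c(water = 3.30, diiodomethane = 6.00),
              gamma_sd = 45.58, gamma_sp = 36.88, gamma_s = 82.46,
              polarity = 44.72, wc = 164.92),
  IH70_MgSt = list(theta = c(water = 64.60, diiodomethane = 62.00),
                   gamma_sd = 26.07, gamma_sp = 19.22, gamma_s = 45.29,
                   polarity = 42.44, wc = 90.58),
  MgSt = list(theta = c(water = 102.63, diiodomethane = 68.64),
              gamma_sd = 24.33, gamma_sp = 2.64, gamma_s = 26.96,
              polarity = 9.79, wc = 53.92)
)

# Drug-on-carrier pairs: printed work of adhesion (used for the force),
# median diameters (um), published force (mN) and spreading coefficient.
ref_pairs <- list(
  "uMXP + IH70" = list(drug = "uMXP", carrier = "IH70",
                       w_adh_printed = 104.98, d50 = c(3.602, 215.00),
                       f_adh = 1.168e-3, s21 = 6.87),
  "uMXP + IH70_MgSt" = list(drug = "uMXP", carrier = "IH70_MgSt",
                            w_adh_printed = 76.55, d50 = c(3.602, 215.00),
                            f_adh = 0.849e-3, s21 = -37.44),
  "MXPspd + IH70" = list(drug = "MXPspd", carrier = "IH70",
                         w_adh_printed = 102.67, d50 = c(2.109, 215.00),
                         f_adh = 0.674e-3, s21 = 8.55),
  "MXPspd + IH70_MgSt" = list(drug = "MXPspd", carrier = "IH70_MgSt",
                              w_adh_printed = 76.80, d50 = c(2.109, 215.00),
                              f_adh = 0.493e-3, s21 = -34.83)
)

solve_ref_material <- function(material) {
  solve_wu(contact_angle_set(material, ref_materials[[material]]$theta))
}

# impactor run with an exact lognormal partition and no losses anywhere
exact_lognormal_run <- function(mmad, gsd, total = 1000) {
  gen_impactor_run(mmad, gsd, total_ug = total,
                   retention = c(device = 0, capsule = 0),
                   induction_port_frac = 0, cv = 0)
}
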