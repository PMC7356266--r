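# Deterministic Weibel-type 24-generation airway scaffold. Per-particle
# stochastic perturbation of tube dimensions (standing in for airway-cast
# morphometric distributions) is applied at simulation time, not here.

# Classic symmetric-dichotomy morphometry (lengths/diameters in cm at a
# reference lung volume of ~4800 mL); generation 0 is the trachea.
.weibel_length_cm <- c(12.0, 4.76, 1.90, 0.76, 1.27, 1.07, 0.90, 0.76,
                       0.64, 0.54, 0.46, 0.39, 0.33, 0.27, 0.23, 0.20,
                       0.165, 0.141, 0.117, 0.099, 0.083, 0.070, 0.059, 0.050)
.weibel_diam_cm <- c(1.80, 1.22, 0.83, 0.56, 0.45, 0.35, 0.28, 0.23,
                     0.186, 0.154, 0.130, 0.109, 0.095, 0.082, 0.074, 0.066,
                     0.060, 0.054, 0.050, 0.047, 0.045, 0.043, 0.041, 0.041)
.weibel_ref_volume_ml <- 4800

#' Weibel-type airway geometry scaled to a functional residual capacity
#'
#' Symmetric 24-generation dichotomous tree. Linear dimensions are scaled
#' isometrically by `(frc_ml / 4800)^(1/3)`. The volume unaccounted for by
#' the conducting tubes is assigned as alveolar volume to the alveolated
#' generations (18-23, proportional to airway multiplicity) so that the
#' cumulative tree volume equals `frc_ml`; this drives how deep an inhaled
#' air parcel penetrates.
#'
#' @param frc_ml Functional residual capacity, mL. Default 3300 (adult).
#' @return Object of class `airway_geometry`: data frame with one row per
#'   generation (`generation`, `length_cm`, `diam_cm`, `multiplicity`,
#'   `tube_volume_ml` (all tubes of the generation), `alveolar_volume_ml`,
#'   `cum_volume_ml`, `region`), plus attribute `frc_ml`.
#' @export
airway_geometry <- function(frc_ml = 3300) {
  stopifnot(is.numeric(frc_ml), frc_ml > 500)
  s <- (frc_ml / .weibel_ref_volume_ml)^(1 / 3)
  g <- 0:23
  len <- .weibel_length_cm * s
  dia <- .weibel_diam_cm * s
  mult <- 2^g
  tube_vol <- mult * pi * (dia / 2)^2 * len           # cm3 == mL
  alv <- numeric(24)
  alveolated <- g >= 18
  residual <- frc_ml - sum(tube_vol)
  if (residual > 0) {
    alv[alveolated] <- residual * mult[alveolated] / sum(mult[alveolated])
  }
  geom <- data.frame(
    generation = g, length_cm = len, diam_cm = dia, multiplicity = mult,
    tube_volume_ml = tube_vol, alveolar_volume_ml = alv,
    cum_volume_ml = cumsum(tube_vol + alv),
    region = ifelse(g <= 16, "bronchial", "acinar"),
    stringsAsFactors = FALSE
  )
  structure(geom, class = c("airway_geometry", "data.frame"),
            frc_ml = frc_ml)
}

#' Breathing profile
#'
#' @param inhaled_volume_l Inhaled air volume, L (> 0).
#' @param inhalation_time_s Inhalation duration, s (> 0).
#' @param breath_hold_s Post-inhalation pause, s (>= 0).
#' @param exhalation_time_s Exhalation duration, s (> 0).
#' @return Object of class `breathing_profile`; `flow_l_min` is the mean
#'   inspiratory flow `volume / inhalation time`.
#' @export
#' @examples
#' copd_profile()  # 1.7 L over 3.2 s, 5 s hold, 3 s exhalation
breathing_profile <- function(inhaled_volume_l, inhalation_time_s,
                              breath_hold_s = 0, exhalation_time_s) {
  vals <- c(inhaled_volume_l, inhalation_time_s, exhalation_time_s)
  if (any(!is.finite(vals)) || any(vals <= 0) || !is.finite(breath_hold_s) ||
      breath_hold_s < 0) {
    stop("volume and times must be positive; breath hold non-negative",
         call. = FALSE)
  }
  structure(
    list(inhaled_volume_l = inhaled_volume_l,
         inhalation_time_s = inhalation_time_s,
         breath_hold_s = breath_hold_s,
         exhalation_time_s = exhalation_time_s,
         flow_l_min = 60 * inhaled_volume_l / inhalation_time_s),
    class = "breathing_profile"
  )
}

#' COPD breathing profile for DPI inhalation
#'
#' Mean breathing parameters registered for COPD patients inhaling through
#' a capsule DPI device: 1.7 L inhaled over 3.2 s (mean inspiratory flow
#' ~31.9 L/min), 3 s exhalation, with a post-inhalation breath hold of 5 or
#' 10 s.
#'
#' @param breath_hold_s Breath hold, s (default 5).
#' @return A [breathing_profile()].
#' @export
copd_profile <- function(breath_hold_s = 5) {
  breathing_profile(inhaled_volume_l = 1.7, inhalation_time_s = 3.2,
                    breath_hold_s = breath_hold_s, exhalation_time_s = 3)
}
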