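# Blend composition arithmetic, capsule fill mass, spectrophotometric drug
# content with LOD/LOQ gating, and content-uniformity assessment.

#' Blend composition
#'
#' @param components Named numeric vector of component masses in grams,
#'   all > 0.
#' @param drug_component Name of the active ingredient among the components.
#' @return Object of class `blend_composition`.
#' @export
#' @examples
#' blend_composition(c(drug = 0.2, IH70 = 1.956, MgSt = 0.044), "drug")
blend_composition <- function(components, drug_component) {
  if (!is.numeric(components) || is.null(names(components)) ||
      any(!nzchar(names(components)))) {
    stop("'components' must be a named numeric vector of masses (g)",
         call. = FALSE)
  }
  if (any(!is.finite(components)) || any(components <= 0)) {
    stop("component masses must be positive", call. = FALSE)
  }
  if (anyDuplicated(names(components))) {
    stop("component names must be unique", call. = FALSE)
  }
  if (!drug_component %in% names(components)) {
    stop("drug component '", drug_component, "' not found in blend",
         call. = FALSE)
  }
  structure(list(components = components, drug_component = drug_component),
            class = "blend_composition")
}

#' Mass fractions of a blend
#'
#' @param blend A [blend_composition()].
#' @return Named numeric vector of fractions summing to 1.
#' @export
mass_fractions <- function(blend) {
  stopifnot(inherits(blend, "blend_composition"))
  blend$components / sum(blend$components)
}

#' Drug mass fraction of a blend
#'
#' @param blend A [blend_composition()].
#' @return Drug mass / total mass.
#' @export
drug_fraction <- function(blend) {
  unname(mass_fractions(blend)[blend$drug_component])
}

#' Capsule fill mass delivering a target drug dose
#'
#' @param dose_mg Target drug dose per capsule, mg.
#' @param drug_fraction Drug mass fraction of the blend, in (0, 1].
#' @return Fill mass, mg (full precision; round to 0.1 mg for reports).
#' @export
#' @examples
#' fill_mass(1.3, 0.2 / 2.2)  # 14.3 mg
fill_mass <- function(dose_mg, drug_fraction) {
  if (!is.numeric(dose_mg) || any(dose_mg < 0)) {
    stop("dose must be non-negative (mg)", call. = FALSE)
  }
  if (!is.numeric(drug_fraction) || any(drug_fraction <= 0) ||
      any(drug_fraction > 1)) {
    stop("drug fraction must lie in (0, 1]", call. = FALSE)
  }
  dose_mg / drug_fraction
}

#' Spectrophotometric calibration line
#'
#' Zero-intercept Beer-Lambert calibration `absorbance = slope * conc` with
#' detection (LOD) and quantification (LOQ) limits.
#'
#' @param slope Calibration slope, mL/ug (> 0).
#' @param lod Limit of detection, ug/mL.
#' @param loq Limit of quantification, ug/mL (> lod).
#' @param wavelength_nm Detection wavelength, nm.
#' @return Object of class `calibration_line`.
#' @export
calibration_line <- function(slope, lod, loq, wavelength_nm = NA_real_) {
  if (!is.numeric(slope) || slope <= 0) stop("slope must be > 0", call. = FALSE)
  if (!is.numeric(lod) || !is.numeric(loq) || lod < 0 || lod >= loq) {
    stop("need 0 <= lod < loq", call. = FALSE)
  }
  structure(list(slope = slope, lod = lod, loq = loq,
                 wavelength_nm = wavelength_nm),
            class = "calibration_line")
}

#' Convert absorbance to concentration with LOD/LOQ qualifier
#'
#' @param a Absorbance reading(s), >= 0.
#' @param cal A [calibration_line()].
#' @return Data frame with columns `absorbance`, `conc_ug_ml` and
#'   `qualifier` (one of `"quantifiable"`, `"detected-below-LOQ"`,
#'   `"below-LOD"`).
#' @export
absorbance_to_conc <- function(a, cal) {
  stopifnot(inherits(cal, "calibration_line"))
  if (!is.numeric(a) || any(!is.finite(a)) || any(a < 0)) {
    stop("absorbance must be non-negative", call. = FALSE)
  }
  conc <- a / cal$slope
  qualifier <- ifelse(conc >= cal$loq, "quantifiable",
                      ifelse(conc >= cal$lod, "detected-below-LOQ",
                             "below-LOD"))
  data.frame(absorbance = a, conc_ug_ml = conc, qualifier = qualifier,
             stringsAsFactors = FALSE)
}

#' Assess content uniformity of dosage units
#'
#' Applies the pharmacopoeial blend-uniformity rule (every unit within
#' 85-115% of label claim and relative standard deviation of the units
#' <= 6%) and the stricter common industrial rule (every unit within
#' 90-110%). The RSD uses the sample (n-1) standard deviation, the
#' pharmacopoeial convention for 10 dosage units.
#'
#' @param contents_pct Numeric vector (length >= 2) of unit contents as
#'   percent of label claim.
#' @return Object of class `uniformity_report`: `contents_pct`, `mean_pct`,
#'   `rsd_pct`, `pass_pharmacopeia`, `pass_industry`.
#' @export
assess_uniformity <- function(contents_pct) {
  if (!is.numeric(contents_pct) || length(contents_pct) < 2L) {
    stop("need at least 2 unit contents", call. = FALSE)
  }
  if (any(!is.finite(contents_pct)) || any(contents_pct < 0)) {
    stop("contents must be non-negative percentages", call. = FALSE)
  }
  m <- mean(contents_pct)
  rsd <- if (m > 0) 100 * stats::sd(contents_pct) / m else 0
  structure(
    list(contents_pct = contents_pct, mean_pct = m, rsd_pct = rsd,
         pass_pharmacopeia = all(contents_pct >= 85 & contents_pct <= 115) &&
           rsd <= 6,
         pass_industry = all(contents_pct >= 90 & contents_pct <= 110)),
    class = "uniformity_report"
  )
}

#' @export
print.uniformity_report <- function(x, ...) {
  cat(sprintf(
    "<uniformity_report> n = %d  mean %.2f%%  RSD %.2f%%\n  pharmacopoeial (85-115%%, RSD<=6%%): %s   industrial (90-110%%): %s\n",
    length(x$contents_pct), x$mean_pct, x$rsd_pct,
    if (x$pass_pharmacopeia) "PASS" else "FAIL",
    if (x$pass_industry) "PASS" else "FAIL"))
  invisible(x)
}
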