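---
title: "Methods: surface energetics, impactor reduction and stochastic lung deposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surface energetics, impactor reduction and stochastic lung deposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpiaero)
```

# Scope

`dpiaero` implements the computational chain of a carrier-based dry powder
inhaler (DPI) formulation study: physical blends of a micron-scale drug and
a large lactose carrier (optionally surface-coated with magnesium
stearate), characterised by surface energetics, blend/dose arithmetic,
cascade-impactor aerodynamics, and a Monte Carlo whole-lung deposition
simulation. Process execution (milling, spray drying), solid-state
analytics (XRPD, SEM), laser diffraction itself, and dissolution assays are
out of scope; their outputs (median diameters, compositions) are inputs
here.

# Surface energetics

## Model

For a probe liquid $l$ with known dispersive/polar surface-tension parts
$(\gamma_l^d, \gamma_l^p)$ resting on a solid with unknown parts
$(\gamma_s^d, \gamma_s^p)$, the harmonic-mean (Wu) combining rule ties the
measured contact angle $\Theta$ to the unknowns:

$$(1+\cos\Theta)\,\gamma_l
  = \frac{4\gamma_s^d\gamma_l^d}{\gamma_s^d+\gamma_l^d}
  + \frac{4\gamma_s^p\gamma_l^p}{\gamma_s^p+\gamma_l^p}.$$

Two liquids of well-separated polarity (water: 22.6/50.2 mN/m;
diiodomethane: 49/1.8 mN/m — overridable) give two equations in two
unknowns. Each right-hand side is strictly increasing in both unknowns, so
the root is unique in the positive quadrant. `solve_wu()` uses a damped
Newton iteration with the analytic Jacobian, started from the Owens–Wendt
(geometric-mean) closed form, which is linear in
$(\sqrt{\gamma_s^d},\sqrt{\gamma_s^p})$; a nested-bisection fallback on
$[10^{-6}, 500]$ mN/m covers pathological starts. Convergence is declared
at a residual below $10^{-10}$ mN/m per equation and verified below
$10^{-8}$; angle sets admitting no positive root are rejected as
non-physical. Angles $\ge 90^\circ$ (negative $\cos\Theta$) are valid and
exercised by strongly hydrophobic materials such as magnesium stearate.

Derived per-material quantities: total energy
$\gamma_s=\gamma_s^d+\gamma_s^p$, polarity $100\,\gamma_s^p/\gamma_s$, and
work of cohesion $W_c = 2\gamma_s$.

## Pair metrics

For a drug (1) on a carrier (2):

* work of adhesion
  $W_{adh} = 4\left[\frac{\gamma_1^d\gamma_2^d}{\gamma_1^d+\gamma_2^d} +
  \frac{\gamma_1^p\gamma_2^p}{\gamma_1^p+\gamma_2^p}\right]$ (symmetric;
  self-adhesion equals cohesion);
* Derjaguin adhesion force
  $F_{adh} = 2\pi \frac{R_A R_B}{R_A+R_B} W_{adh}$ with $R_i = D(0.5)_i/2$.
  Units are handled inside `adhesion_force()`: with the reduced radius in
  micrometres and $W_{adh}$ in mN/m, $F$ in mN carries a $10^{-6}$ factor,
  which reproduces published forces of order $10^{-3}$ mN for micron drugs
  on a 215 µm carrier;
* spreading coefficient $S_{21} = W_{adh} - W_{c,\mathrm{drug}}$, positive
  when film spreading of the drug over the carrier is favourable.

Published tables of this kind are sometimes internally inconsistent: the
work-of-adhesion column may disagree with the harmonic-mean value computed
from the same study's component table, while the spreading coefficients
are consistent with the component route and the forces are consistent with
the printed work-of-adhesion column. `interaction_pair()` therefore
accepts a `w_adh_override` used for the force only, and always reports the
harmonic-mean value alongside; neither number is silently "corrected".

# Blend design

Mass fractions, capsule fill mass (`dose / drug fraction`, reported to
0.1 mg), Beer–Lambert inversion of absorbance with LOD/LOQ gating, and
content uniformity. The uniformity rule implemented is the stated
pharmacopoeial blend criterion — every unit within 85–115% of label claim
and RSD of the units ≤ 6% — plus the common industrial 90–110% band. The
full two-stage compendial uniformity-of-dosage-units procedure is
deliberately not implemented: the source study applies only the
single-stage rule. RSD uses the sample ($n-1$) standard deviation, the
convention for 10 dosage units.

# Impactor reduction

An eight-stage Andersen cascade impactor run is reduced as follows.

1. **Emitted fraction**: percentage of total recovered drug outside the
   device and capsules.
2. **Cumulative undersize**: for each stage cut-off diameter (ECD), the
   percentage of *sized* mass (stages + filter; induction port and
   mouthpiece count as emitted but not sized) on stages with smaller
   cut-offs plus the filter.
3. **Log-probit fit**: ordinary least squares of
   $\Phi^{-1}(\text{cum}/100)$ on $\ln(\text{ECD})$, excluding points at
   exactly 0% or 100% (infinite probit). Then
   $\mathrm{MMAD}=\exp(-a/b)$, $\mathrm{GSD}=\exp(1/b)$. For lognormal
   mass distributions this is exact ($R^2 = 1$).
4. **Fine particle fractions** below 5 and 3 µm, evaluated from the fitted
   line (a piecewise-linear probit–log interpolation is available as an
   option) and rescaled to the chosen denominator.

Choices made where the source is silent:

* **Stage cut-offs** default to the standard published 28.3 L/min set
  {9.0, 5.8, 4.7, 3.3, 2.1, 1.1, 0.7, 0.4} µm for stages 0–7; they are
  calibration constants, kept in `aci_cutoffs()` and overridable.
* **FPF denominator** is not universally standardised; the default is the
  emitted dose (consistent with an emitted-fraction definition that
  excludes device and capsule), with `recovered` and `sized` switches.
  Since published FPF tables rarely state the denominator, both routes are
  exposed rather than guessed.

# Stochastic lung deposition

A particle-tracking Monte Carlo model, structurally a simplified stochastic
whole-lung model: it is **not** a re-implementation of any proprietary
code lineage, and no CFD, airway-narrowing disease model or clearance is
included.

* **Geometry.** A deterministic Weibel-type symmetric 24-generation tree,
  scaled isometrically to a functional residual capacity (default
  3300 mL); the volume not accounted for by conducting tubes is assigned
  to the alveolated generations (18–23) so the cumulative tree volume
  equals the FRC. Morphometric variability (airway-cast distributions are
  not reproducible from the source) is emulated by per-particle,
  per-generation lognormal perturbations of tube length and diameter
  (CV 0.1 by default) and per-tube gravity angles drawn uniformly on
  0–90°; the branching angle is fixed at 35° by default.
* **Extrathoracic filter.** An empirical mouth–throat impaction efficiency
  $1-\exp(-a\,(d_{ae}^2 Q)^b)$, $d$ in µm, $Q$ in L/min, with $a=2.78
  \times 10^{-4}$, $b=1.152$ — constants of the empirical fit are config
  arguments, chosen to reproduce the steep measured rise of mouth–throat
  deposition between ~3 and ~10 µm at DPI flows. The ultrafine diffusive
  term is negligible at drug-aerosol sizes, so the small-particle limit is
  ≈ 0. Exhaled particles pass the extrathoracic region without capture
  (pass-through), so ET deposition is an inhalation-phase event only.
* **Tube deposition.** Per generation, mechanism efficiencies are combined
  as $1-(1-\eta_{imp})(1-\eta_{sed})(1-\eta_{diff})$ (independent
  mechanisms, each separately testable): impaction in a bent tube in
  Stokes-number form (full capture at $\theta\,\mathrm{Stk} \ge 1$),
  gravitational sedimentation in an inclined tube
  $1-\exp(-2 v_s t\cos\varphi/(\pi R))$, and Gormley–Kennedy diffusion for
  laminar flow. Aerodynamic diameters use the unit-density convention
  (density/shape already folded into $d_{ae}$), with Cunningham slip.
* **Breathing.** Constant inspiratory flow `volume / time` (only mean
  breathing parameters are available; no intra-breath waveform). The
  default profile is COPD-like: 1.7 L inhaled over 3.2 s (~31.9 L/min),
  3 s exhalation, breath holds of 0/5/10 s. A particle's penetration
  depth is set by the air volume inhaled after its (uniform) entry time
  against the cumulative tree volume. The breath hold applies zero-flow
  sedimentation plus first-mode cylindrical diffusion in the resting
  generation for the hold duration; exhalation retraces the path
  proximally at the exhalation flow.
* **Random numbers.** One seeded generator per run, consumed in
  fixed-length blocks per phase and generation regardless of particle
  state. Two runs differing only in breath-hold duration therefore share
  every random draw (common random numbers), which makes breath-hold
  comparisons monotone by the physics (longer hold ⇒ larger deposition
  probability at identical uniforms) rather than by chance, and makes
  results bit-reproducible at fixed seed and `n` (single-threaded).

Reported fractions (ET / per-generation lung, split bronchial = gens 0–16
and acinar = 17–23 / exhaled) are percentages of the emitted dose
(everything entering the mouth) and sum to 100 exactly — mass conservation
is an identity of the bookkeeping, tested to $10^{-9}$.

# Synthetic data

Generators produce every pipeline input with the statistical structure the
analysis assumes, so all stages are testable offline:

* **Contact angles**: exact forward solution of the Wu relation per liquid
  at the true components, plus Gaussian replicate noise in degrees
  (default SD 0.5°, emulating triplicate goniometry). Zero noise inverts
  exactly.
* **Impactor runs**: emitted sized mass partitioned by lognormal CDF
  differences at the stage cut-offs, multiplicative lognormal noise per
  location (default CV 5%, consistent with the few-percent SDs typical of
  replicate impactor tables), device/capsule retention (defaults 8%/5%,
  chosen to give emitted fractions in the published 70–92% range) and a
  10% induction-port loss. Zero noise round-trips MMAD/GSD to < 0.5%.
* **Uniformity samples**: Gaussian contents around label claim (default
  SD 3%, matching a "homogeneous, SD < 5%" blend).

Default truth values (surface-energy components, D(0.5) medians, blend
masses, MMADs 3.11–7.43 µm, GSD 1.8) are seeded from the published tables
so synthetic outputs are plausible for this formulation class. GSD is not
published per formulation; 1.8 is a typical DPI value, stated once here
and not tuned.

What a green synthetic test does **not** establish: agreement with any
particular laboratory's raw data (per-plate masses and replicate angles
are unpublished), real geometric intersubject variability (our
perturbations are a stated stand-in), or regional deposition accuracy
beyond qualitative orderings (fine APSD ⇒ more lung, breath hold ⇒ less
exhaled).

# Numerical choices and degenerate inputs

* Wu solve: residual tolerance $10^{-10}$ (assert $10^{-8}$), bounds
  $[10^{-6}, 500]$ mN/m, 200 damped-Newton iterations before fallback.
* Log-probit fit: requires ≥ 2 points strictly inside (0, 100)%; a
  non-increasing undersize curve (non-positive slope) is a degenerate
  distribution error, not a silent NaN.
* Probit = standard normal quantile; fits are unweighted OLS.
* Zero sized mass, zero total recovered mass, non-positive diameters,
  colinear probe liquids and invalid breathing profiles raise immediate
  input errors.
* Forces are reported at full precision; published-table formatting (2
  decimals, 3 significant figures × 10⁻³) is applied only in output
  tables.

# Known limitations

* The symmetric Weibel-type tree underestimates path-length dispersion
  relative to asymmetric stochastic morphometries; per-generation numbers
  should be read as indicative.
* The extrathoracic fit is a single-parameter-family impaction curve; it
  ignores nasal routes, device-specific mouthpiece geometry and the
  ultrafine diffusion term.
* Constant-flow inhalation ignores ramp-up effects known to matter for
  DPI de-agglomeration; the impactor stage (not the simulator) is where
  device dispersion physics enters, via the measured APSD.
* The two-liquid harmonic-mean decomposition is one of several surface
  energy conventions; acid–base (three-liquid) decompositions are
  deliberately out of scope.
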