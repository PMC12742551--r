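---
title: "Models and methods behind ionpsqa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ionpsqa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionpsqa)
```

`ionpsqa` models the complete dose-verification chain used in
patient-specific QA (PSQA) of scanned ion beams: a treatment field is
recalculated in a water phantom, delivered to a stack of 24 small-volume
ionization chambers, and judged by normalized dose deviations against
institutional tolerances. This vignette documents the models, the
parameters that matter, and the choices made where the design was
genuinely open. It states no empirical result that the package's tests and
acceptance script do not themselves compute.

## Coordinate convention

All geometry lives in the phantom frame: origin at the center of the
water-phantom entrance window placed at the isocenter; axis A = x = depth
along the beam, axis B = y = vertical, axis C = z = lateral; millimetres
everywhere. Dose-grid voxel centers sit at `origin + (index − 0.5) ·
spacing` on every axis, and the beam always enters perpendicular to the
entrance window (the phantom cannot tilt, so gantry angles never appear in
the phantom frame).

## The synthetic dose engine

The dose engine plays the role of the treatment planning system for
synthetic data. It is deliberately a *plausibility* model: the published
verification procedure depends on having realistic spread-out Bragg peak
(SOBP) dose distributions with correct qualitative structure (entrance
plateau, flat modulated target dose, steep distal falloff, lateral
Gaussian penumbra), not on reproducing any particular facility's beam
data.

**Pristine Bragg curves.** Each energy layer's depth-dose is an analytic
curve: an entrance plateau at a fraction `entrance_to_peak_ratio` of the
peak rising through a Gaussian proximal shoulder (`peak_width`, mm) into
the peak, followed by a Gaussian distal edge whose 80%–20% falloff
distance (`distal_falloff`, mm) scales with range. Per-ion defaults
(`depth_dose_defaults()`): entrance ratios 0.30/0.25/0.15 and falloffs of
1.2%/0.8%/0.5% of range for protons/helium/carbon — range straggling
grows with range and shrinks with ion mass, and heavier ions have sharper,
narrower peaks. The peak sits at `range − 0.9 · distal_falloff`, which
keeps the maximum just proximal of the nominal range and the dose beyond
`range + 3 · distal_falloff` below 1% of the peak (a tested invariant).
The absolute `peak_dose_per_particle` scale (1.5e−6 / 6e−6 / 2.5e−5
Gy·mm² per particle) is set so that a 2 Gy field over a decilitre-scale
target needs on the order of 10⁹ particles, matching the magnitude quoted
for clinical scanned-beam fields. Supported ranges are 2–300 mm; curves
are tabulated at 0.25 mm and evaluated by linear interpolation.

**Dose superposition.** A field's dose is the exact sum over spots of
`N · d_layer(x) · G(y − y₀, z − z₀)` with `G` a normalized 2D Gaussian of
the spot's FWHM, computed separably per layer (depth profile ⊗ lateral
map), so the grid is exactly linear in every spot's particle number — a
property the tests rely on. Nuclear halo, lateral scattering growth with
depth and fragmentation tails are intentionally absent.

**SOBP optimization.** `optimize_sobp()` flattens the central-axis dose by
multiplicative layer-weight iteration: the axis dose is evaluated at every
layer's pristine-peak depth and each weight is scaled by
`prescribed / dose at its own peak` until flat to 0.01% (cap 80
iterations; the update is a Richardson–Lucy-type fixed point that
converges quickly because each layer dominates its own peak). A final
global rescale pins the mean dose over the target region exactly to the
prescription. The procedure is deterministic — no seed enters the
optimizer. Layer spacing defaults scale with peak width (2.5 mm proton,
2 mm helium, 1.5 mm carbon): coarser steps leave visible plateau ripple
for the sharp carbon peaks, which clinically is suppressed by ripple
filters that this model does not include. The template extends the deepest
layer 3 mm past the distal target edge (`distal_margin`) so the plateau
stays flat up to the edge; a 5 cm modulation yields roughly 20–35 layers,
consistent with typical scanned-beam plans. Degenerate inputs are defined:
a single-layer template reduces to closed-form scaling, prescribed dose 0
returns an all-zero field, and a target deeper than the deepest layer is
rejected as infeasible.

**Range shifter.** Modelled purely as a water-equivalent range loss
subtracted from every layer; an optional linear FWHM broadening term
exists but is off by default because scattering physics is out of scope.

## The measurement model

The default stack layout (`default_stack_layout()`) places 6 rows of 4
chambers along the depth axis at 10 mm pitch, lateral offsets ±6/±18 mm,
rows cycling through three height levels (−8/0/+8 mm). The published
system's exact chamber coordinates are not public; these are documented
stand-ins satisfying the stated constraints (24 chambers, three heights,
no overlap). Planned doses are trilinear interpolations of the grid at
each chamber's effective point of measurement.

Simulated readings apply, in order: a per-chamber random position error
(`positioning_sd`, mm), volume averaging over the sensitive volume
(default 30 mm³, a cylinder approximated by its bounding box and
integrated with a fixed 3×3×3 Gauss–Legendre rule — exact for cubic dose
variation, adequate because the trilinear grid is only piecewise linear
anyway), a calibration bias, multiplicative reading noise
(`relative_noise_sd`; noise scales with signal because chamber readings
do), and an additive background offset (`background_offset`, Gy). The
calibration chain (chamber factor, beam-quality factor kQ = 1.026, air
density) is carried in `chamber_spec()` but cancels exactly unless a
human-error mode injects a wrong factor — in routine operation these
corrections are applied consistently on both sides of the comparison.
Three discrete human-error modes mirror the documented failure classes:
`wrong_calibration` (a fractional dose error, default 5%),
`wrong_position` (a stack shift along the depth axis, default 5 mm) and
`wrong_air_gap` (a smaller effective depth shift). With a zero error model
and a point chamber the simulation reproduces the planned doses exactly —
the tested zero-error fixed point of the whole pipeline.

## Verification scoring

Per-chamber deviations are `100 · (measured − planned) / D_max` in percent
of the **whole-field** maximum (taken from the grid, not the chamber
subset, so all positions share one normalization). Gradients are estimated
at the voxel enclosing the chamber from its six ±1-voxel neighbors by
central differences; the three components are combined by Euclidean norm.
Whether the institutional gradient is a norm, a maximum component or a
directional derivative is not published — the norm is the conventional
scalar reduction, and a `"max"` metric is available via
`tolerance_config(gradient_metric = )`. A chamber is deactivated when its
gradient in mGy/mm exceeds `gradient_threshold_fraction` (default 0.05) of
`D_max` expressed in mGy; this matches the dimensionally loose clinical
phrasing "gradient greater than 5% of the maximum dose" by interpreting
the threshold per millimetre. Boundary equality keeps the chamber active,
and all tolerance boundaries are inclusive (benefit of the doubt at exact
equality; both choices are tested explicitly). Summary statistics use the
sample SD (n−1), defined as 0 for a single active chamber; the published
analysis does not state its SD convention, and the sample convention is
the default of every mainstream statistics stack. A field with no active
chambers raises an explicit "no evaluable chambers" error rather than a
silent pass.

The repeat policy encodes the institutional decision path: pass → accept;
first failure → repeat; failure after a repeat → accept with justification
only when at most `k = 2` active chambers lie beyond ±7% and all of them
sit at gradients at or above the 0.75 quantile of the field's chamber
gradients, otherwise adapt the plan. The clinical wording ("a few
chambers", "explained by steep dose gradients") gives no numbers; `k` and
the quantile are exposed as configuration.

## Plan rules

`check_atp()` compares an adapted plan against its verified original:
same ion (short-circuits), fraction dose equal to 1e−6 Gy, same field
count, angles within ±10° on the shortest arc (so 355° vs 5° differ by
10°), modifier sets unchanged and positions within ±100 mm, at most 20
energy levels added relative to the original (the one intentionally
asymmetric rule), total particle number within ±20% — with the smaller
total as denominator so the verdict cannot depend on which plan is called
"original" — and "comparable field contributions" formalized as
optimization metadata (layer spacing, spot spacing, grid size) within 10%
relative tolerance, since the clinical wording is qualitative. A
documented gap: the clinical criteria allow individual fields to vary more
in particle number without giving a bound, so no per-field particle check
is made. `integrity_check()` compares the transfer-relevant plan tags
(approval status, label, review timestamp, patient identifiers, field
names, spot count, particle tuples, modifiers, isocenter) exactly;
numeric tuples use zero tolerance because transfer corruption is discrete,
not a rounding phenomenon.

## Cohort statistics

The analysis pipeline excludes human-error-flagged records first, then
aggregates per category: mean and sample SD of the per-field mean
deviations, the global minimum/maximum of the per-field minima/maxima,
pass rates, times and activated-chamber counts. The test battery follows
standard practice for this kind of cohort: one-sample t against zero for
the (symmetric) mean deviations, one-sample Wilcoxon signed-rank for the
strongly asymmetric minima/maxima, Levene's test (centered on the mean) at
α = 0.01 gating pooled versus Welch two-sample t-tests, one-way ANOVA with
Tukey HSD run only on significance, and Pearson correlation for the
position/volume covariates. Shapiro–Wilk normality is computed and
reported alongside the t-test but never blocks it (robustness for large,
symmetric samples); no multiple-testing correction is applied beyond
Tukey, mirroring the reproduced analysis. Significance is α = 0.01
throughout. `threshold_sensitivity()` re-runs activation and
classification at alternative gradient thresholds on retained per-chamber
data and asserts the set-inclusion monotonicity of activation.
`time_accounting()` combines summed beam time with per-step overheads
(defaults 15 min preparation and 10 min analysis per verification, 30 min
setup and 5 min pre-irradiation per session).

## What the synthetic cohort emulates — and what it does not

`generate_parametric_cohort()` draws, per field: category labels from the
configured mixtures (defaults follow the published cohort's room/ion/TPS/
range-shifter/indication/year proportions), a field-mean deviation from
the calibrated normal (default −0.5 ± 0.9 % of D_max), an
activated-chamber count (rounded normal 21 ± 2 clipped to 1–24), and
per-chamber residuals from a two-component normal mixture — a narrow core
(SD 1.0%) plus a rare wide component (weight 0.03, SD 6%) chosen once so
that roughly 0.7% of active-chamber deviations fall beyond ±7%, the
reported tail frequency. Residuals are centered within each field, so the
configured location/scale is *exactly* the distribution of the per-field
mean; this makes calibration closure well-defined and is the design choice
behind the parameter-recovery tests. Times are log-normal (positivity) and
pass flags are always recomputed from `tolerance_config()`.

Consequences to keep in mind when interpreting passing tests: the
published tables constrain only summary moments, so the within-field joint
distribution here is one admissible choice; tail events are drawn
independently per chamber, whereas real steep-gradient failures cluster
within fields, so the generator's field-level failure rate follows from
the chamber-level tail rate rather than being calibrated separately; and
category effects enter only through the single calibration axis. Passing
recovery tests therefore demonstrates that the analysis correctly inverts
this generator — not that real PSQA data look exactly like it.

`generate_mechanistic_cohort()` instead runs the full physics pipeline per
field (SOBP plan, grid, stack placement over the modulation, measurement
simulation, verification) with a default error model of 0.5 mm positioning
scatter, 0.5% reading noise and a −10 mGy background offset — values a
physicist would call routine for a multichannel small-volume chamber
system. It is intended for tens of fields on 2 mm grids.

## Problem sizes and numerical tolerances

The test suite runs parametric cohorts up to the full published size
(23014 fields; sub-second) and mechanistic cohorts of 3–20 fields on 2 mm
grids in a 200 × 120 × 120 mm phantom (about one second per field).
Stochastic recovery checks use 3–4 standard-error tolerances; oracle
comparisons (gradient estimator versus an independent finite-difference
implementation, classification versus exhaustive rule evaluation on
boundary-dense triples) use 1e−9 or exact agreement. Statistical
calibration is checked over 2000 null simulations at α = 0.01 with a
four-binomial-SE band. The SOBP flatness target (central-axis within ±3%
of prescription, mean target dose within 1%) is the package's own
acceptance choice for the synthetic engine.

## Known limitations

- The dose engine is a stand-in, not a commissioned beam model: no nuclear
  fragmentation, no depth-dependent lateral scattering, no ripple-filter
  model, no RBE weighting, no DICOM I/O.
- Chamber volume averaging uses a box approximation of the cylindrical
  sensitive volume with a fixed quadrature; recombination, polarity and
  temperature/pressure chains are out of scope.
- The cohort generator cannot be validated against the underlying
  institutional measurements (not publicly available); its defaults encode
  the published summary statistics only.
- Yearly bookkeeping in the published record contains a small internal
  inconsistency (the per-year field counts do not sum exactly to the
  stated total); the package always reports internally consistent totals
  computed from its own records.
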