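---
title: "Methods: energy dissipation from force spectroscopy and paired bone toughness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: energy dissipation from force spectroscopy and paired bone toughness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteoforce)
```

# Scope

osteoforce implements two connected analyses around the mechanics of
phosphorylated bone-matrix proteins such as osteopontin (OPN):

1. **AFM force spectroscopy arm.** From raw force–distance retraction curves,
   extract per-pull *maximum adhesion force*, *pulling length* and *dissipated
   energy*, aggregate them by experimental condition (substrate, solution, pH,
   protein phosphorylation state), normalize to a reference environment and
   compare conditions statistically.
2. **Bone cohort arm.** From notched-femur three-point-bending records and
   phosphoprotein assay readings, compute a single-valued fracture toughness
   at maximum load, the global matrix phosphorylation level, and the paired
   contralateral-limb deltas that isolate a treatment effect from
   between-animal variation.

A synthetic-data module generates raw curves, calibration inputs and paired
cohorts with known ground truth, so every stage of the pipeline is testable
end to end without instrument data.

# Calibration model

A raw curve stores piezo position $z$ (m) and photodiode deflection $d$ (V).
Two factors convert it to physics:

* **InvOLS** (inverse optical lever sensitivity, m/V). Estimated by pressing
  the cantilever onto a nominally infinitely stiff surface: in contact the tip
  tracks the piezo, so deflection rises linearly in $z$ with slope
  $1/\mathrm{InvOLS}$. We fit an ordinary least-squares line to the loading
  part of each of (by default) ten curves and average the inverted slopes.
  The *loading part* is defined as the contiguous terminal span of the
  approach where the deflection exceeds 10% of its maximum — the flat
  out-of-contact baseline never enters the fit.
* **Spring constant** $k$ (N/m) by the thermal-noise method, in its
  equipartition form: $k = \beta\, k_B T / \mathrm{Var}(d_m)$ where $d_m$ is
  the free-cantilever deflection in metres. We use the plain variance
  estimator rather than a spectral Lorentzian fit because it is the minimal
  estimator consistent with the method's assumption and is exactly testable
  against simulated white-noise series. $\beta$ (default 1) exposes the usual
  first-flexural-mode correction (0.817) without asserting it; the
  temperature default is 298 K, configurable.

Force and tip–sample separation then follow the chain
$F = k \cdot \mathrm{InvOLS} \cdot d$ and
$s = (z_\mathrm{ref} - z) + \mathrm{InvOLS}\cdot d$, with separation
increasing away from the surface. The separation origin is provisional until
contact alignment.

# Per-pull quantities

Each retraction trace is contact-aligned: the contact point is the
zero-crossing of force at the end of the initial repulsive span (the last
zero-crossing before adhesion onset), interpolated linearly between the
bracketing samples, and both axes are shifted so that point is $(0, 0)$.
Traces that never cross (all-repulsive or all-adhesive) are flagged rejected
and carried through the batch as rejection records.

* **Maximum adhesion force** $F_{max}$: magnitude of the most negative force
  at non-negative separation (the Y-minimum of the retraction curve).
* **Pulling length** $L_p$: the separation at which adhesion last drops below
  1% of $F_{max}$ — operationally, the end of the last adhesion excursion
  exceeding the threshold. Read literally, "adhesion smaller than 1% of the
  maximum" holds at every large separation, so only the last-excursion-end
  reading yields a finite, adhesion-bounded region; the package implements
  that reading.
* **Dissipated energy** $E$: trapezoidal integral of $\max(0, -F)$ over
  $s \in [0, L_p]$ on the sampled grid (no resampling). Only adhesive
  (negative-force) spans count, so brief positive noise overshoots inside the
  window contribute zero rather than cancelling real work. $E$ is reported
  positive.

## Noise robustness of the pulling length

With baseline force noise $\sigma$, the 1% threshold can sit inside the noise
band (e.g. $\sigma$ at 5% of a small event peak), and isolated noise spikes
beyond the final rupture would otherwise stretch $L_p$ to the end of the
trace. Two guards keep the detection faithful without changing the measured
quantity:

* an excursion must contain at least `min_run` (default 3) consecutive
  super-threshold samples, and
* its peak must exceed `noise_guard` (default 5) times a robust noise
  estimate, $\widehat\sigma = \mathrm{MAD}(\Delta F)/\sqrt2$.

On noise-free data both guards are inert and the literal threshold rule is
recovered exactly. With noise at 5% of the smallest event peak, the median
pulling-length error stays below one sampling interval and the median energy
error below 1% (the suite asserts 5%).

# Condition aggregation and statistics

Per-condition summaries report $n$, mean energy, SD and SE $= SD/\sqrt n$
over accepted pulls; rejected pulls are excluded but counted. For display,
mean and SE are divided by the mean energy of the substrate's reference
environment (EDTA for mica, water for hydroxyapatite, configurable), so the
reference's normalized mean is exactly 1. Normalization happens at the level
of condition means, not per pull: the two choices agree for the mean but not
for the SE, and the means-level reading matches how normalized bar plots with
SE bars are usually constructed. Hypothesis tests always run on **raw**
energies — dividing both groups by one positive constant leaves the t-test
unchanged, so normalization is pure display scaling.

Condition comparisons use a two-sided unpaired Student's t-test (pooled
variance, matching the "Student" naming; a config switch enables the Welch
form) at threshold 0.05, preceded by a one-sample Kolmogorov–Smirnov
normality check against a normal with the sample's own mean and SD. Because
those parameters are estimated from the same data, the asymptotic KS p-value
is conservative; the report carries that caveat and flags — never gates —
non-normal groups. No multiple-testing correction is applied across the
condition grid. Degenerate (zero-variance) inputs yield flagged reports,
never silent NaN: small bone cohorts make this reachable.

# Fracture toughness and phosphorylation

A notched femur in three-point bending yields a single-valued toughness at
maximum load:

$$K_c = Y(\theta, R_m/t)\;\sigma_{max}\;\sqrt{\pi a},\qquad
\sigma_{max} = \frac{P_{max}\,L}{4}\cdot\frac{c}{I},\quad
I = \frac{\pi}{4}(R_o^4 - R_i^4),\quad a = \theta\,R_m,$$

with $\theta$ the half crack angle (degrees in the tables, radians
internally), $R_m = (R_o+R_i)/2$ the mid-wall radius, $t = R_o - R_i$ the
cortical thickness, and crack length $a$ measured along the mid-wall arc.
Whether the outer fibre distance $c$ is $R_o$ (default) or $R_m$ is exposed
in configuration, since published maximum-load formulations differ on this
point. The geometry factor $Y$ is bilinearly interpolated from an editable,
versioned CSV; the shipped default
(`inst/extdata/geometry_factor_synthetic.csv`) is a **synthetic** smooth
surface constructed for this package — laboratories should install their own
calibrated tabulation, and everything around the table (validation, stress
decomposition, tests) is agnostic to which one is installed.

Specimen validity rules are applied once, on the pre-analysis cohort, not
iteratively: reject if $\theta \notin [0°, 110°]$ (the accurate testing
range), if $|\theta - \bar\theta| > 2\,\mathrm{SD}$ over the cohort, if the
notch extends past 1/3 of the cortex, or if it is flagged off-centre.

Global phosphorylation is the mean replicate absorbance per nanogram of
protein (assays in triplicate; the replicate CV is reported and flagged when
undefined). The paired construction takes, per animal, treated minus
contralateral-control (delta); within each genotype a paired t-test compares
the arms, and between genotypes the deltas are compared by an
independent-samples t-test, all two-tailed at 0.05.

# The synthetic-data generator

The generator emulates the acquisition protocol: the probe parks 3 µm from
the surface, approaches at 2.0 µm/s to a 15 nN repulsive contact threshold,
dwells 10 s, and retracts at 5.0 µm/s. Rupture events rise from the previous
rupture position to their contour length and drop to baseline
instantaneously; the rising limb is either triangular (analytic area
$P\cdot b/2$) or a worm-like-chain-style concave limb with closed-form area.
The shape switch exists because only the enclosed area matters downstream,
and analytic areas make exact tests possible. Contour lengths are snapped to
the sampling grid so the rupture drop coincides with a sampled point; the
stored ground truth (energy, max force, last-rupture position) refers to the
snapped scenario. Gaussian baseline force noise is added after the noise-free
profile is built; raw signals are then encoded through the calibration
(deflection $= F/(k\cdot\mathrm{InvOLS})$, piezo position consistent with the
intended separation), so the calibrate–analyze chain can be checked round
trip to machine precision at zero noise.

Thermal series are white Gaussian noise at the equipartition variance
$k_BT/k$ — the simplest series honouring the estimator's assumption; real
cantilever spectra are coloured by hydrodynamic damping, which the
equipartition estimator integrates out anyway. Stiff-surface curves are
piecewise-linear deflection ramps plus voltage noise.

Paired cohorts draw, per animal, an underlying value (group mean plus
animal-level Gaussian intercept); the control limb adds a limb-level
residual, the treated limb multiplies the underlying value by $(1 +
\mathrm{effect})$ before adding its residual, and the treated limb (left or
right) is randomized per animal. Defaults mirror the study arms: 7 pairs per
genotype; toughness scale 4.0 MPa·m^0.5 with between-animal SD 0.5 and limb
SD 0.15 (values in the range reported for mouse femora, with pairing noise
well below animal-to-animal spread, which is the point of the contralateral
design); effect +18% for the phosphorylation scenario and −25% for the
dephosphorylation scenario; phosphorylation level 5×10⁻⁴ AU/ng with
proportional spreads and a 5% replicate CV. Where the underlying study
reports no magnitude (noise levels, sampling rates, assay scale), the
defaults are package choices surfaced in `run_config()` and here.

**What passing tests do and do not show.** The generator produces idealized
events (instant ruptures, white noise, no drift, no hydrodynamic colouring,
no tilt or adhesion on approach). Recovery within tolerance on synthetic data
demonstrates the *pipeline's* correctness — its integration, thresholds and
statistics — not that any real film behaves like the model; conclusions about
real samples still require real curves.

# Numerical choices and degenerate inputs

* Integration is trapezoidal on the sampled grid; with rupture drops snapped
  to samples the triangle areas are exact, and on densely sampled curves
  (0.1 nm grid in the acceptance checks) the remaining discretization error
  sits well inside the 0.1% oracle-equivalence band.
* Contact interpolation is linear between the bracketing samples; with noise
  the onset blurs by roughly noise/contact-stiffness, a fraction of a sample
  at realistic stiffness.
* Zero maximum force short-circuits pulling length and energy to 0; an
  all-repulsive or all-adhesive trace becomes a rejection record with a
  reason, as does an unsplittable (monotone-piezo) cycle.
* Test problem sizes (100 oracle curves, 10⁶-point Riemann sums, 2000-rep
  null calibrations, 500-cohort sign recovery) were chosen as the smallest
  sizes at which the Monte-Carlo bands are meaningful.
* Energies are joules internally; attojoules (10⁻¹⁸ J) are a convenient
  display unit at this scale.

# Known limitations

* No worm-like-chain fitting of individual ruptures, unfolding-event
  counting, or loading-rate analysis: the pipeline extracts exactly the three
  per-pull quantities above.
* The KS check with estimated parameters is conservative (no Lilliefors
  correction), deliberately.
* The shipped geometry-factor table is synthetic (see above); absolute $K_c$
  values from it are internally consistent but not comparable to published
  bone toughness numbers until a calibrated table is installed.
* Instrument-vendor binary formats are out of scope; curves arrive as ASCII
  with a declared dialect.
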