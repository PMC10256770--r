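---
title: "Models and methods behind nanowarm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nanowarm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanowarm)
```

# Scope

Organ cryobanking by vitrification requires cooling a CPA-equilibrated organ
faster than the CPA's critical cooling rate (CCR) into a glass, and — the
harder problem — rewarming it faster than the critical warming rate (CWR).
Nanowarming does the rewarming volumetrically, by exciting iron-oxide
nanoparticles (IONPs) in the organ vasculature with an RF field. `nanowarm`
implements the quantitative pipeline around that workflow for the rat
kidney: CPA perfusion protocol construction and evaluation, Krogh-cylinder
mass-transport simulation, thermal-history and DSC analysis, micro-CT
radiodensity classification, normothermic machine perfusion (NMP) metrics
with gated group statistics, and 30-day post-transplant outcome summaries.
A deterministic synthetic-data generator stands in for instrument data so
the whole pipeline is testable end to end.

Numbered driver scripts under `analysis/` walk through the stages and write
their tables to `results/`; every computation they narrate lives in the
package and is unit-tested.

# Perfusion protocols

A protocol is an ordered list of segments (`flush`, `ramp`, `hold`, `step`,
`ionp`) over the CPA concentration timeline, annotated with pressure and
temperature setpoints. Concentrations are stored in mM (so "5 M" is
5000 mM). Ramp durations are derived from endpoints and rate, which is what
makes the published totals checkable arithmetic: the VMP loading schedule
(20-min flush; 0 to 5000 mM at 50 mM/min; 10-min hold; 25-min step at
8400 mM) sums to 155 min, and the unloading schedule (15-min hold at
4200 mM with 300 mM mannitol; ramp to 0 at -35 mM/min with mannitol at
-2.5 mM/min; 30-min flush) to 165 min.

Design choices:

* `step` segments are right-continuous — the stepped value holds on
  `[start, end)` — matching the "stepped up to full strength" semantics.
* Adjunct co-solutes (mannitol) are parallel piecewise functions sharing the
  CPA timeline; their ramp rates must be consistent with the segment
  duration derived from the CPA rate.
* The IONP co-perfusion (10 mg Fe/mL in VMP, 0.5 mL/min) is an explicit
  segment kind with a default duration of 4.5 min — the midpoint of the
  reported 4–5 min window, which is also the duration stated with the
  loading results — and is excluded from the 155-min loading total because
  it overlaps the final minutes of the full-strength step. IONPs are
  treated as non-permeating and never enter the transport model.
* The nanoparticle flow QC rule is strict: unloading flow must exceed 45%
  of loading flow; a ratio of exactly 0.45 fails.

# Krogh-cylinder transport model

The kidney is modelled as many identical parallel units — a capillary of
radius 3.5 µm in a tissue annulus of radius 20 µm, 1 mm long, split into 10
axial segments, with 2×10⁶ units per kidney. These dimensions are a
documented assumption (vascular-anatomy textbook magnitudes), not a
measured geometry, and every one is overridable; per-gram conclusions
should not lean on them. Vascular segments advect the inlet concentration
as stirred tanks in series (a plug-flow discretization); each axial segment
exchanges water and CPA with a single well-mixed extravascular compartment.
No radial diffusion PDE is attempted: exchange is membrane-limited by
assumption.

Membrane fluxes follow Kedem–Katchalsky irreversible thermodynamics with
van't Hoff osmotic pressure (ideal, osmotic coefficient 1; no activity
model is warranted by the available coefficients):

$$J_v = L_p\left(\Delta p - \sigma R T (c_v - c_e) - R T (c_{iv} - c_{ie})\right),
\qquad
J_s = \omega R T (c_v - c_e) + (1-\sigma)\,\bar c\, J_v$$

with $L_p = 1.5\times10^{-14}$ m³/(N s), $\omega = 7.0\times10^{-13}$
mol/(N s), $\sigma = 0.1$ (VMP in rat kidney at 4 °C). Concentrations in mM
are used directly as mol/m³ (the units are identical). Both coefficients
are treated as per-unit-membrane-area; because the literature does not
always state that normalization, `membrane_params(area_scale=)` exposes a
total-area multiplier. Impermeant osmolytes (≈300 mM on both sides
initially) are conserved in moles, so osmotic shrinkage concentrates them —
the restoring force that arrests shrinkage.

**The convective mean concentration.** The textbook form of $\bar c$ is the
arithmetic membrane mean. At the gradients CPA loading creates (5000 mM
against a CPA-free tissue), the arithmetic-mean drag term is several times
the permeative term, and because it keeps "dragging" solute out of a
compartment that contains none, it drives the tissue concentration strongly
negative — a known artifact of the linearized form far from equilibrium.
`simulate_perfusion()` therefore defaults to a donor-side (upwind) mean:
$\bar c$ is the concentration on the side the volume flux leaves. This
preserves positivity and agrees with the arithmetic and log-mean forms in
the small-gradient limit; both remain selectable, and the standalone
`kk_fluxes()` calculator keeps the textbook arithmetic default.

**Numerics.** The ODE system (per-segment vascular concentration, relative
extravascular volume, extravascular concentration, cumulative inlet/outlet
solute) is nondimensionalized to O(1) scales and integrated with
`deSolve::lsoda` (adaptive, stiff-capable; rtol = atol = 10⁻⁸), restarted
at every protocol segment boundary so concentration steps are exact solver
restarts. Carrying the cumulative boundary fluxes as solver states makes
the solute balance checkable to solver accuracy: the suite requires a
relative residual below 10⁻⁶ on 100 random protocols and typically observes
10⁻¹⁰. The hydrostatic term uses the protocol pressure setpoint on the
vascular side and 0 in the tissue; temperature is the segment setpoint (no
Arrhenius scaling — only single-temperature coefficients are available).

Verification anchors: a brute-force explicit-Euler integrator at 100× finer
steps agrees within 0.5% sup-norm; the σ=1, ω=0 limit settles on the
Boyle–van't Hoff volume $V/V_0 = c_{i0}/(c_{in}+c_{iv})$ within 0.1%; the
permeation-only compartment reproduces its analytic time constant
$\tau = V_0/(A\,\omega R T)$ within 2%.

# Thermal histories, the freezer program, and DSC

Temperature logs are 1-s-cadence probe records. `fit_rate()` reports the
mean rate between the first crossings (linearly interpolated) of a
temperature window — defaulting to the ice-risk zone bounded by
$T_m = -40.8$ °C and $T_g = -128.3$ °C — plus instantaneous rates from
central differences after a 5-sample moving average. Rate checks against
CCR (2 °C/min) and CWR (50 °C/min) are strict inequalities on the
magnitude; the "~" in a reported "~50 °C/min" is ignored (point value,
configurable). Note the cooling protocol deliberately anneals 25 min at
-122 °C *inside* that window; the shipped cooling scenario therefore fits
the active ramp above the anneal, since a window mean across a designed
hold measures the hold, not the ramp.

The controlled-rate-freezer program (0 → -122 °C at -40 °C/min; 25-min
anneal; -122 → -150 °C at -5 °C/min; 10-min hold) is represented as a
piecewise-linear setpoint trajectory spanning 43.65 min.

`ice_fraction()` baseline-corrects a DSC thermogram with a linear fit
through the outer 15% flanks of the scan (which makes the result exactly
invariant to constant or linear instrumental baselines), integrates the
event over temperature by the trapezoid rule, divides by the scan rate to
get J/g, and reports a percentage of the reference latent heat (334 J/g,
pure-water value, configurable — the upstream DSC references do not restate
theirs). `critical_rate()` interpolates log₁₀(ice fraction) linearly
against rate and returns the rate at the threshold ice fraction, default
0.5% (the conventional "appreciable ice" cutoff; recorded with every
result), flagging extrapolation beyond the measured range.

# Micro-CT

Raw volumes are calibrated against water and air reference tubes scanned
with the sample: the affine map sends the water ROI mean to exactly 0 HU
and the air ROI mean to exactly -1000 HU, which makes the calibration
invariant to any affine rescaling of raw intensities. Region statistics use
the population SD. State classification is a radiodensity threshold —
region mean at or above the threshold is called vitrified, below it frozen
— with the default of 400 HU sitting between the reported vitrified-kidney
(507 HU) and icy-fat (267 HU) radiodensities. That number is this
artifact's explicit heuristic, not a published decision rule, and it must
be shifted upward for IONP-loaded scans, whose absolute radiodensity the
iron oxide raises (the shipped IONP scenario uses 520 HU). The
discontinuity screen formalizes the visual check for cracks/ice as a
conservative heuristic: connected components of anomalously low-HU voxels
(default: 4 robust SDs below the volume median), scored by bounding-box
extent and elongation, reported only above a minimum physical extent.
Voxel grids are (z, y, x) with voxel-center coordinates.

# NMP metrics and gated statistics

Vascular resistance is mass-normalized as pressure over flow-per-gram,
mmHg/(mL/min/g) — i.e. numerically pressure×mass/flow — matching the
published unit string "mmHg/mL/min × g", which is stated here prominently
because that string parses ambiguously. Substrate fluxes use
(arterial − venous) × flow / mass (mmol/L × mL/min ≡ µmol/min); lactate
production flips the sign. Creatinine clearance is the classic UV/P per
organ. Oxygen consumption uses dissolved oxygen only — the perfusate is an
acellular Krebs–Henseleit buffer — with a default solubility of
1.4 µmol/(L·mmHg) at 37 °C, configurable because the source constant is in
an external reference.

`group_compare()` implements the gated decision tree: Shapiro–Wilk per
group; if consistent with normality, Levene (Brown–Forsythe) gates Tukey
HSD (equal variances) versus Games–Howell (unequal; hand-implemented Welch
t against the studentized-range distribution, since no installed package
provides it); otherwise Kruskal–Wallis with Holm-adjusted pairwise Wilcoxon
(Holm chosen because the source names adjustment but not a method). Two
points the suite documents honestly rather than hides: at n = 4/group,
Levene detects even a 36× SD ratio only ~84% of the time, and a
Games–Howell pair with Welch df ≈ 3 essentially cannot produce p < 0.001,
so the reported highly significant VS55 separation at n = 4 is not
reproducible by this gate at that n (the suite verifies it at n = 20,
where power is ~1).

# Transplant outcomes

Daily labs (day -1 baseline through day 30) are summarized per animal by
the creatinine landmarks: peak and its day, time to normalization — the
first day at or after the peak strictly below 2.0 mg/dL, no interpolation —
and terminal value. Counting from the peak matters: baselines are already
below threshold, and the clinically meaningful landmark is recovery after
dysfunction. Weight is normalized to day -1. Group comparisons use the
per-variable test mapping (t-test for potassium and hemoglobin, Wilcoxon
otherwise), available-case, no imputation. Storage-duration correlations
use Kendall tau with the exact null for n ≤ 10 without ties; constant
inputs are flagged undefined. eGFR is a pluggable callable (the source
formula lives in an external reference); UV/P clearance is the conventional
default.

# The synthetic-data generator

Every generator is a pure function of (parameters, seed): it draws through
a private RNG stream, restores the caller's RNG state, and reproduces
byte-identical output for a seed. What each emulates, and what it does not:

* **Temperature logs** — linear segments plus Gaussian probe noise
  (default SD 0.5 °C) at 1-s cadence, with an optional annealing plateau.
  No convective lag, no thermal gradients across the organ.
* **Thermograms** — Gaussian exo/endotherm whose integrated area equals the
  target ice fraction of the reference latent heat, on a (possibly sloped)
  baseline. No instrument transfer function.
* **CT phantoms** — per-region Gaussian HU in disjoint boxes (the
  nanoparticle-free scenario uses 507 ± 30 HU kidney and 267 ± 104 HU fat;
  the IONP scenario 768/628/656/560 HU), affinely mapped to a raw scanner
  scale, with water/air reference tubes (SD 1 HU — pure reference
  materials, kept small so calibration uncertainty stays well below the
  region-mean standard error) so calibration is exercised end to end. No
  anatomy, no beam hardening, no projections.
* **NMP traces** — minute-40 endpoint metrics drawn from group
  Normal(mean, SD) distributions and smoothly interpolated backwards, with
  pressure held in the physiologic 90–110 mmHg window; the series are
  constructed by inverting the metric formulas so the analysis recovers
  each kidney's drawn endpoints exactly. Only the vascular-resistance
  endpoints are published numbers; the other group parameters are
  synthetic plausible values chosen once to reproduce the qualitative
  group ordering. This is endpoint-level emulation, not an organ model.
* **Transplant cohorts** — control recipients stay near-normal (level
  0.48 ± 0.15 mg/dL across animals, anchored to the day-30 table);
  nanowarmed recipients rise to a peak (4.0 ± 0.5 mg/dL) on day 2–3,
  decline along a two-phase shape — a log-linear shoulder to the 2.0 mg/dL
  crossing (day 16–20 per animal), then a fast exponential to a terminal
  0.62 ± 0.15 mg/dL clipped to 0.4–0.8 — with correlated potassium/pH/
  HCO₃/pCO₂ excursions resolving by day 15, a transient ~10% weight excess
  resolving by day 12, and a surgical hemoglobin dip in both groups. The
  two-phase shape is an artifact choice: a single exponential cannot both
  cross 2.0 around day 19 and be normal by day 23. A single-exponential
  tail is visually similar but quantitatively incompatible with those two
  landmarks simultaneously.

Passing tests on these generators show the *pipeline* recovers the
distributions and landmarks it is fed; they cannot show that real kidneys
behave this way. In particular the generators have no within-animal
autocorrelation beyond their smooth shapes, no missingness, and no
measurement-device quirks.

# Problem sizes and runtime

The test-suite and reproduction-script sizes are chosen to keep everything
desk-scale on one CPU: CT phantoms of 64³ voxels with a 10⁵-voxel kidney
region; 200 simulated kidneys for the NMP endpoint recovery; 100 random
protocols (2–5 segments, minutes-scale durations) for the conservation
sweep; 500 replicates for the noisy rate-estimator check; 40 replicate
cohorts for the outcome-ordering properties. The full suite runs in well
under a minute; the reproduction script in seconds.

# Known limitations

* The Krogh geometry is assumed, not fitted; absolute tissue
  concentrations scale with it. Loading-optimization conclusions are
  relative comparisons between protocols under identical geometry.
* The transport model has no CPA toxicity cost, no viscosity-coupled flow
  (measured flow is an input), and no radial concentration profile.
* No heat-transfer or electromagnetic (RF/SAR) modelling: thermal analysis
  consumes measured or generated logs.
* The vitrified/frozen HU threshold is a heuristic; with IONPs present it
  must be re-derived per loading.
* The statistical gate reproduces the published decision tree, not the
  published p-values at n = 4 (see above).
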