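---
title: "Models, calibration and design of the metaboscope pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, calibration and design of the metaboscope pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboscope)
```

## What the package computes

`metaboscope` implements the quantification chain of a two-arm metabolic
intervention study (obesity surgery versus a low-calorie diet) in which
insulin-stimulated glucose metabolism is measured by simultaneous
whole-body ¹⁸F-FDG-PET/MRI during a hyperinsulinaemic–euglycaemic clamp,
alongside an OGTT and fasting biochemistry. Because no individual-level
data from such trials are publicly deposited, the package pairs the
analysis chain with a synthetic cohort generator whose defaults encode the
published group-level summaries, so that every stage can be tested against
known ground truth.

## FDG kinetics and Patlak analysis

Tissue FDG kinetics follow the irreversible two-tissue compartment model
with rate constants `K1` (plasma → free tissue pool, ml·ml⁻¹·min⁻¹), `k2`
(efflux, min⁻¹), `k3` (irreversible phosphorylation, min⁻¹) and fractional
blood volume `Vb`:

$$C_T(t) = \frac{K_1}{k_2+k_3}\left[k_3 + k_2 e^{-(k_2+k_3)t}\right]
\otimes C_p(t) + V_b\,C_b(t).$$

`simulate_2tcm()` evaluates the convolution by trapezoidal quadrature on a
fine internal grid (default `dt = 0.05` min), with the exponentially
weighted integral accumulated in decayed form so it never overflows. The
solver agrees with an independent stiff ODE integration to about 10⁻⁵
relative at the default step (tested against `deSolve`).

`patlak_fit()` estimates the net influx rate as the OLS slope of
`C_T(t)/C_p(t)` against the normalised time `∫₀ᵗC_p\,dτ / C_p(t)` for
`t ≥ t*`. For the irreversible model the slope converges to
`Ki = K1·k3/(k2+k3)` from below as `t*` grows; at the package's standard
test kinetics (`K1 = 0.1, k2 = 0.15, k3 = 0.05`, `Ki = 0.025`/min) the
bias is ~0.5% at `t* = 20` min and shrinks monotonically. The default
`t* = 10` min is the end of the dynamic scan: every whole-body pass is
later, so all pass samples enter the fit. The `Vb` term contaminates the
Patlak intercept, not the slope, and is therefore not corrected further;
this is also how the "blood FDG adjustment" of the real protocol is
represented. All simulated activities are decay-corrected to injection
time, so no ¹⁸F half-life appears anywhere in the fitting.

Voxelwise maps (`make_ki_image()`) use exactly the same OLS as ROI fits,
vectorised over voxels, with no spatial regularisation; voxels whose
time-averaged activity falls below 1% of the robust maximum are background
and masked to `NA`.

The plasma input function is an analytic Feng-type curve (linear rise times
a fast exponential plus two slow exponentials), scaled to the injected dose
of 4 MBq per kg body weight. An analytic form was chosen because the
acquisition's own image-derived input function is not described in enough
detail to reproduce; Patlak estimates are invariant to the overall input
scale, which the tests assert explicitly.

### Lumped constants

`MRglu = Ki·[glucose]/LC`, reported per 100 ml of tissue. The published
tables print no lumped constants, so the defaults are the literature values
conventionally used with this methodology — brain 0.81, skeletal muscle
1.16, myocardium 1.00, adipose 1.14, liver 1.00 — and are plain
configuration (`default_lumped_constants()`). Published MRglu cells
therefore act as calibration targets for the generator, not as validation
of the LC choice.

## Clamp quantification

Insulin is infused at 56 mU per m² body surface per minute (Du Bois BSA by
default; Mosteller available) and glucose is clamped at 5.6 mmol/l with
insulin near 700 pmol/l. The M value is the time-weighted (trapezoidal)
mean glucose infusion rate over the 60–120 min steady-state window divided
by lean body mass, making it robust to irregular sampling. Steady state is
accepted when the in-window glucose CV is at most 5% (`cv_tol`); the
protocol itself asserts steady state without a criterion, so the gate is a
package choice and configurable. Molar conversion uses the molar mass of
glucose (1 mg = 5.5506 µmol), which reconciles the M value scale
(mg·kg⁻¹·min⁻¹) with the turnover scale (µmol·kg⁻¹·min⁻¹): 8.65
mg·kg⁻¹·min⁻¹ ≡ 48.0 µmol·kg⁻¹·min⁻¹. No glucose-space drift correction is
applied (the source protocol mentions none); the steady-state window mean
is used as-is. Lean body mass is the bioimpedance value carried on the
participant record, not the MRI non-adipose volume.

## Whole-body turnover

Whole-body glucose disposal is tissue-integrated:
`Rd = Σ_t MRglu_t · V_t / LBM`, with the glucose equivalent of urinary
tracer loss subtracted from apparent uptake (strategy `subtract`, or
`ignore`). Urinary loss is modelled as renal clearance of FDG — bladder
activity accrual rate over plasma activity — times the plasma glucose
concentration. Endogenous glucose production is then the steady-state
balance `EGP = Rd − GIR`; the identity `Rd − GIR − EGP = 0` is the
pipeline's conservation law and holds exactly through all unit
conversions. Negative EGP is physiologically meaningful under
hyperinsulinaemia and reported as-is with a warning, never clipped.

## Body composition

Fat fraction is `FF = F/(W+F)` per voxel; voxels with total signal below
5% of the robust maximum are background. Adipose tissue is the body voxels
with `FF ≥ 0.5` — a transparent threshold standing in for the unpublished
vendor segmentation — so adipose and non-adipose volumes partition the
whole-body volume exactly, mirroring the additivity of the published volume
table. Liver and pancreas fat are ROI means of the fat-fraction map; in
the synthetic pipeline the ROIs come from the phantom's ground-truth labels
(standing in for manual delineation). Voxelised ellipsoid volumes recover
analytic volumes within 2% at 4 mm voxels and converge as the grid is
refined (tested at 8/4/2 mm).

## Glucose homeostasis indices

* **HOMA-IR** `= G[mmol/l] · I[µU/ml] / 22.5` with insulin converted from
  pmol/l by 6.945. This is the unique standard variant that reproduces all
  four published HOMA-IR cells from the published glucose and insulin
  cells, which is why it is pinned.
* **Matsuda** `= 10000 / sqrt(G0·I0·Ḡ·Ī)` with glucose in mg/dl
  (×18.016), insulin in µU/ml, and time-weighted OGTT means. The exact
  variant used by any given study cannot be pinned from printed values;
  this composite-mean convention is documented as a package choice.
* **Insulinogenic index** `= (I30 − I0)/(G30 − G0)` in mU/l per mmol/l,
  insulin converted by the same 6.945 factor for internal consistency.
  The 30-min sample this requires is the reason the OGTT grid includes it.
* **Disposition index** is the product of the two. Note that published
  *group-level* disposition values need not equal the product of the
  group-level insulinogenic and Matsuda values (means of products are not
  products of means); the package computes all three per subject, where
  the identity is exact.
* **HbA1c** converts IFCC → NGSP by the master equation
  `% = 0.09148·mmol/mol + 2.152`.
* **Glycaemia classes** use the ADA cut-offs: impaired fasting glucose at
  5.6 mmol/l (configurable to the WHO 6.1) or impaired glucose tolerance
  at 7.8 mmol/l; diabetes-range values are rejected because the study
  population excludes diabetes.

## Trial statistics

Each variable is gated per arm by a Shapiro–Wilk test at α = 0.05 on
baseline values (the gating granularity is a package choice); non-normal
variables are log-transformed and summarised as geometric means with 95%
t-intervals, back-transformed. Within-arm changes use paired t tests (on
the gated scale, with log-scale effects reported as percent change with
asymmetric CIs); between-arm comparisons of change use ANCOVA adjusted for
the outcome's baseline. Baseline group differences use plain Student's
t test (Welch off by default, configurable). Prediabetes reversion is
compared with a two-sided Fisher's exact test (point-probability rule).
All tests are two-sided at α = 0.05 and no multiple-testing correction is
applied anywhere. A constant baseline degrades the ANCOVA to the
unadjusted comparison with a warning rather than failing.

## The synthetic cohort generator

The generator defines the study conditions; its defaults are not tuning
knobs. It emulates:

* a surgery arm of 15 and a diet arm of 9 (sex ratios 1:14 and 1:8 M:F),
  with baseline anthropometrics and biochemistry drawn from the published
  per-arm summaries — variables published as geometric means with CIs are
  sampled log-normally (the log-SD recovered from the CI width and n via
  `gm_ci_to_sdlog()`), variables published as mean ± SD are sampled
  normally, truncated at physiological bounds; height is derived from
  sampled weight and BMI so the BMI identity is exact;
* intervention effects keyed to the published pre→post shifts: −7.7% /
  −7.4% body weight, −30.8% / −28.1% fasting insulin, +25% leg-muscle and
  −57% cardiac Ki after surgery, smaller diet-arm shifts, each applied
  multiplicatively with per-subject log-normal effect noise;
* clamp traces reaching 5.6 mmol/l glucose and 700 pmol/l insulin exactly
  at the 40-min equilibration point (quadratic ramp), with multiplicative
  measurement noise (default CVs: glucose 3%, insulin 5%, GIR 3%);
* OGTT curves on the conventional 0/30/60/90/120-min grid (the 30-min
  point is required by the insulinogenic index). Glucose follows a
  gamma-variate excursion anchored to the subject's 2-h glucose; after
  surgery the curve is re-anchored so the trapezoid AUC rises by exactly
  the configured fraction (default 20%) with an earlier, higher peak.
  Insulin follows a delayed excursion (peak ~90 min, shape power 6) whose
  amplitude (10.5 × fasting insulin) was calibrated once so the Matsuda
  index at the surgery-arm baseline point values equals 3.2; with that
  calibration the insulinogenic index comes out ≈1.8, inside the published
  mean ± SD band (1.5 ± 0.7) though not at its centre — the published
  index variants are not fully identifiable, and Matsuda was prioritised;
* organ FDG kinetics back-derived from the published per-arm MRglu values:
  `Ki = MRglu·LC/(100·5.6)`, with fixed per-organ shape parameters
  (`k2`, `k3`, `Vb`) and `K1` solved from Ki; between-subject CVs taken
  from the published SDs;
* a body phantom of ellipsoidal parts (head, torso, legs; brain, heart,
  liver, pancreas, bladder, leg muscles, an abdominal adipose depot, a
  residual lean core sized by bisection) whose whole-body volume is
  0.934 l/kg of body weight and whose adipose fraction follows the
  subject's bioimpedance fat% (×1.325 mass→volume), giving ~103 l body
  and ~67 l adipose volume at the surgery-arm baseline; adipose voxels
  have fat fraction 0.90, liver and pancreas carry the subject's sampled
  fat percentages;
* urinary FDG as first-order clearance into the bladder (3% of dose with a
  120-min time constant — the source protocol says only that urinary FDG
  was adjusted for, not how it accrues), worth ~5% of whole-body uptake in
  glucose equivalents.

Two latent truths close the energy balance: each subject's M value
(insulin sensitivity) and clamp EGP are sampled log-normally from the
published summaries, and the residual lean compartment's uptake is then
solved so that tissue-integrated disposal equals `GIR + EGP` plus urinary
loss. If that solution would fall below 0.2 µmol·(100 ml)⁻¹·min⁻¹ it is
floored there and the EGP truth absorbs the shortfall, keeping the
conservation law exact. Every generated dataset ships this ground truth
(per-organ Ki and MRglu, volumes, Rd/EGP, urinary loss) for recovery tests.

What the generator does **not** emulate: PET raw-data and reconstruction
physics (noise is multiplicative and independent per frame, with no
attenuation, scatter or partial-volume structure), MR physics, realistic
anatomy beyond disjoint ellipsoids, incretin physiology and
dumping-symptom dynamics, and any within-subject correlation between
measurement modalities beyond the shared latent truth. Passing tests
therefore demonstrate correctness of the quantification chain under the
stated statistical structure, not robustness to real-world imaging
artefacts.

## Numerical choices and degenerate inputs

* Convolution step `dt = 0.05` min; Patlak integrals on the same grid.
* Trapezoidal integration everywhere a sampled curve is integrated; window
  means interpolate the window bounds so they are resampling-invariant.
* Table-style rounding is half-away-from-zero (`round_half_up()`), matching
  printed-precision reproduction.
* Paired differences whose spread is at float-noise level (zero-noise
  fixtures) short-circuit to `p = 1`/`p = 0` rather than calling a t test
  on essentially constant data.
* `G30 = G0` makes the insulinogenic index undefined: flagged `NA` with a
  warning (0/0) rather than a value.
* Background voxels (zero water+fat or zero activity) are `NA`-masked, not
  treated as zero; empty ROI masks raise errors for means and are flagged
  missing in uptake tables.
* Seeds: every generator stream derives a 31-bit stream seed from the
  cohort seed and the subject/stage labels, so outputs are reproducible
  per subject and independent of evaluation order, and the caller's RNG
  state is left untouched.

## Problem sizes used in the shipped checks

The packaged tests run the full chain at the study's own arm sizes
(15 + 9), use 500 replicate scalar trials for ANCOVA interval coverage,
n = 500 single-arm cohorts for sampling-convergence checks, and 8–10 mm
phantom grids for routine image tests (4 mm where the 2% ellipsoid
recovery guarantee is asserted); these sizes were chosen so the whole
suite exercises every claim in well under half an hour on one core.

## Known limitations

* Lumped constants, the Matsuda/insulinogenic variants and the urinary
  accrual model are documented conventions, not reproductions of
  unpublished implementation detail.
* Rd is computed from the tissue-integrated route only; no independent
  tracer-disappearance estimate is provided, so `Rd = GIR + EGP` is
  enforced rather than testable on real data.
* The phantom's "abdominal adipose tissue" is a single ellipsoidal depot;
  no visceral/subcutaneous subdivision is attempted.
* Voxelwise Patlak assumes a single shared input function and aligned,
  motion-free frames.
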