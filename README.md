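# metaboscope

Quantification of whole-body and tissue-specific glucose metabolism for
two-arm weight-loss intervention studies that combine a
hyperinsulinaemic–euglycaemic clamp with simultaneous whole-body
¹⁸F-FDG-PET/MRI, an OGTT and fasting biochemistry — together with a
synthetic cohort generator so the complete analysis chain can be exercised,
tested and calibrated without any real imaging or clinical data.

It is aimed at researchers in metabolic imaging and clinical glucose
physiology who need a transparent, reproducible implementation of the
standard quantification chain:

* **FDG kinetics** — forward simulation of the irreversible two-tissue
  compartment model
  `C_T(t) = K1/(k2+k3) · [k3 + k2·e^(−(k2+k3)t)] ⊗ C_p(t) + Vb·C_b(t)`,
  and Patlak graphical analysis: regressing `C_T(t)/C_p(t)` on
  `∫₀ᵗ C_p dτ / C_p(t)` for `t ≥ t*` gives the net influx rate
  `Ki = K1·k3/(k2+k3)` as the slope, at ROI or voxel level.
* **Tissue glucose metabolic rate** — `MRglu = Ki·[glucose]/LC`, scaled to
  µmol·(100 ml tissue)⁻¹·min⁻¹ via tissue lumped constants.
* **Clamp quantification** — insulin infusion at 56 mU·m⁻²·min⁻¹ (Du Bois
  body surface), steady-state window 60–120 min, M value = mean glucose
  infusion rate per kg lean body mass, and the whole-body balance
  `Rd = GIR + EGP` with urinary tracer-loss correction.
* **Body composition** — Dixon fat-fraction maps `FF = F/(W+F)`,
  threshold segmentation into adipose / non-adipose volumes, and ROI liver
  and pancreas fat percentages.
* **Glucose homeostasis indices** — HOMA-IR (`G·I/22.5`, insulin
  pmol/l → µU/ml by 6.945), Matsuda, insulinogenic and disposition indices,
  HbA1c IFCC→NGSP conversion, and ADA glycaemia classification.
* **Trial statistics** — Shapiro–Wilk normality gating with log-transform
  and geometric-mean back-transform, paired within-arm tests,
  baseline-adjusted ANCOVA between arms, and Fisher's exact test on
  prediabetes reversion.

## Worked example

```r
library(metaboscope)

# a two-arm synthetic trial (15 surgery, 9 low-calorie diet)
cfg <- cohort_config(n_surgery = 15, n_lcd = 9, seed = 2)
res <- analyze_trial(simulate_trial(cfg), seed = 2)

subset(res$comparisons,
       variable %in% c("mrglu_leg_muscle", "mrglu_heart") & arm == "surgery",
       select = c(variable, arm, scale, effect, p_value))
#>            variable     arm scale    effect      p_value
#> 28 mrglu_leg_muscle surgery   log  16.12701 5.262021e-03
#> 31      mrglu_heart surgery   log -56.96709 1.971952e-10

# fasting indices from first principles
homa_ir(5.6, 67.9)        # 2.433341  -> 2.4 at one decimal
hba1c_ifcc_to_ngsp(35.3)  # 5.381244  -> 5.38

# Patlak recovery of a known net influx rate
inp <- feng_input(seq(0, 95, by = 0.05), 100)
tac <- simulate_2tcm(kinetic_params(0.1, 0.15, 0.05), inp, seq(0, 95, 0.25))
patlak_fit(tac, inp, t_star = 20)
#> <patlak ki=0.02487 ml/ml/min, v0=0.414, r2=1.0000, n=301 (t*>=20 min)>
```

The first block analyses a full simulated trial end-to-end (clamp traces,
OGTT samples, FDG sessions) and shows the post-surgery tissue pattern the
generator injects: leg-muscle glucose uptake rises (~+25%) while cardiac
uptake falls, both significant within the surgery arm (the per-trial
estimate of the injected +25% muscle effect varies with the simulation
seed). The Patlak fit recovers the analytic `Ki = 0.1·0.05/0.20 = 0.025`
within 0.5%.

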