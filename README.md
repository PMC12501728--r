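# renalperf

Renal cortical perfusion can be measured without exogenous contrast by
FAIR arterial spin labeling MRI (ASL) and, on hybrid PET/MR scanners,
simultaneously by dynamic [15O]H2O PET.  Whether the two modalities
agree — within a scan session, across weeks, and with each other — is a
statistical question about repeated, nested measurements, not a single
correlation.  `renalperf` implements the full analysis chain for such a
dual-modality study, for imaging scientists who want a tested, scriptable
alternative to scanner-console and one-off in-house code:

* **ASL**: pair averaging, single-subtraction FAIR quantification

  f = 6000 λ ΔM e^(TI/T1b) / (2 α TI M0)   [mL/min/100 mL]

  with renal protocol constants (T1,blood 1600 ms, λ 0.9 mL/g,
  α 0.6375, TI 1500 ms), cortical ROI means with the
  500 mL/min/100 mL voxel exclusion rule, and automated slice QC.

* **PET**: the one-tissue compartment model
  dCt/dt = K1·Ca(t−δ) − k2·Ct with measured signal
  (1−Va)·Ct + Va·Ca, fixed Va = 0.15 mL/mL, fitted arterial delay,
  duration-weighted fits over the first 150 s, perfusion = k2·p·100
  (p = 0.94 mL/g); basis-function parametric K1/k2/perfusion maps; and
  an image-derived input function extracted from the abdominal aorta by
  seeded k-means clustering of voxel curve shapes.

* **Agreement**: linear regression, Bland–Altman limits of agreement,
  and a REML variance-components mixed model (participant, kidney,
  day random effects; participant/day/residual SDs modality-specific)
  from which repeatability, reproducibility and cross-modality
  LoA = 1.96·√(Σ relevant σ²) and CoV = (LoA/1.96)/√2 / mean are
  derived.

* **Phantoms**: synthetic dynamic PET volumes (26-frame, 420-s
  schedule), FAIR control/label series, and long-format agreement
  tables with known variance components, so every stage is validated
  as a round trip against ground truth.

## Worked example

Fit a noisy simulated cortical time-activity curve and quantify an ASL
difference signal:

```r
library(renalperf)

input <- make_aif(peak_time = 30, peak_amplitude = 40, recirc_fraction = 0.1)
sched <- default_frame_schedule()          # 1x10, 8x5, 4x10, 2x15, 3x20, 8x30 s
truth <- kinetic_params(K1 = 3.0, k2 = 3.19, va = 0.15, delay = 4)
curve <- simulate_tac(truth, input, sched, noise_scale = 0.3, seed = 2)
fit_1tcm(curve, input)
#> <1TCM fit: K1 = 3.075 mL/min/mL, k2 = 3.238 /min, delay = 4.20 s,
#>  perfusion = 304.4 mL/min/100 mL, 17 frames>
```

The fitted clearance (3.238 /min vs the true 3.19) times the partition
coefficient gives cortical perfusion 304.4 mL/min/100 mL against a true
300 — a 1.5% error at roughly 5% frame noise.  The ASL side inverts
exactly on noise-free data:

```r
dm <- 300 * 2 * 0.6375 * 1.5 * 1000 * exp(-1.5 / 1.6) / (6000 * 0.9)
dm                                          # forward difference signal
#> 41.608
quantify_perfusion(array(dm, 1), array(1000, 1))$values
#> 300
```

A full simulated study — 10 participants, 2 kidneys, 3 scans, both
modalities — and its mixed-model agreement summary:

```r
tab <- simulate_agreement_dataset(agreement_design(), variance_components(),
                                  seed = 1)
mfit <- fit_mixed_model(tab)
derive_agreement(mfit, comparison_repeatability("ASL"))
#> $name        "ASL repeatability"
#> $bias        -10.7
#> $loa         68.9        # 1.96 * sqrt(2 * residual_ASL^2)
#> $cov_percent 8.87
```

At n = 10 the component estimates are individually noisy (that is, in
fact, one of the study-design lessons the variance model makes
explicit); the recovery tests average over replicate simulated studies.
`run_pipeline()` chains everything end to end — phantom, IDIF, kinetic
fits, ASL quantification, mixed model — and is bit-reproducible given a
seed.  A thin command-line front end lives at `inst/cli/renalperf.R`
(`simulate | asl | pet | agree | run`).

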