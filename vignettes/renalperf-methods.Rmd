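---
title: "Methods: dual-modality renal perfusion quantification and agreement analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-modality renal perfusion quantification and agreement analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renalperf)
```

# Scope

`renalperf` implements the analysis chain of a dual-modality renal
perfusion study in which each kidney's cortical perfusion is measured
simultaneously by FAIR arterial spin labeling MRI (ASL) and by dynamic
[15O]H2O PET, repeated within a day and across days, and the two
modalities are compared with agreement statistics.  Because studies of
this kind rarely deposit raw scans, the package pairs every analysis
stage with a synthetic generator whose ground truth is known exactly, so
each stage can be validated as a round trip.

# ASL quantification

The FAIR difference signal is quantified with the single-subtraction
inversion-recovery model

$$ f = \frac{6000\,\lambda\,\Delta M\, e^{TI/T_{1,\mathrm{blood}}}}
            {2\,\alpha\, TI\, M_0} $$

with perfusion $f$ in mL/min/100 mL (unit tissue density, so /100 g and
/100 mL coincide), $\Delta M$ the pair-averaged control-minus-label
signal, $M_0$ the proton-density image, $TI$ the inflow time in seconds
and $\lambda$ the blood-tissue partition coefficient in mL/g.  Defaults
are the renal protocol constants: $T_{1,\mathrm{blood}}$ 1600 ms, tissue
T1 1400 ms, $\lambda$ 0.9, combined labelling/background-suppression
efficiency $\alpha = 0.6375$, $TI$ 1500 ms.  Vendor implementations
differ in whether a tissue-relaxation term enters; we adopt the plain
single-subtraction form, treat $\alpha$ as a single multiplier, and
expose a multiplicative `correction_factor` so a vendor variant can be
slotted in without touching the pipeline.  Pair averaging precedes
quantification (the averaged $\Delta M$ is quantified once, not per
pair).

Cortical ROI values are means over valid voxels after removing voxels
above 500 mL/min/100 mL — the standard guard against large-vessel and
artifact voxels in renal cortex ROIs.  `slice_qc()` provides a
deterministic surrogate for the visual slice rejection a reader would
perform: a slice is dropped when its fraction of negative difference
voxels exceeds 0.4 (a pure-noise slice sits near 0.5) or its mean falls
below 10% of the median slice mean.  On clean synthetic data all slices
pass; the thresholds are configurable and can be disabled.

```{r asl}
dm <- 300 * 2 * 0.6375 * 1.5 * 1000 * exp(-1.5 / 1.6) / (6000 * 0.9)
dm                                        # forward difference at 300 mL/min/100 mL
quantify_perfusion(array(dm, 1), array(1000, 1))$values
```

# PET kinetics

Tissue concentration follows the one-tissue compartment model
$\dot C_t = K_1 C_a(t - \delta) - k_2 C_t$, measured as
$C = (1 - V_a) C_t + V_a C_a(t - \delta)$ with the arterial blood volume
fraction fixed at $V_a = 0.15$ mL/mL.  Perfusion is $k_2\,p \cdot 100$
with the tissue-blood partition coefficient $p = 0.94$ mL/g — for a
freely diffusible tracer the clearance rate, not the uptake rate, is the
robust perfusion estimate in a vascular organ.  The alternative
measurement equation $C_t + V_a C_a$ is available behind a flag.

Numerics: the convolution with the exponential impulse response is
evaluated exactly for a piecewise-linear input on its fine grid (0.1 s)
through a first-order recursive filter, and model values are averaged
over each frame so simulated and fitted curves live on the same footing.
Only frames whose midpoint lies within the first 150 s enter the fit (17
of the 26 default frames) — later frames carry little flow information
for [15O]H2O and more motion.  Weights default to frame durations, the
usual surrogate for count-limited variance; uniform weights are
available.  The arrival delay is grid-searched over ±10 s in 0.5-s steps
with parabolic refinement; $K_1$ is profiled linearly at each
$(k_2, \delta)$ and $k_2$ minimised by bracketed search on the log scale
in [0.01, 20] /min.  Estimates at the clearance search boundary are
flagged as non-converged.

Parametric maps use the basis-function method: tissue responses
$B_\theta = C_a(\cdot - \delta) \otimes e^{-\theta \cdot}$ are
precomputed on a default grid of 50 log-spaced clearance values in
[0.06, 6] /min (bracketing physiological renal clearance of roughly
1–5 /min), reducing each voxel to a linear solve per node plus grid
selection.  The delay is fixed (typically from an ROI fit); whether a
per-voxel delay adds anything is doubtful at renal SNR and we chose the
fixed-delay convention.  On noise-free phantoms the voxel estimates
match the nonlinear ROI fit to within one grid step, and refining the
grid can only decrease each voxel's residual.

The input function is image-derived: voxel curves in a search region
around the abdominal aorta are area-normalised, partitioned by seeded
k-means (default 4 clusters), and the cluster maximising peak over tail
mean (earliest time-to-peak as tie-break) is taken as arterial; the IDIF
is the mean raw curve of that cluster, optionally restricted to its
hottest fraction.  Normalisation removes amplitude so the clustering
separates curve *shapes*; under point-spread blur, pure-spill voxels
share the arterial shape and only the hottest-fraction restriction
rejects them — with a 6-mm PSF, keeping the hottest ~10% recovers the
first-pass peak to a few percent on the default phantom.  The
frame-sampled IDIF is returned to a fine grid by a mean-preserving
piecewise-linear reconstruction (each frame's average is preserved
exactly), which retains the first-pass peak height that plain midtime
interpolation flattens and makes input-function-driven fits accurate to
well under 1% on noise-free data.

# Agreement statistics

Pairwise agreement uses ordinary Bland–Altman analysis (bias ± 1.96
sample SDs of the differences).  The study-level analysis is a linear
mixed-effects model on the long-format table of single-kidney perfusion
values: fixed effects of modality, scan sequence (1–3) and their
interaction; random intercepts for participant, kidney-within-
participant and day-within-kidney; independent residuals.  Participant,
day and residual SDs are modality-specific; the kidney SD is shared.
Allowing the *residual* SD to vary with modality goes beyond the
narrower reading in which only participant and day SDs do — without it,
same-day repeatability (which is driven purely by residual variation)
could not differ between modalities, yet modality-specific repeatability
is exactly what such studies report.  We treat this as the intended
model.  Cross-modality random effects are drawn independently by
default; a shared-plus-specific participant decomposition is available
(`sd_participant_shared`) because cross-modality agreement depends on
that choice and the convention is not standardised.

Estimation is restricted maximum likelihood written directly on the
block-diagonal marginal covariance (one block per participant): fixed
effects are profiled out by generalised least squares and the log-SDs
are optimised by Nelder–Mead plus BFGS polish from a method-of-moments
start and a scaled restart, keeping the better optimum.  Blocks with
identical design patterns share their Cholesky factors, so balanced
designs cost one 12×12 factorisation per objective evaluation.
Vanishing SDs are pinned to the zero boundary; data with zero residual
spread (pure fixed effects) short-circuit to OLS with all SDs zero,
since REML is improper there.  On single-modality nested designs the
estimates agree with `lme4::lmer` to optimizer tolerance, and on
balanced one-way layouts with the closed-form ANOVA components; both
serve as independent oracles in the test suite, never as the
implementation.

Derived agreement statistics follow the variance-summation rule: for two
compared measurements, the SD of their difference is
$\sqrt{\sum \sigma^2}$ over every random component that differs between
them, counted once per measurement with the modality-appropriate value —
residual always; day when the measurements are on different days *or*
from different modalities (day effects are modality-specific);
participant only across modalities; the shared kidney term always
cancels (same-kidney comparisons).  Then LoA $= 1.96\,\mathrm{SD}$ and
CoV $= 100\,(\mathrm{SD}/\sqrt{2})/\bar{f}$, the $\sqrt 2$ assigning one
measurement's share of a paired difference.  The reference mean
$\bar{f}$ defaults to the mean of the observed cell means entering the
comparison and can be overridden.

```{r cov}
# repeatability LoA of 85.4 mL/min/100 mL at a scan-1/2 mean of 283.5
cov_from_loa(85.4, 283.5)
```

# The synthetic generators

The phantom module supplies every input the analysis consumes, under
the acquisition conditions of the study design: a 26-frame, 420-s
dynamic PET schedule (1×10, 8×5, 4×10, 2×15, 3×20, 8×30 s), 20 ASL
control/label pairs with the constants above, and a
10-participant × 2-kidney × 3-scan × 2-modality agreement design (scans
1–2 on day 1, scan 3 on day 2), i.e. 60 single-kidney measurements per
modality.

Choices the study itself does not pin down are artifact defaults, chosen
once on physiological grounds:

* **Arterial input.**  A gamma-variate first pass (shape 3, arrival
  10 s, peak 30 s at 40 kBq/mL) with an optional exponential
  recirculation tail.  A measured aortic curve would be bumpier; the
  gamma-variate has a closed-form integral, which the tests exploit.
* **PET noise.**  Zero-mean Gaussian with per-frame SD proportional to
  $\sqrt{\mathrm{value}/\mathrm{duration}}$ — the standard surrogate for
  reconstructed count statistics.  True reconstruction noise is
  spatially correlated and non-Gaussian at low counts; consequently the
  phantom validates estimator behaviour, not absolute noise levels.
* **Geometry.**  Simple ellipsoids on a 48×48×24 grid of 3-mm voxels:
  an elongated central aorta of 10-mm radius (the calibre of the adult
  abdominal aorta, which is why its core survives a 6-mm PSF), two
  cortex ellipsoids (default K1 3 mL/min/mL, k2 3.19 /min ≈ 300
  mL/min/100 mL), and two low-flow medulla ellipsoids.  Anatomical
  kidney shapes, motion, attenuation and scatter are out of scope, so
  passing tests say nothing about motion robustness on real data.
* **Agreement variance defaults.**  Residual SDs near 31 (ASL) and 25
  (PET) mL/min/100 mL, day SDs near 8.5, participant SDs near 39 —
  back-solved once from the variance-summation rule so that the
  generator's dispersion emulates published healthy-kidney agreement
  statistics.  They are generator defaults, not estimates.

Problem sizes used in the validation suite are deliberately desk-scale:
noisy 1TCM recovery uses 200 replicate TACs at ~5% peak CoV;
variance-component recovery RMS-averages REML estimates over 40
replicate studies of 200 participants (a single study of 200 leaves the
weakly identified day SDs with ~25% Monte-Carlo spread — the day
contrast is residual-dominated, and the REML estimate legitimately hits
the zero boundary on some draws — so replicate averaging is needed to
test the estimator rather than one draw); the LoA rule is checked
against 10^5 directly simulated paired differences.

# Known limitations

* The vendor's exact ASL quantification variant (and the role of the
  1400-ms tissue T1 in it) is not public; the package reproduces the
  stated constants in the standard model and leaves a correction-factor
  hook.
* The IDIF clustering recipe (normalisation, cluster count, selection
  rule, hot-voxel fraction) is a configurable artifact choice, seeded
  for reproducibility; real-data performance depends on dispersion and
  partial-volume effects the phantom does not model.
* Delay handling for parametric maps reuses a single ROI-fit delay per
  scan; per-voxel delays are not estimated.
* Whether the random participant effects of the two modalities should
  be correlated is not identifiable from the model structure alone;
  both options are provided and the default (independent) is stated,
  not asserted as the original analysis's choice.
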