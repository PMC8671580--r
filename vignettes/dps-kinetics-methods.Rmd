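---
title: "Kinetic modelling of dynamic planar myocardial MIBG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modelling of dynamic planar myocardial MIBG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpskin)
```

## The measurement problem

Myocardial scintigraphy with radio-iodinated meta-iodobenzylguanidine (MIBG),
a norepinephrine analogue, is the standard imaging biomarker for Lewy body
disease (LBD): degeneration of cardiac sympathetic nerve terminals lowers
myocardial tracer retention. The conventional read-out is two static planar
scans hours apart, summarised as early and delayed heart-to-mediastinum count
ratios (eHMR, dHMR) and a washout rate (WR). Those indices ignore the tracer's
kinetics — the first-pass extraction, the continuous loss from vesicular
stores — and the long pause between scans is burdensome for exactly the
patients being evaluated.

`dpskin` implements the alternative: a single 30-minute dynamic planar
acquisition (145 frames: 30 × 2 s, 40 × 6 s, 75 × 20 s, optionally followed by
two 3 × 300 s static scans at 90 and 180 min), compartmental modelling of the
resulting time–activity curves (TACs), and a diagnostic-performance layer.
Because clinical data of this kind cannot be shared, the package also ships a
synthetic-cohort generator with known ground truth, so the entire chain is
testable end to end.

## From mediastinal curve to plasma input function

The mediastinal ROI curve (mTAC) serves as an image-derived estimate of blood
activity. From its peak time onward it is fitted
(`fit_mtac()`) with a three-phase exponential plus constant,

$$m(t) = \sum_{i=1}^{3} A_i e^{-\lambda_i (t - t_0)} + C,$$

by frame-duration-weighted Levenberg–Marquardt least squares with
non-negativity bounds and ten log-spaced rate initialisations (screened
cheaply, best start polished to `ftol` $10^{-15}$). Two numerical points
deserve note:

* **$t_0$ is not identifiable post-peak.** Shifting $t_0$ by $\delta$ and
  rescaling each $A_i$ by $e^{\lambda_i \delta}$ produces the identical
  curve. The fit therefore reports the unique representative with $t_0$ at
  the peak-frame midpoint; tests compare amplitudes only after
  re-referencing to a common $t_0$.
* **Rates are capped at 30 min⁻¹.** An unbounded fastest rate lets a single
  noisy frame be absorbed by a near-delta component (rates of order
  $10^8$ min⁻¹ were observed on synthetic data), which corrupts everything
  downstream. A 30 min⁻¹ phase decays within a couple of seconds — faster
  than any physiologic blood-clearance phase at this frame resolution.

Plasma, not whole blood, drives the tissue, and only the parent compound
enters the terminals. Lacking per-patient blood samples, the package applies
population-shaped corrections (`correction_curves()`): a blood-to-plasma
ratio (BPR) held at 0.6 (haematocrit 40%) for the first 45 s and rising
smoothly to a plateau, and a parent-fraction curve (PBMC) declining
monotonically from 1 at injection to an asymptote of 0.30. The published
population curves' exact shapes are not reproduced anywhere accessible, so
both are parametric stand-ins — exponential approaches with default rates
0.05 min⁻¹ (BPR) and 0.03 min⁻¹ (PBMC) — and every parameter is
configurable. They are assumptions to be replaced when better population data
are available, not measurements.

The plasma input function is then
$\mathrm{PIF}(t) = m(t)\,\mathrm{pbmc}(t)/\mathrm{bpr}(t)$ (`build_pif()`,
`pif_fun()`), and the tissue curve is the heart ROI minus the fitted
mediastinal model (`build_ttac()`); tissue values may legitimately be
negative after subtraction.

**Before the peak** the fitted model is evaluated as a linear ramp from zero
at injection. This matters: the compartment convolution integrates the input
from $t=0$, and extrapolating the peak value backwards (an alternative
"hold" mode, available but not default) inflated early input mass enough to
bias the loss-rate estimate by about 7% in development tests. No activity
exists before the bolus arrives; the ramp encodes that.

## The compartment model and its estimation

The tissue curve follows a one-tissue model with two or three parameters:

$$\mathrm{tTAC}(t) = \mathrm{PIF}(t) \otimes \mathrm{iUp}\,
  e^{-\mathrm{iLoss}\, t} + \mathrm{iNs} \cdot \mathrm{PIF}(t),$$

where iUp (min⁻¹) is the unidirectional uptake rate into vesicular trapping,
iLoss (min⁻¹) the fractional loss rate of trapped tracer (turnover), and iNs
(unitless) the non-specific interstitial distribution, justified by the
assumption that the interstitium equilibrates with plasma within a minute of
injection — which is also why the fit window starts at 1 min. The
two-parameter variant (1T2P) omits iNs.

Numerical choices (`forward_model()`, `fit_kinetics()`):

* **Convolution** on a uniform 1-s grid with the exponential-integrator
  update $y_{k+1} = y_k e^{-L\,\Delta} + \mathrm{iUp}\,P(t_k + \Delta/2)
  (1 - e^{-L\Delta})/L$. This is *exact* for inputs constant over each cell
  (the convolution-oracle test exploits that) and second-order for smooth
  inputs; it is well defined for negative $L$, which the unconstrained fit
  requires. Model values are compared to data as frame averages, because
  frames span 2–300 s and midpoint sampling biases long frames (a midpoint
  mode exists for speed).
* **Estimation by variable projection.** At fixed iLoss the model is linear
  in (iUp, iNs), so those are profiled out by weighted linear least squares
  and iLoss is found by a coarse grid (−0.4 to 1 min⁻¹) refined with Brent's
  method. This replaces a multi-start 3-parameter nonlinear search: it is
  deterministic, has no starting-value sensitivity, and cannot converge to a
  local optimum in the linear coordinates. All parameters remain
  unconstrained — negative estimates are reported and counted (`NegCnt` in
  `truncation_study()`), never censored, because their frequency under scan
  truncation is itself a finding.
* **Weights** are proportional to frame duration (an approximate-Poisson
  duration/value mode is available); scaling all weights by a constant
  provably leaves the minimiser unchanged.
* **Degeneracy**: an all-zero tissue curve leaves iLoss undefined; the fit
  flags `identifiable = FALSE` and floors the weighted residual sum at
  $10^{-12}$ before computing the information criteria
  AIC $= N\ln(\mathrm{WSSR}) + 2p$ and SIC $= N\ln(\mathrm{WSSR}) +
  p\ln N$, which satisfy AIC − SIC $= p(2-\ln N)$ identically.

Derived indices (`derive_indices()`): the composite specific-distribution
ratio iUp/iLoss and the pharmacological half-life 0.693/iLoss min (the
conventional rounded constant, not `log(2)`), both flagged undefined when
iLoss ≤ 0. Note that a mean of per-patient ratios is not a ratio of means.

## Conventional indices

`hmr()` is the duration-weighted heart/mediastinum window mean ratio
(early 10–15 min, delayed 190–195 min). `washout_rate()` is
$[(H_e - M_e) - (H_d - M_d)]/(H_e - M_e)$ on decay-corrected window means;
once both terms share any common decay reference the choice of reference
time cancels, so curves decay-corrected to injection need no further
adjustment. Physical decay uses the iodine-123 half-life 13.2235 h
(configurable); the value is the standard nuclide constant. `fit_linear()`
and `fit_monomolecular()` provide the regressions linking new to existing
indices (HMRs against iUp/iLoss; WR against iLoss via the saturating
one-phase association $y = Y_0 + (P - Y_0)(1 - e^{-kx})$, and against
0.693/iLoss linearly). The monomolecular fit is likewise a profiled linear
fit over a rate grid, because generic NLS fails on noise-free data with zero
residual — a case the test suite exercises.

## Diagnostic performance layer

* `roc_auc()` computes the AUC as the exact Mann–Whitney concordance
  (half credit for ties) with a seeded stratified bootstrap CI, and the
  Youden cut-off over observed score values with ties broken towards the
  least extreme threshold. Orientation is explicit per index: iLoss and WR
  rise with disease; iUp/iLoss, eHMR and dHMR fall.
* `bootstrap_auc_test()` is a paired, stratified subject-resampling test of
  an AUC difference (normal-based on the bootstrap SE, two-sided).
* `smote()` balances classes by interpolating between a minority point and
  one of its k = 5 nearest minority neighbours at a uniform random
  fraction; output counts are exactly equal and bit-reproducible for a
  fixed seed.
* `repeated_svm_evaluation()` runs seeded stratified 70/30 splits
  (per-class floors, remainders by largest fractional part, so a 210-sample
  balanced cohort always yields 63 test samples), standardises features on
  the training part only, and fits a linear or RBF support vector machine
  (cost 1; RBF bandwidth $1/d$ on standardised features — the unstated
  original hyperparameters are defaulted, all configurable). Each run
  records the test AUC from decision values and the diagnostic odds ratio
  (TP·TN)/(FP·FN) with 0.5 added to every cell whenever any is zero.
  Balancing is applied once up front by default (matching the published
  workflow figure); a per-fold mode can be built from the pieces if wanted.
* `dunnett_comparison()` wraps a pooled-variance many-to-one multivariate-t
  comparison (single-step Dunnett) with a seeded quadrature, reducing
  exactly to the pooled t-test for two groups.

Patients whose fitted iLoss is non-positive are excluded from ratio-based
analyses and counted (`dps_evaluate()` reports the count), mirroring the
NegCnt bookkeeping.

## The synthetic cohort: what it emulates and what it does not

`cohort_config()`/`generate_cohort()` draw 166 patients by default — 105 LBD
(35 pRBD-positive Parkinson's disease, 61 pRBD-negative PD, 9 dementia with
Lewy bodies) and 61 non-LBD — with per-group distributions of the true
kinetic parameters: moment-matched log-normals for iLoss and for the ratio
iUp/iLoss (iUp is their product, which naturally reproduces the observed
partial counterbalancing of high loss by uptake), and a zero-truncated
normal for iNs (0.21 ± 0.11). The three LBD subgroups use reported subgroup
statistics as calibration anchors (ratio 1.17 ± 0.47, 2.30 ± 1.67,
1.09 ± 0.68; iLoss 0.0647 ± 0.0170, 0.0557 ± 0.0129, 0.0683 ± 0.0247). No
non-LBD distribution has been reported, so the control group is this
package's assumption: iLoss 0.035 ± 0.008 — anchored to the reported normal
loss rate (< 0.035 min⁻¹) of a comparable catecholamine tracer — and ratio
4.0 ± 1.2, chosen once, a priori, so that the implied class separation sits
at the discrimination level reported for the indices (AUC ≈ 0.9 for iLoss);
it was not adjusted afterwards. Conclusions about the *real* cohort's
non-LBD patients cannot be drawn from it.

Each patient's mediastinal curve jitters a bolus-like template
(A = 40, 8, 2 cps/pixel; λ = 2.0, 0.15, 0.01 min⁻¹; C = 0.8; t₀ = 0.5 min —
a sharp peak with slow late clearance) on the log scale. Scans are simulated
by running the forward model and adding zero-mean Gaussian noise with
variance proportional to value/duration — the Poisson counting law for a
ROI-mean rate. The default `noise_level = 0.35` was calibrated once against
the reported truncation behaviour of the clinical cohort (the share of
negative iLoss estimates at a 5-min truncation, 14% there, 17% here; the
order of magnitude of the 5-min dispersion) and then frozen.

What the generator does **not** emulate: spillover and partial-volume
effects between heart and mediastinum, patient motion, scatter and
attenuation, ROI-placement variability, and any correlation structure
between mediastinal shape and disease group. Passing tests therefore
demonstrate the correctness and stability of the *analysis chain*, not
clinical performance on real images.

Determinism throughout: every stochastic step takes an explicit seed;
per-patient seeds derive from the master seed; a fixed configuration and
seed reproduce cohorts, fits and reports byte for byte.

## Problem sizes used by the shipped tests

The test suite exercises the default 166-patient cohort once (cached across
test files), a 50-patient subset for the truncation comparison at 5 and
30 min, 10,000 generator draws for the calibration checks, and reduced
bootstrap/SVM run counts where only structure is being asserted; the full
200-run evaluation is available through `dps_evaluate()` defaults. These
sizes were chosen to keep the suite fast while leaving every scientific
assertion at its stated tolerance.

## Known limitations

* The BPR/PBMC correction shapes are stand-ins; kinetic indices shift
  systematically if the true population curves differ. This is the main
  caveat for absolute (not comparative) use of iUp and iNs.
* The heart ROI blood contribution is handled only through mediastinal
  subtraction, as in the reference protocol; no explicit blood-pool spill
  term is modelled.
* `0.693/iLoss` and `iUp/iLoss` are unstable near iLoss = 0; the package
  flags rather than imputes them.
* The SVM hyperparameters are sensible defaults, not tuned values; no
  nested cross-validation is performed.
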