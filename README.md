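# dpskin

Kinetic analysis of **d**ynamic **p**lanar **s**cintigraphy of myocardial
¹²³I-MIBG (meta-iodobenzylguanidine), for researchers in nuclear cardiology
and movement-disorder neurology who want tracer *turnover* — not just static
uptake ratios — from a single 30-minute planar acquisition.

Cardiac sympathetic denervation in Lewy body disease (LBD) lowers myocardial
MIBG retention. The conventional read-out (early/delayed heart-to-mediastinum
ratios and washout rate from two static scans hours apart) ignores the
kinetics. `dpskin` fits the dynamic time–activity curves with a one-tissue
compartment model,

```
tTAC(t) = PIF(t) ⊗ iUp · exp(−iLoss · t) + iNs · PIF(t)
```

where the plasma input function PIF is the tri-exponentially fitted
mediastinal curve corrected by population blood-to-plasma (BPR) and
parent-fraction (PBMC) curves, `⊗` is convolution, and the estimated
parameters are the uptake rate **iUp** (min⁻¹), the loss (turnover) rate
**iLoss** (min⁻¹) and the non-specific interstitial fraction **iNs**.
Derived indices are iUp/iLoss and the pharmacological half-life 0.693/iLoss.
Fits use frame-duration-weighted nonlinear least squares (variable
projection: iLoss profiled by Brent search, iUp/iNs solved linearly), with
AIC/SIC model comparison against the two-parameter variant and a
scan-truncation study that counts negative estimates (NegCnt).

A diagnostics layer provides ROC/AUC with Youden cut-offs, paired bootstrap
AUC comparison, SMOTE class balancing, repeated split-sample linear/RBF SVM
evaluation with diagnostic odds ratios, and Dunnett subgroup comparison.
Because clinical data of this kind are not shareable, a synthetic-cohort
generator (105 LBD + 61 non-LBD by default, subgroup distributions on
published calibration anchors, Poisson-like counting noise, known ground
truth) makes the full chain reproducible and testable. See the methods
vignette (`vignettes/dps-kinetics-methods.Rmd`) for the model, assumptions
and design decisions.

## Worked example

Simulate a small cohort, run the kinetic pipeline, evaluate discrimination:

```r
library(dpskin)
cfg  <- cohort_config(n = c(PD_pRBDneg = 8, nonLBD = 8))
ch   <- generate_cohort(cfg, seed = 42)
scans <- lapply(ch$scans, function(s) list(htac = s$htac, mtac = s$mtac))
fit  <- dps_fit_cohort(scans, cfg$corrections, end_times_min = 30, models = "1T3P")
head(merge(fit$kinetic, ch$cohort[, c("patient_id", "true_iLoss")]), 4)
#>   patient_id        iUp      iLoss true_iLoss     ratio       aic
#> 1       p001 0.11735473 0.06604793 0.06675905 1.7768117 181.81694
#> 2       p002 0.04211293 0.04998705 0.04857596 0.8424769  66.24359
#> 3       p003 0.18237987 0.06341701 0.06371562 2.8758826 209.88342
#> 4       p004 0.83102682 0.08527327 0.08540680 9.7454550 321.84484

rep <- dps_evaluate(fit, ch$cohort[, c("patient_id", "class_label", "subgroup")],
                    n_runs = 50, n_boot = 500, seed = 1)
rep
#> <dps_report> 16 patients, 1T3P at 30 min
#> ROC:
#>   index   auc cutoff sensitivity specificity
#> 1 iLoss 0.984 0.0432       1.000       0.875
#> 2 ratio 0.828 3.9260       0.875       0.750
#> 3  eHMR 0.672 4.7748       0.625       0.875
#> 4  dHMR 0.844 2.2836       0.875       0.875
#> 5    WR 0.844 0.9362       0.750       0.875
#> SVM mean AUC: linear 0.930, RBF 0.980; mean DOR: linear 25.4, RBF 23.2
```

Each fitted `iLoss` tracks its ground truth to a few percent; `iLoss`
separates the simulated disease groups best, matching the design of the
generator. `write_report(rep, "report.json")` serialises the evaluation with
a provenance block. A thin command-line front end
(`inst/cli/dpskin.R simulate|fit|evaluate`) wraps the same functions for
shell use.

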