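# ToftsPK

Quantitative pharmacokinetic analysis of dynamic contrast-enhanced
(DCE) MRI, built for per-site treatment-response studies in head-and-neck
squamous cell carcinoma and usable for any single-compartment DCE
protocol. The package is aimed at imaging scientists who need the whole
chain — relaxometry, tracer kinetics, ROI statistics and the clinical
outcome layer — as tested, scriptable R functions rather than a vendor
black box.

## What it computes

Tissue gadolinium concentration follows the standard Tofts model

    C_t(t) = Ktrans ∫₀ᵗ C_p(τ) e^(−kep (t−τ)) dτ,

with the volume transfer constant `Ktrans` (min⁻¹), the efflux rate
`kep` (min⁻¹) and the extravascular extracellular volume fraction
`ve = Ktrans/kep`. Around this core the package provides:

* **Relaxometry** — closed-form dual-flip-angle (2°/15°) SPGR T1
  mapping (`fitT1DualFlip`), with plausibility bounds and validity masks.
* **Concentration** — SPGR inversion of the dynamic signal against the
  pre-contrast T1 map with baseline-calibrated M0 and relaxivity
  r1 = 4.5 s⁻¹mM⁻¹ (`signalToConcentration`); arterial input function
  extraction with hematocrit correction (Hct 0.42, `extractAIF`).
* **Kinetics** — exact-exponential discretized Tofts convolution
  (`toftsForward`), voxel-wise bounded Levenberg–Marquardt fitting with
  deterministic profile initialisation (`fitToftsVoxel`,
  `fitParameterMaps`), an R² ≥ 0.7 quality filter, and AUGC in mM·min
  (`computeAUGC`).
* **ROI analysis** — filtered ROI means, volumes in cm³, pre-to-post
  percent change (`roiMean`, `roiVolume`, `percentChange`).
* **Outcome statistics** — logistic regression with Wald odds-ratio CIs,
  p-value-based stepwise selection with confounder adjustment, paired
  t-tests, ROC analysis with Youden-index thresholds and DeLong CIs,
  diagnostic-performance tables and Fisher's exact test.
* **Synthetic data** — 4D phantoms with known kinetic ground truth and
  simulated per-site cohorts (`generatePhantom`, `generateCohort`), so
  every stage is testable without clinical data.

## Worked example

Simulate one tumour voxel at the study protocol, recover its kinetics,
and run the headline outcome statistics:

```r
library(ToftsPK)

p  <- AcquisitionProtocol()                   # TR 4 ms, 2°/15°, 2.59 s × 185
t  <- frameTimes(p)
cp <- evaluateAIF(AIFModel(onset = 6), t)     # population AIF, bolus at 6 s
ct <- toftsForward(0.37, 0.67, cp, t)         # ground truth kinetics
sig <- synthesizeSignal(ct, t10 = 1400, m0 = 1000, p,
                        noiseSigma = 0.4, seed = 1)
cs  <- signalToConcentration(sig, t10 = 1400, protocol = p)
fitToftsVoxel(cs, AIF(t, cp))
#> Tofts fit: Ktrans 0.3748 /min, kep 0.6734 /min, ve 0.5566,
#>            R2 0.9978, AUGC 2.539 mM min
```

The fitted `Ktrans`/`kep` land within ~1% of the simulated truth at this
noise level, `ve` is their ratio by construction, and the AUGC sits in
the 2–3 mM·min range typical of untreated tumour.

```r
diagnosticPerformance(tp = 10, fp = 4, tn = 15, fn = 4)
#>   sensitivity specificity accuracy  ppv  npv
#>          71.4        78.9     75.8 71.4 78.9
fisherExact2x2(matrix(c(10, 4, 4, 15), 2, byrow = TRUE))
#> [1] 0.00567

co <- generateCohort(CohortSpec(seed = 2))    # 14 SF vs 19 SC sites
rocAnalysis(co$pct_augc, co$outcome, positive = "SF")
#> ROC: AUC 0.782 (95% CI 0.624-0.94); optimal threshold > -13.65
#>      (sens 92.9%, spec 57.9%)
```

A full phantom-to-statistics run is one call,
`runPipeline(asPipelineConfig(list(seed = 1)), outDir = "out")`, and a
thin CLI with per-stage subcommands lives at
`inst/scripts/dce-pipeline.R` (see `inst/extdata/example_config.yaml`).

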