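---
title: "Methods: Tofts pharmacokinetic modelling of DCE-MRI and treatment-response statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Tofts pharmacokinetic modelling of DCE-MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ToftsPK)
```

## The problem

Dynamic contrast-enhanced (DCE) MRI follows a gadolinium bolus through
tissue with a fast T1-weighted sequence repeated every few seconds.
In head-and-neck squamous cell carcinoma, the perfusion and permeability
of the tumour vasculature carry information about hypoxia and hence about
the likelihood that a primary or nodal site will fail chemoradiotherapy.
`ToftsPK` implements the full quantitative chain for such studies:
relaxometry, signal-to-concentration conversion, kinetic modelling, ROI
summaries, and the outcome statistics that relate imaging parameters to
per-site treatment outcome (site control, SC, versus site failure, SF).
Because per-site clinical data of this kind are not publicly deposited,
the package ships a synthetic phantom and cohort generator with known
ground truth; every stage is validated against those.

## Signal model and relaxometry

The dynamic series is a spoiled gradient echo (SPGR) acquisition, whose
steady-state magnitude is

$$S = M_0 \sin\alpha \, \frac{1 - E_1}{1 - E_1\cos\alpha},
\qquad E_1 = e^{-TR/T_1}.$$

The default `AcquisitionProtocol()` encodes the study settings: TR 4.0 ms,
dynamic flip angle 15°, a 2° pre-contrast acquisition, 2.59 s per dynamic,
185 dynamics, injection commanded 6 s after the start of the dynamic run.

With exactly two flip angles the variable-flip-angle problem has a
closed-form solution: in the linearization $y = S/\sin\alpha$ versus
$x = S/\tan\alpha$ the two points determine a line of slope $E_1$, from
which $T_1 = -TR/\log E_1$ and $M_0$ follow. `fitT1DualFlip()` therefore
uses the deterministic two-point solution rather than an iterative fit.
Voxels with $E_1 \notin (0,1)$ or $T_1 \notin [50, 5000]$ ms are flagged
invalid rather than raising errors; no spatial smoothing or B1 correction
is applied (perfect spoiling and a uniform transmit field are assumed).

## Concentration and the arterial input function

Gadolinium shortens T1 in proportion to its concentration,
$R_1(t) = 1/T_{10} + r_1 C(t)$ with relaxivity $r_1 = 4.5\,
\mathrm{s^{-1}mM^{-1}}$ by default. `signalToConcentration()` inverts the
SPGR equation at the dynamic flip angle; the per-voxel scale $M_0$ is
calibrated from the pre-injection baseline frames together with the
pre-contrast T1 map, so baseline concentration is zero by construction.
Frame timestamps are the start of each dynamic readout; the baseline set
is the $\lfloor 6/2.59 \rfloor = 2$ dynamics wholly completed before the
injection command (the third frame overlaps the injection window and is
excluded). Any frame whose signal implies $E_1 \notin (0,1)$ — for
example magnitude above the SPGR ceiling $M_0\sin\alpha$ — invalidates
the voxel rather than being clipped.

`extractAIF()` averages the whole-blood concentration over an arterial
mask and divides by $1 - \mathrm{Hct}$ (default hematocrit 0.42) to give
the plasma curve $C_p(t)$. Arterial-voxel selection in clinical work is
manual and irreproducible; the synthetic module instead drives phantoms
with a parametric population AIF (`AIFModel()`). The default is the
classical biexponential decay
$C_p(t) = a_1 e^{-m_1 t'} + a_2 e^{-m_2 t'}$ (with $t'$ the time since
bolus arrival), whose parameters default to the standard population
values scaled to a 0.1 mmol/kg dose; this form admits analytic oracles
(value $a_1 + a_2$ at arrival, integral $a_1/m_1 + a_2/m_2$) that anchor
the tests. A Parker-type two-Gaussian-plus-sigmoid mixture is available
as an alternative. The biexponential jumps at onset (no upslope); the
injection-to-carotid delay is a free `onset` parameter, defaulting to the
injection command time, and is not calibrated to any particular cohort.

## The Tofts model and its fitting

Tissue concentration follows the one-compartment Tofts model,

$$C_t(t) = K^{trans}\int_0^t C_p(\tau)\, e^{-k_{ep}(t - \tau)}\, d\tau,$$

with $K^{trans}$ (min⁻¹) the plasma-to-interstitium transfer constant,
$k_{ep}$ (min⁻¹) the efflux rate, and $v_e = K^{trans}/k_{ep}$ the
extravascular extracellular volume fraction. Rate constants are carried
in min⁻¹ throughout; time grids are in seconds and converted exactly once
at the model boundary.

`toftsForward()` discretizes the convolution by treating $C_p$ as
piecewise linear between samples and integrating the exponential kernel
exactly on each interval (a recursive $O(n)$ scheme). For a constant
input this reproduces the closed-form step response
$\frac{K^{trans}}{k_{ep}} c_0 (1 - e^{-k_{ep}t})$ to machine precision,
which is the convolution oracle used in the tests.

`fitToftsVoxel()` minimizes the residual sum of squares over
$(K^{trans}, k_{ep})$, with $v_e$ derived — this parameterization makes
the ratio identity $v_e \equiv K^{trans}/k_{ep}$ exact for every
converged voxel, matching the reported trio. Because the model is linear
in $K^{trans}$ at fixed $k_{ep}$, initialisation is a deterministic
profile search over 25 log-spaced $k_{ep}$ values with $K^{trans}$
projected in closed form, followed by bounded Levenberg–Marquardt
refinement (`minpack.lm`). Bounds are $K^{trans} \in (10^{-4}, 5]$,
$k_{ep} \in (10^{-4}, 10]$ min⁻¹. The fit is fully deterministic given
inputs, and $v_e$ near or above 1 is retained (clinical fits in this
setting report unexpectedly high $v_e$) though physically implausible
regions warn at phantom-specification time.

The goodness of fit $R^2 = 1 - SS_{res}/SS_{tot}$ is reported per voxel;
`fitParameterMaps()` excludes voxels with $R^2 < 0.7$ (or non-converged
fits) from the `validMask` used downstream. A threshold "set for
fitting" could also be read as triggering a refit; exclusion is the
conservative interpretation and is applied consistently in the ROI stage.

AUGC, the area under the gadolinium concentration–time curve over the
whole acquisition, is the trapezoidal integral in **mM·min**. The unit
label seen in clinical reports for this quantity is sometimes "mM s",
but magnitudes of 2–3 over a ~460 s acquisition are only consistent with
minute-based integration, so minute units are adopted throughout.

## ROI summaries and percent change

`roiMean()` averages a parameter map over the voxels of a site mask that
pass the $R^2$ filter. A site with fewer than 5 valid voxels is declared
unanalyzable (`NA` with a warning) — the ROI counterpart of residual
masses too small or necrotic to evaluate. `roiVolume()` is voxel count ×
voxel volume in cm³, measured on the same contour used for the kinetics.
Pre-to-post change is `percentChange()` $= 100(post - pre)/pre$,
undefined when the pre-treatment value is zero.

## Outcome statistics

* **Logistic regression** (`univariateLogistic()`): ML fit of
  $\mathrm{logit}\,P(\mathrm{SF}) = \beta_0 + \beta_1 x$, odds ratio
  $e^{\beta_1}$ with Wald 95% CI (the convention of standard clinical
  software output); separation is flagged and the CI reported unbounded.
* **Stepwise selection** (`stepwiseMultivariate()`): forward selection on
  likelihood-ratio tests with entry $p < 0.05$ and removal $p \ge 0.10$
  — the conventional defaults when only "stepwise" is specified — then a
  refit including the stated confounders for adjusted odds ratios.
  AIC-based `step()` would answer a different question, so the p-value
  machinery is implemented directly.
* **Paired t-test** (`pairedTTest()`): two-sided test on post − pre
  differences; zero-variance differences are degenerate and flagged.
* **ROC analysis** (`rocAnalysis()`): the AUC is computed by the rank
  (Mann–Whitney) formulation, which equals the trapezoidal area under the
  empirical curve exactly; "equal weighting of sensitivity and
  specificity" is operationalized as maximization of the Youden index
  $J = se + sp - 1$, with candidate thresholds at midpoints between
  adjacent distinct scores and ties resolved to the lowest such
  threshold. The AUC confidence interval uses the DeLong variance
  estimator. These exact semantics are implemented in the package;
  `pROC` serves as an independent cross-check in the test suite.
* **Diagnostic tables** (`diagnosticPerformance()`): the five standard
  metrics in percent; zero-denominator ratios are `NA`, never 0.
* **Fisher's exact test** (`fisherExact2x2()`): two-sided by the
  minimum-likelihood rule (the R/SAS convention), delegated to
  `stats::fisher.test` and verified against brute-force hypergeometric
  enumeration for every 2×2 table with total ≤ 30.

Sites contributed by the same patient are treated as independent
observations — the design choice of the motivating analysis style — so
no clustering correction is applied.

## What the synthetic data do and do not emulate

`generatePhantom()` produces a motion-free 4D SPGR series whose tissue
voxels follow exact Tofts kinetics with known $(K^{trans}, k_{ep}, T_1,
M_0)$, an arterial region carrying $C_b = C_p(1-\mathrm{Hct})$, a 2°
pre-contrast volume for T1 mapping, and additive Gaussian magnitude
noise. Gaussian noise (rather than Rician) is used because at clinical
SNR the difference is negligible and Gaussian keeps the estimator
unbiased-ness arguments and oracles simple. Patient motion, B1
inhomogeneity, slice-profile effects and bolus dispersion between artery
and tissue are deliberately not simulated; a no-op registration hook is
the appropriate mental model for the motion-free phantoms. Passing the
phantom recovery tests therefore demonstrates correctness of the
estimation chain, not robustness to those physical confounds.

`generateCohort()` draws per-site parameter values with independent
normal marginals per outcome group from the moments in
`defaultCohortMoments()` (post-treatment residual-mass statistics, 14 SF
vs 19 SC sites). Marginals are not truncated, so requested moments are
matched in expectation; correlations between parameters within a site
are not modelled.

## Problem sizes and numerical choices

The validation suite uses a 12×12×4 phantom with a 200-voxel tumour
region at the full 185-frame study grid for end-to-end recovery (median
relative error of $K^{trans}$ and $k_{ep}$ under 5% at baseline SNR 50),
a 1000-replicate cohort simulation for the ROC benchmark (mean empirical
AUC for percent change in AUGC, 14-vs-19 sites), and 1000 null
replicates for the logistic type-I-error calibration. These sizes were
chosen so each property is measured with comfortable statistical margin
while the whole suite runs in well under a minute per file.

Degenerate inputs are handled explicitly rather than numerically:
all-zero concentration curves return non-converged results with
undefined $R^2$; constant predictors return the null odds ratio;
zero-variance paired differences are flagged; empty masks and
single-class outcomes are errors.

## Known limitations

* The two-angle T1 map inherits the noise of a single low-flip
  acquisition; no regularization is applied, so T1 errors propagate into
  concentration (visible as a small bias at low SNR).
* The population AIF replaces individual arterial sampling; absolute
  $K^{trans}$ values in real data depend strongly on that choice.
* The standard Tofts model omits a plasma-volume term; extended Tofts,
  two-compartment exchange and reference-region models are out of scope.
* Statistical routines assume independent sites; intra-patient
  correlation is not modelled.
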