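#' @import methods
NULL

#' Acquisition protocol for a dynamic SPGR series
#'
#' Holds the scanner and injection constants that drive both signal
#' synthesis and signal-to-concentration conversion: repetition/echo time,
#' the two flip angles of the dual-angle scheme, temporal resolution,
#' number of dynamics, injection timing and voxel geometry.
#'
#' @slot tr repetition time (ms)
#' @slot te echo time (ms); carried for provenance, not used in the models
#' @slot flipDynamic flip angle of the dynamic series (degrees)
#' @slot flipT1map low flip angle used for pre-contrast T1 mapping (degrees)
#' @slot dt temporal resolution (seconds per dynamic)
#' @slot nDynamics number of dynamic frames
#' @slot injectionStart time of the contrast injection command after the
#'   start of the dynamic acquisition (s)
#' @slot sliceThickness slice thickness (mm)
#' @slot matrixSize in-plane acquisition matrix (two integers)
#' @slot voxelSize voxel edge lengths (mm, three values)
#' @exportClass AcquisitionProtocol
setClass("AcquisitionProtocol",
  representation(
    tr = "numeric", te = "numeric",
    flipDynamic = "numeric", flipT1map = "numeric",
    dt = "numeric", nDynamics = "integer",
    injectionStart = "numeric", sliceThickness = "numeric",
    matrixSize = "integer", voxelSize = "numeric"
  )
)

setValidity("AcquisitionProtocol", function(object) {
  msg <- character(0)
  if (length(object@tr) != 1 || object@tr <= 0) msg <- c(msg, "tr must be a single positive number (ms)")
  if (length(object@dt) != 1 || object@dt <= 0) msg <- c(msg, "dt must be a single positive number (s)")
  if (length(object@nDynamics) != 1 || object@nDynamics < 2L) msg <- c(msg, "nDynamics must be >= 2")
  if (!(object@flipT1map > 0 && object@flipT1map < object@flipDynamic && object@flipDynamic <= 90))
    msg <- c(msg, "flip angles must satisfy 0 < flipT1map < flipDynamic <= 90")
  if (object@injectionStart < 0) msg <- c(msg, "injectionStart must be >= 0")
  if (length(object@voxelSize) != 3 || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three positive lengths (mm)")
  if (length(msg)) msg else TRUE
})

#' Parametric population arterial input function
#'
#' A functional form for the plasma concentration curve used by the
#' synthetic module in place of manual carotid voxel selection. Two forms
#' are provided: `"biexponential"` (Weinmann-type decay, parameters `a1`,
#' `a2` in mM and `m1`, `m2` in 1/min) and `"parker"` (two-Gaussian bolus
#' plus sigmoid-gated exponential washout).
#'
#' @slot model model identifier, `"biexponential"` or `"parker"`
#' @slot parameters named list of scalars of the chosen form
#' @slot onset bolus arrival time (s); the curve is zero before it
#' @exportClass AIFModel
setClass("AIFModel",
  representation(model = "character", parameters = "list", onset = "numeric")
)

setValidity("AIFModel", function(object) {
  msg <- character(0)
  if (length(object@model) != 1) msg <- c(msg, "model must be a single string")
  if (length(object@onset) != 1 || object@onset < 0) msg <- c(msg, "onset must be a single nonnegative time (s)")
  if (length(object@parameters) && is.null(names(object@parameters)))
    msg <- c(msg, "parameters must be a named list")
  if (length(msg)) msg else TRUE
})

#' Sampled arterial input function
#'
#' Plasma gadolinium concentration versus time, i.e. the whole-blood
#' concentration divided by (1 - hematocrit).
#'
#' @slot tGrid sample times (s)
#' @slot cp plasma concentration (mM)
#' @slot hematocrit hematocrit fraction used for the plasma correction
#' @exportClass AIF
setClass("AIF",
  representation(tGrid = "numeric", cp = "numeric", hematocrit = "numeric")
)

setValidity("AIF", function(object) {
  msg <- character(0)
  if (length(object@tGrid) != length(object@cp)) msg <- c(msg, "tGrid and cp must have equal length")
  if (any(diff(object@tGrid) <= 0)) msg <- c(msg, "tGrid must be strictly increasing")
  if (any(object@cp < 0)) msg <- c(msg, "cp must be nonnegative")
  if (!(object@hematocrit >= 0 && object@hematocrit < 1)) msg <- c(msg, "hematocrit must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Gadolinium concentration time series
#'
#' One or more tissue concentration curves on a common time grid, with the
#' indices of the pre-contrast baseline frames and a per-curve validity
#' flag (curves whose SPGR inversion left the admissible range are marked
#' invalid rather than silently clipped).
#'
#' @slot tGrid sample times (s)
#' @slot conc concentration matrix (curves x time, mM)
#' @slot baselineIdx indices of the pre-injection frames
#' @slot valid logical, one flag per curve
#' @exportClass ConcentrationSeries
setClass("ConcentrationSeries",
  representation(tGrid = "numeric", conc = "matrix",
                 baselineIdx = "integer", valid = "logical")
)

setValidity("ConcentrationSeries", function(object) {
  msg <- character(0)
  if (ncol(object@conc) != length(object@tGrid)) msg <- c(msg, "conc must have one column per time point")
  if (length(object@baselineIdx) < 1) msg <- c(msg, "baselineIdx must be nonempty")
  if (any(object@baselineIdx < 1 | object@baselineIdx > length(object@tGrid)))
    msg <- c(msg, "baselineIdx out of range")
  if (length(object@valid) != nrow(object@conc)) msg <- c(msg, "valid must have one flag per curve")
  if (length(msg)) msg else TRUE
})

#' Pre-contrast T1 map
#'
#' Result of the dual-flip-angle relaxometry fit: longitudinal relaxation
#' time T1 and equilibrium signal scale M0 per voxel, with a mask of voxels
#' where the closed-form estimate was admissible.
#'
#' @slot t1 T1 (ms); NA where invalid
#' @slot m0 equilibrium signal scale; NA where invalid
#' @slot validMask logical array, TRUE where estimation succeeded
#' @exportClass T1Map
setClass("T1Map",
  representation(t1 = "array", m0 = "array", validMask = "array")
)

setValidity("T1Map", function(object) {
  msg <- character(0)
  if (!identical(dim(object@t1), dim(object@m0)) ||
      !identical(dim(object@t1), dim(object@validMask)))
    msg <- c(msg, "t1, m0 and validMask must share dimensions")
  ok <- object@validMask
  if (any(ok) && (any(!is.finite(object@t1[ok])) || any(object@t1[ok] <= 0)))
    msg <- c(msg, "t1 must be positive and finite on validMask")
  if (any(ok) && (any(!is.finite(object@m0[ok])) || any(object@m0[ok] <= 0)))
    msg <- c(msg, "m0 must be positive and finite on validMask")
  if (length(msg)) msg else TRUE
})

#' Voxel-wise Tofts parameter maps
#'
#' Fitted Ktrans, kep, derived ve = Ktrans/kep, goodness of fit R^2 and
#' AUGC per voxel, plus the mask of voxels retained for downstream ROI
#' statistics (converged fits with R^2 at or above the threshold).
#'
#' @slot ktrans volume transfer constant (1/min)
#' @slot kep efflux rate constant (1/min)
#' @slot ve extracellular extravascular volume fraction
#' @slot r2 goodness of fit of the voxel fit
#' @slot augc area under the gadolinium concentration curve (mM min)
#' @slot mask voxels that were submitted to fitting
#' @slot validMask voxels passing convergence and the R^2 filter
#' @slot r2Threshold the goodness-of-fit threshold applied
#' @exportClass ParameterMaps
setClass("ParameterMaps",
  representation(ktrans = "array", kep = "array", ve = "array",
                 r2 = "array", augc = "array",
                 mask = "array", validMask = "array",
                 r2Threshold = "numeric")
)

setValidity("ParameterMaps", function(object) {
  d <- dim(object@ktrans)
  same <- vapply(list(object@kep, object@ve, object@r2, object@augc,
                      object@mask, object@validMask),
                 function(a) identical(dim(a), d), logical(1))
  msg <- character(0)
  if (!all(same)) msg <- c(msg, "all maps and masks must share dimensions")
  if (!(object@r2Threshold >= 0 && object@r2Threshold <= 1))
    msg <- c(msg, "r2Threshold must lie in [0, 1]")
  if (any(object@validMask & !object@mask)) msg <- c(msg, "validMask must be a subset of mask")
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic DCE phantom
#'
#' Geometry, ground-truth kinetics and noise level of a digital phantom.
#' Each tissue region carries a mask plus true Ktrans, kep (1/min), T1 (ms)
#' and M0; the artery region carries blood T1/M0 and is driven directly by
#' the (hematocrit-scaled) AIF.
#'
#' @slot gridShape 3D voxel grid dimensions
#' @slot regions list of tissue regions; each a list with elements
#'   `name`, `mask` (logical array), `ktrans`, `kep`, `t1`, `m0`
#' @slot artery list with elements `mask`, `t1`, `m0`
#' @slot background list with elements `t1`, `m0` for unlabelled voxels
#' @slot noiseSigma standard deviation of additive Gaussian magnitude noise
#' @slot seed RNG seed for the noise draw
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(gridShape = "integer", regions = "list", artery = "list",
                 background = "list", noiseSigma = "numeric", seed = "numeric")
)

setValidity("PhantomSpec", function(object) {
  msg <- character(0)
  if (length(object@gridShape) != 3 || any(object@gridShape < 1))
    msg <- c(msg, "gridShape must be three positive integers")
  masks <- c(lapply(object@regions, `[[`, "mask"), list(object@artery$mask))
  masks <- Filter(Negate(is.null), masks)
  for (m in masks) {
    if (!identical(dim(m), as.integer(object@gridShape)))
      msg <- c(msg, "all masks must match gridShape")
  }
  if (length(masks) > 1) {
    tot <- Reduce(`+`, lapply(masks, function(m) m * 1L))
    if (any(tot > 1L)) msg <- c(msg, "region and artery masks must be disjoint")
  }
  for (r in object@regions) {
    if (!all(c("mask", "ktrans", "kep", "t1", "m0") %in% names(r)))
      msg <- c(msg, "each region needs mask, ktrans, kep, t1, m0")
    else if (r$ktrans <= 0 || r$kep <= 0 || r$t1 <= 0 || r$m0 <= 0)
      msg <- c(msg, "region ktrans, kep, t1, m0 must be positive")
  }
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Synthetic 4D DCE phantom
#'
#' A generated dynamic series together with everything a pipeline run or a
#' validation study needs: the noiseless series, the low-flip-angle
#' pre-contrast volume for T1 mapping, region masks, ground-truth parameter
#' maps and the protocol/AIF that produced it.
#'
#' @slot series 4D magnitude series (x, y, z, t), with noise
#' @slot cleanSeries the same series without noise
#' @slot lowFlip 3D pre-contrast volume at the low flip angle, with noise
#' @slot cleanLowFlip its noiseless counterpart
#' @slot masks named list of logical arrays (tissue regions plus `artery`)
#' @slot truth named list of ground-truth maps (`ktrans`, `kep`, `ve`,
#'   `t1`, `m0`; NA outside the tissue regions)
#' @slot protocol the [AcquisitionProtocol-class] used
#' @slot aifModel the [AIFModel-class] used
#' @slot hematocrit hematocrit fraction applied to the artery signal
#' @exportClass DCEPhantom
setClass("DCEPhantom",
  representation(series = "array", cleanSeries = "array",
                 lowFlip = "array", cleanLowFlip = "array",
                 masks = "list", truth = "list",
                 protocol = "AcquisitionProtocol", aifModel = "AIFModel",
                 hematocrit = "numeric")
)

#' Specification of a simulated per-site cohort
#'
#' Group sizes and per-parameter normal moments for the two outcome groups
#' (site failure, SF, and site control, SC) from which [generateCohort()]
#' draws a table of simulated tumour sites.
#'
#' @slot nSF number of site-failure sites
#' @slot nSC number of site-control sites
#' @slot moments data.frame with columns `parameter`, `sf_mean`, `sf_sd`,
#'   `sc_mean`, `sc_sd`
#' @slot seed RNG seed (NA for none)
#' @slot pPrimary proportion of sites labelled `primary` (the rest `nodal`)
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(nSF = "integer", nSC = "integer", moments = "data.frame",
                 seed = "numeric", pPrimary = "numeric")
)

setValidity("CohortSpec", function(object) {
  msg <- character(0)
  if (object@nSF < 1L || object@nSC < 1L) msg <- c(msg, "group sizes must be positive")
  need <- c("parameter", "sf_mean", "sf_sd", "sc_mean", "sc_sd")
  if (!all(need %in% names(object@moments)))
    msg <- c(msg, paste("moments must have columns:", paste(need, collapse = ", ")))
  else if (any(object@moments$sf_sd < 0) || any(object@moments$sc_sd < 0))
    msg <- c(msg, "SDs must be >= 0")
  if (!(object@pPrimary >= 0 && object@pPrimary <= 1)) msg <- c(msg, "pPrimary must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
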