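#' Construct a parametric population AIF
#'
#' Two functional forms are available. `"biexponential"` is the classic
#' Weinmann-type population curve: for t >= onset,
#' \deqn{C_p(t) = a_1 e^{-m_1 (t-onset)} + a_2 e^{-m_2 (t-onset)}}
#' with amplitudes in mM and rates in 1/min; the default parameters are
#' the standard population values scaled to a 0.1 mmol/kg dose
#' (a1 = 0.399, a2 = 0.478 mM; m1 = 0.144, m2 = 0.0111 /min).
#' `"parker"` is the population mixture of two Gaussian boluses plus a
#' sigmoid-gated exponential washout; its parameters (`A1`, `A2` mM min,
#' `T1`, `T2`, `sigma1`, `sigma2`, `tau` min, `alpha` mM, `beta`, `s`
#' 1/min) default to the published population means.
#'
#' @param model `"biexponential"` or `"parker"`
#' @param parameters named list overriding any default parameter
#' @param onset bolus arrival time (s)
#' @return an [AIFModel-class]
#' @examples
#' aif <- AIFModel(onset = 6)
#' evaluateAIF(aif, t = seq(0, 460, by = 2.59))[1:5]
#' @export
AIFModel <- function(model = c("biexponential", "parker"),
                     parameters = list(), onset = 6) {
  model <- match.arg(model)
  defaults <- switch(model,
    biexponential = list(a1 = 0.399, a2 = 0.478, m1 = 0.144, m2 = 0.0111),
    parker = list(A1 = 0.809, A2 = 0.330, T1 = 0.17046, T2 = 0.365,
                  sigma1 = 0.0563, sigma2 = 0.132,
                  alpha = 1.050, beta = 0.1685, s = 38.078, tau = 0.483)
  )
  unknown <- setdiff(names(parameters), names(defaults))
  if (length(unknown))
    stop("unknown parameter(s) for model '", model, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  defaults[names(parameters)] <- parameters
  new("AIFModel", model = model, parameters = defaults, onset = onset)
}

#' Evaluate a parametric AIF on a time grid
#'
#' @param params an [AIFModel-class]
#' @param t time grid (s), strictly increasing
#' @return plasma concentration (mM) at each time; zero before the onset
#' @export
evaluateAIF <- function(params, t) {
  stopIfNot(is(params, "AIFModel"), "params must be an AIFModel")
  stopIfNot(all(diff(t) > 0), "t must be strictly increasing")
  tm <- (t - params@onset) / 60  # minutes since bolus arrival
  p <- params@parameters
  cp <- switch(params@model,
    biexponential = p$a1 * exp(-p$m1 * pmax(tm, 0)) +
                    p$a2 * exp(-p$m2 * pmax(tm, 0)),
    parker = {
      g <- function(A, T0, sig) A / (sig * sqrt(2 * pi)) *
        exp(-(tm - T0)^2 / (2 * sig^2))
      g(p$A1, p$T1, p$sigma1) + g(p$A2, p$T2, p$sigma2) +
        p$alpha * exp(-p$beta * pmax(tm, 0)) / (1 + exp(-p$s * (tm - p$tau)))
    },
    stop("unknown AIF model: ", params@model, call. = FALSE)
  )
  cp[tm < 0] <- 0
  pmax(cp, 0)
}

#' Construct a sampled AIF
#'
#' @param tGrid sample times (s)
#' @param cp plasma concentration (mM)
#' @param hematocrit hematocrit fraction recorded with the curve
#' @return an [AIF-class]
#' @export
AIF <- function(tGrid, cp, hematocrit = 0.42) {
  new("AIF", tGrid = tGrid, cp = cp, hematocrit = hematocrit)
}

setMethod("show", "AIF", function(object) {
  cat("AIF: ", length(object@cp), " samples over ",
      round(max(object@tGrid), 1), " s; peak ",
      signif(max(object@cp), 4), " mM; hematocrit ",
      object@hematocrit, "\n", sep = "")
})

#' Extract an AIF from arterial voxels of a dynamic series
#'
#' Converts the signal of every artery voxel to whole-blood gadolinium
#' concentration (SPGR inversion against the blood T1), averages the valid
#' voxel curves, and divides by (1 - hematocrit) to obtain the plasma
#' concentration. Small negative excursions from noise are clipped to
#' zero.
#'
#' @param series 4D magnitude array (x, y, z, t)
#' @param arteryMask 3D logical array selecting artery voxels
#' @param t1Blood blood T1 (ms) used for the conversion
#' @param protocol an [AcquisitionProtocol-class]
#' @param r1 contrast agent longitudinal relaxivity (1/s/mM)
#' @param hematocrit hematocrit fraction; plasma = blood / (1 - Hct)
#' @return an [AIF-class] on the frame-time grid of the protocol
#' @export
extractAIF <- function(series, arteryMask, t1Blood, protocol,
                       r1 = 4.5, hematocrit = 0.42) {
  stopIfNot(sum(arteryMask) > 0, "artery mask must select at least one voxel")
  stopIfNot(hematocrit >= 0 && hematocrit < 1, "hematocrit must lie in [0, 1)")
  sig <- seriesToMatrix(series, arteryMask)
  cs <- signalToConcentration(sig, t10 = t1Blood, protocol = protocol, r1 = r1)
  if (!any(cs@valid)) stop("no artery voxel admitted a valid SPGR inversion", call. = FALSE)
  cb <- colMeans(cs@conc[cs@valid, , drop = FALSE])
  cp <- pmax(cb, 0) / (1 - hematocrit)
  AIF(tGrid = cs@tGrid, cp = cp, hematocrit = hematocrit)
}

# flatten the voxels selected by mask into a (voxel x time) matrix
seriesToMatrix <- function(series, mask) {
  d <- dim(series)
  stopIfNot(length(d) == 4, "series must be a 4D array")
  stopIfNot(identical(dim(mask), d[1:3]), "mask must match the series grid")
  nt <- d[4]
  flat <- matrix(series, nrow = prod(d[1:3]), ncol = nt)
  flat[as.vector(mask), , drop = FALSE]
}
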