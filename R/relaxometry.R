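#' Spoiled gradient echo signal equation
#'
#' Steady-state SPGR magnitude signal
#' \deqn{S = M_0 \sin\alpha \frac{1 - E_1}{1 - E_1\cos\alpha},
#'       \quad E_1 = e^{-TR/T_1}.}
#' Vectorized over all arguments.
#'
#' @param m0 equilibrium signal scale
#' @param t1 longitudinal relaxation time (ms), positive
#' @param alpha flip angle (degrees), in (0, 90]
#' @param tr repetition time (ms), positive
#' @return the magnitude signal
#' @examples
#' spgrSignal(1000, 1000, 15, 4)
#' @export
spgrSignal <- function(m0, t1, alpha, tr) {
  stopIfNot(all(t1 > 0), "t1 must be positive")
  stopIfNot(all(tr > 0), "tr must be positive")
  stopIfNot(all(alpha > 0 & alpha <= 90), "alpha must lie in (0, 90] degrees")
  a <- deg2rad(alpha)
  e1 <- exp(-tr / t1)
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' Dual-flip-angle T1 estimation
#'
#' Closed-form variable-flip-angle fit from exactly two SPGR signals.
#' With the linearization y = S/sin(alpha) against x = S/tan(alpha), the
#' line through the two points has slope E1 = exp(-TR/T1) and intercept
#' M0 (1 - E1), so T1 = -TR / log(E1). Voxels whose slope falls outside
#' (0, 1), or whose T1 leaves the plausibility window, are flagged invalid
#' rather than raising an error.
#'
#' @param sLow signal at the low flip angle (`flipT1map`); scalar, vector
#'   or array
#' @param sHigh signal at the high flip angle (`flipDynamic`), same shape
#' @param protocol an [AcquisitionProtocol-class] providing TR and the two
#'   flip angles
#' @param t1Bounds plausibility window for T1 (ms); estimates outside are
#'   marked invalid
#' @return a [T1Map-class] with `t1`, `m0` and `validMask` shaped like the
#'   input
#' @examples
#' p <- AcquisitionProtocol()
#' s2 <- spgrSignal(900, 800, 2, 4); s15 <- spgrSignal(900, 800, 15, 4)
#' fitT1DualFlip(s2, s15, p)
#' @export
fitT1DualFlip <- function(sLow, sHigh, protocol, t1Bounds = c(50, 5000)) {
  stopIfNot(identical(dim(sLow), dim(sHigh)) && length(sLow) == length(sHigh),
            "sLow and sHigh must have identical shape")
  dims <- if (is.null(dim(sLow))) length(sLow) else dim(sLow)
  aL <- deg2rad(protocol@flipT1map)
  aH <- deg2rad(protocol@flipDynamic)
  xL <- sLow / tan(aL);  yL <- sLow / sin(aL)
  xH <- sHigh / tan(aH); yH <- sHigh / sin(aH)
  e1 <- (yH - yL) / (xH - xL)
  t1 <- -protocol@tr / log(e1)
  m0 <- (yH - e1 * xH) / (1 - e1)
  valid <- is.finite(e1) & e1 > 0 & e1 < 1 &
    sLow > 0 & sHigh > 0 &
    is.finite(t1) & t1 >= t1Bounds[1] & t1 <= t1Bounds[2] &
    is.finite(m0) & m0 > 0
  t1[!valid] <- NA_real_
  m0[!valid] <- NA_real_
  new("T1Map",
      t1 = array(t1, dim = dims),
      m0 = array(m0, dim = dims),
      validMask = array(valid, dim = dims))
}

#' @describeIn fitT1DualFlip number of valid voxels
#' @param object a `T1Map`
#' @export
setGeneric("validFraction", function(object) standardGeneric("validFraction"))

#' @rdname fitT1DualFlip
#' @export
setMethod("validFraction", "T1Map", function(object) mean(object@validMask))

setMethod("show", "T1Map", function(object) {
  ok <- object@validMask
  cat("T1Map: ", length(ok), " voxels, ", sum(ok), " valid (",
      round(100 * mean(ok), 1), "%)\n", sep = "")
  if (any(ok))
    cat("  T1 median ", round(stats::median(object@t1[ok]), 1), " ms [",
        round(min(object@t1[ok]), 1), ", ", round(max(object@t1[ok]), 1),
        "]\n", sep = "")
})
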