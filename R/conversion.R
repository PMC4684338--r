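#' Synthesize a dynamic SPGR magnitude signal from a concentration curve
#'
#' The gadolinium concentration modulates the longitudinal relaxation rate
#' R1(t) = 1/T10 + r1 C(t); the SPGR equation at the dynamic flip angle
#' turns R1(t) into magnitude signal. Additive Gaussian noise with the
#' given standard deviation is drawn reproducibly from `seed` without
#' disturbing the caller's RNG stream.
#'
#' @param ct tissue concentration curve (mM), one value per dynamic
#' @param t10 pre-contrast T1 (ms)
#' @param m0 equilibrium signal scale
#' @param protocol an [AcquisitionProtocol-class]
#' @param noiseSigma standard deviation of the additive magnitude noise
#' @param seed RNG seed for the noise draw (NULL: use the global stream)
#' @param r1 contrast relaxivity (1/s/mM)
#' @return magnitude signal vector, same length as `ct`
#' @examples
#' p <- AcquisitionProtocol(nDynamics = 20)
#' synthesizeSignal(rep(0, 20), t10 = 1000, m0 = 500, protocol = p)
#' @export
synthesizeSignal <- function(ct, t10, m0, protocol, noiseSigma = 0,
                             seed = NULL, r1 = 4.5) {
  stopIfNot(all(t10 > 0), "t10 must be positive")
  stopIfNot(all(ct >= 0), "ct must be nonnegative")
  r1ms <- r1 / 1000                      # 1/ms/mM; T1, TR are in ms
  R1 <- 1 / t10 + r1ms * ct              # 1/ms
  e1 <- exp(-protocol@tr * R1)
  a <- deg2rad(protocol@flipDynamic)
  s <- m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
  if (noiseSigma > 0)
    s <- s + withSeed(seed, stats::rnorm(length(s), sd = noiseSigma))
  s
}

#' Convert dynamic signal to gadolinium concentration
#'
#' Inverts the SPGR equation at the dynamic flip angle. The equilibrium
#' scale M0 of each curve is calibrated from its pre-injection baseline
#' frames together with the pre-contrast T1, so that the baseline maps to
#' concentration ~ 0 by construction. Curves whose signal implies
#' E1 outside (0, 1) anywhere (e.g. signal above the SPGR ceiling
#' M0 sin(alpha)) are marked invalid.
#'
#' Concentration is obtained as C(t) = (R1(t) - 1/T10) / r1 with
#' R1(t) = -log(E1(t)) / TR.
#'
#' @param signal magnitude signal: a vector (one curve) or a matrix
#'   (curves x time)
#' @param t10 pre-contrast T1 (ms), scalar or one value per curve;
#'   alternatively pass `t1map`
#' @param protocol an [AcquisitionProtocol-class]
#' @param r1 contrast relaxivity (1/s/mM)
#' @param t1map optional [T1Map-class]; its valid voxels supply `t10`
#'   (curves at invalid voxels are marked invalid)
#' @param baselineIdx indices of the pre-injection frames; defaults to
#'   [baselineIndices()] of the protocol
#' @return a [ConcentrationSeries-class]
#' @export
signalToConcentration <- function(signal, t10 = NULL, protocol,
                                  r1 = 4.5, t1map = NULL,
                                  baselineIdx = baselineIndices(protocol)) {
  if (is.null(dim(signal))) signal <- matrix(signal, nrow = 1)
  nt <- ncol(signal)
  stopIfNot(nt == protocol@nDynamics,
            "signal must have one column per dynamic of the protocol")
  preValid <- rep(TRUE, nrow(signal))
  if (!is.null(t1map)) {
    stopIfNot(is(t1map, "T1Map"), "t1map must be a T1Map")
    stopIfNot(length(t1map@t1) == nrow(signal),
              "t1map must supply one voxel per signal curve")
    t10 <- as.vector(t1map@t1)
    preValid <- as.vector(t1map@validMask)
    t10[!preValid] <- 1000  # placeholder; curve flagged invalid anyway
  }
  stopIfNot(!is.null(t10), "supply t10 or t1map")
  t10 <- rep_len(t10, nrow(signal))

  a <- deg2rad(protocol@flipDynamic)
  r1ms <- r1 / 1000
  s0 <- rowMeans(signal[, baselineIdx, drop = FALSE])
  e10 <- exp(-protocol@tr / t10)
  f10 <- sin(a) * (1 - e10) / (1 - e10 * cos(a))
  m0 <- s0 / f10

  ms <- m0 * sin(a)
  # E1 = (M0 sin a - S) / (M0 sin a - S cos a)
  e1 <- (ms - signal) / (ms - signal * cos(a))
  ok <- is.finite(e1) & e1 > 0 & e1 < 1
  valid <- preValid & (rowSums(!ok) == 0) & is.finite(m0) & m0 > 0 & s0 > 0
  e1[!ok] <- NA_real_
  R1 <- -log(e1) / protocol@tr           # 1/ms
  conc <- (R1 - 1 / t10) / r1ms
  conc[!valid, ] <- NA_real_
  new("ConcentrationSeries",
      tGrid = frameTimes(protocol), conc = conc,
      baselineIdx = as.integer(baselineIdx), valid = valid)
}

setMethod("show", "ConcentrationSeries", function(object) {
  cat("ConcentrationSeries: ", nrow(object@conc), " curve(s) × ",
      ncol(object@conc), " frames; ", sum(object@valid), " valid; ",
      length(object@baselineIdx), " baseline frames\n", sep = "")
})

#' Concentration series accessors
#'
#' @param object a [ConcentrationSeries-class]
#' @return `concMatrix`: the (curves x time) concentration matrix;
#'   `timeGrid`: the sample times in seconds.
#' @name concentration-accessors
NULL

#' @rdname concentration-accessors
#' @export
setGeneric("concMatrix", function(object) standardGeneric("concMatrix"))

#' @rdname concentration-accessors
#' @export
setMethod("concMatrix", "ConcentrationSeries", function(object) object@conc)

#' @rdname concentration-accessors
#' @export
setGeneric("timeGrid", function(object) standardGeneric("timeGrid"))

#' @rdname concentration-accessors
#' @export
setMethod("timeGrid", "ConcentrationSeries", function(object) object@tGrid)

#' @rdname concentration-accessors
#' @export
setMethod("timeGrid", "AIF", function(object) object@tGrid)

#' @rdname concentration-accessors
#' @export
setGeneric("plasmaCurve", function(object) standardGeneric("plasmaCurve"))

#' @rdname concentration-accessors
#' @export
setMethod("plasmaCurve", "AIF", function(object) object@cp)
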