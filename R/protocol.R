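#' Construct an acquisition protocol
#'
#' The defaults reproduce the 3T head-and-neck dynamic SPGR protocol that
#' motivates the package: TR 4.0 ms, dynamic flip angle 15 degrees with a
#' 2 degree pre-contrast acquisition for T1 mapping, 2.59 s per dynamic,
#' 185 dynamics, and the contrast injection commanded 6 s after the start
#' of the dynamic run.
#'
#' @param tr repetition time (ms)
#' @param te echo time (ms)
#' @param flipDynamic dynamic-series flip angle (degrees)
#' @param flipT1map low flip angle for T1 mapping (degrees)
#' @param dt temporal resolution (s per dynamic)
#' @param nDynamics number of dynamic frames
#' @param injectionStart injection command time after acquisition start (s)
#' @param sliceThickness slice thickness (mm)
#' @param matrixSize in-plane matrix (two integers)
#' @param voxelSize voxel edge lengths (mm, three values)
#' @return an [AcquisitionProtocol-class] object
#' @examples
#' p <- AcquisitionProtocol()
#' scanDuration(p)      # dt * nDynamics, seconds
#' baselineIndices(p)   # the fully pre-injection dynamics
#' @export
AcquisitionProtocol <- function(tr = 4.0, te = 1.0,
                                flipDynamic = 15, flipT1map = 2,
                                dt = 2.59, nDynamics = 185L,
                                injectionStart = 6,
                                sliceThickness = 4,
                                matrixSize = c(128L, 128L),
                                voxelSize = c(1.72, 1.72, 4)) {
  new("AcquisitionProtocol",
      tr = tr, te = te, flipDynamic = flipDynamic, flipT1map = flipT1map,
      dt = dt, nDynamics = as.integer(nDynamics),
      injectionStart = injectionStart, sliceThickness = sliceThickness,
      matrixSize = as.integer(matrixSize), voxelSize = voxelSize)
}

#' @rdname AcquisitionProtocol
#' @export
defaultProtocol <- function() AcquisitionProtocol()

#' Protocol accessors
#'
#' Derived quantities of an [AcquisitionProtocol-class]: the acquisition
#' times of the dynamic frames (start of each readout, seconds), the total
#' scan duration `dt * nDynamics`, and the indices of the baseline frames
#' (dynamics wholly completed before the injection command; at the default
#' protocol `floor(6 / 2.59) = 2` frames).
#'
#' @param object an `AcquisitionProtocol`
#' @return `frameTimes`: numeric vector of length `nDynamics`;
#'   `scanDuration`: scalar seconds; `baselineIndices`: integer vector.
#' @name protocol-accessors
NULL

#' @rdname protocol-accessors
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))

#' @rdname protocol-accessors
#' @export
setMethod("frameTimes", "AcquisitionProtocol", function(object) {
  (seq_len(object@nDynamics) - 1) * object@dt
})

#' @rdname protocol-accessors
#' @export
setGeneric("scanDuration", function(object) standardGeneric("scanDuration"))

#' @rdname protocol-accessors
#' @export
setMethod("scanDuration", "AcquisitionProtocol", function(object) {
  object@dt * object@nDynamics
})

#' @rdname protocol-accessors
#' @export
setGeneric("baselineIndices", function(object) standardGeneric("baselineIndices"))

#' @rdname protocol-accessors
#' @export
setMethod("baselineIndices", "AcquisitionProtocol", function(object) {
  n <- max(1L, min(object@nDynamics, as.integer(floor(object@injectionStart / object@dt))))
  seq_len(n)
})

setMethod("show", "AcquisitionProtocol", function(object) {
  cat("AcquisitionProtocol\n",
      "  TR ", object@tr, " ms, TE ", object@te, " ms, flips ",
      object@flipT1map, "°/", object@flipDynamic, "°\n",
      "  ", object@nDynamics, " dynamics × ", object@dt, " s = ",
      round(scanDuration(object), 2), " s; injection at ",
      object@injectionStart, " s (", length(baselineIndices(object)),
      " baseline frames)\n",
      "  voxel ", paste(object@voxelSize, collapse = " × "), " mm\n",
      sep = "")
})
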