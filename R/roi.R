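#' ROI mean of a parameter map
#'
#' Arithmetic mean over the voxels of `mask` that also pass the validity
#' filter (converged fit with sufficient goodness of fit). Sites whose
#' valid-voxel count falls below `minVoxels` are unanalyzable — the ROI
#' counterpart of residual masses too small or necrotic to evaluate — and
#' yield `NA` with a warning.
#'
#' @param map 3D parameter map
#' @param mask 3D logical ROI mask
#' @param valid optional 3D logical validity mask; default: all voxels
#' @param minVoxels minimum number of valid voxels for an analyzable ROI
#' @return the ROI mean, or `NA` if unanalyzable
#' @export
roiMean <- function(map, mask, valid = NULL, minVoxels = 5) {
  stopIfNot(identical(dim(map), dim(mask)), "map and mask must share dimensions")
  sel <- mask
  if (!is.null(valid)) {
    stopIfNot(identical(dim(valid), dim(mask)), "valid mask must share dimensions")
    sel <- sel & valid
  }
  if (sum(sel) < minVoxels) {
    warning("ROI unanalyzable: ", sum(sel), " valid voxel(s) < ", minVoxels)
    return(NA_real_)
  }
  mean(map[sel])
}

#' ROI volume
#'
#' @param mask 3D logical ROI mask, nonempty
#' @param voxelSize voxel edge lengths (mm, three values)
#' @return volume in cm^3
#' @examples
#' roiVolume(array(TRUE, c(10, 10, 10)), c(1, 1, 1))  # 1 cm^3
#' @export
roiVolume <- function(mask, voxelSize) {
  stopIfNot(sum(mask) > 0, "mask must contain at least one voxel")
  stopIfNot(length(voxelSize) == 3 && all(voxelSize > 0),
            "voxelSize must be three positive lengths (mm)")
  sum(mask) * prod(voxelSize) / 1000
}

#' Percent change from pre- to post-treatment
#'
#' `100 * (post - pre) / pre`; scale-invariant in the common factor of
#' pre and post. A zero pre-treatment value leaves the change undefined
#' (`NA`, with a warning).
#'
#' @param pre,post parameter values (vectorized)
#' @return percent change
#' @examples
#' percentChange(2.36, 0.96)   # -59.3 % drop in AUGC
#' @export
percentChange <- function(pre, post) {
  out <- ifelse(pre == 0, NA_real_, 100 * (post - pre) / pre)
  if (any(pre == 0)) warning("percent change undefined where pre == 0")
  out
}

#' Per-site ROI summary
#'
#' Means of Ktrans, kep, ve and AUGC over the R2-passing voxels of the
#' site mask, plus the site volume, assembled into one row.
#'
#' @param maps a [ParameterMaps-class]
#' @param mask 3D logical site mask
#' @param voxelSize voxel edge lengths (mm)
#' @param siteId identifier carried into the row
#' @param minVoxels minimum valid voxels for an analyzable site
#' @return one-row data.frame with `site_id`, parameter means, `volume`,
#'   `n_valid` and `analyzable`
#' @export
siteSummary <- function(maps, mask, voxelSize, siteId = "site001",
                        minVoxels = 5) {
  ok <- validMask(maps)
  nValid <- sum(mask & ok)
  analyzable <- nValid >= minVoxels
  get <- function(nm) if (analyzable) mean(parameterMap(maps, nm)[mask & ok]) else NA_real_
  data.frame(site_id = siteId,
             ktrans = get("ktrans"), kep = get("kep"), ve = get("ve"),
             augc = get("augc"),
             volume = roiVolume(mask, voxelSize),
             n_valid = nValid, analyzable = analyzable,
             stringsAsFactors = FALSE)
}
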