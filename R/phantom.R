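#' Construct a phantom specification
#'
#' @param gridShape 3D voxel grid dimensions
#' @param regions list of tissue regions, each a list with `name`,
#'   `mask` (3D logical), `ktrans`, `kep` (1/min), `t1` (ms), `m0`
#' @param artery list with `mask`, `t1`, `m0` for the arterial voxels
#' @param background list with `t1`, `m0` for unlabelled voxels
#' @param noiseSigma SD of additive Gaussian magnitude noise
#' @param seed RNG seed for the noise draw (NA: global stream)
#' @return a [PhantomSpec-class]
#' @export
PhantomSpec <- function(gridShape, regions, artery,
                        background = list(t1 = 800, m0 = 600),
                        noiseSigma = 0, seed = NA_real_) {
  for (r in regions) {
    if (!is.null(r$ktrans) && !is.null(r$kep) && r$ktrans / r$kep > 1)
      warning("region '", r$name, "' has ve = ktrans/kep > 1 (physically implausible)")
  }
  new("PhantomSpec", gridShape = as.integer(gridShape), regions = regions,
      artery = artery, background = background,
      noiseSigma = noiseSigma, seed = as.numeric(seed))
}

#' Default two-region phantom specification
#'
#' A small grid holding a tumour-like region (Ktrans 0.37/min, kep
#' 0.67/min, T1 1400 ms — typical head-and-neck SCC values), a muscle-like
#' region (Ktrans 0.10/min, kep 0.50/min, T1 1000 ms) and an arterial
#' column (blood T1 1650 ms at 3T).
#'
#' @param shape 3D grid dimensions
#' @param noiseSigma SD of additive Gaussian magnitude noise
#' @param seed RNG seed
#' @return a [PhantomSpec-class]
#' @export
defaultPhantomSpec <- function(shape = c(12L, 12L, 4L), noiseSigma = 0,
                               seed = NA_real_) {
  shape <- as.integer(shape)
  blank <- array(FALSE, shape)
  tumor <- blank; tumor[2:6, 2:11, ] <- TRUE
  muscle <- blank; muscle[8:11, 2:6, ] <- TRUE
  artery <- blank; artery[8:9, 9:10, ] <- TRUE
  PhantomSpec(
    gridShape = shape,
    regions = list(
      list(name = "tumor", mask = tumor, ktrans = 0.37, kep = 0.67,
           t1 = 1400, m0 = 1000),
      list(name = "muscle", mask = muscle, ktrans = 0.10, kep = 0.50,
           t1 = 1000, m0 = 1000)),
    artery = list(mask = artery, t1 = 1650, m0 = 1000),
    noiseSigma = noiseSigma, seed = seed)
}

#' Generate a 4D DCE phantom
#'
#' Builds a dynamic SPGR magnitude series whose tissue voxels follow Tofts
#' kinetics driven by the parametric AIF, whose arterial voxels carry the
#' whole-blood signal C_b = C_p (1 - Hct), and whose low-flip pre-contrast
#' volume supports dual-angle T1 mapping. The noiseless series and the
#' ground-truth parameter maps are returned alongside the noisy data.
#'
#' @param spec a [PhantomSpec-class]
#' @param protocol an [AcquisitionProtocol-class]
#' @param aif an [AIFModel-class]; its onset defaults to the protocol's
#'   injection start
#' @param hematocrit hematocrit fraction relating plasma to blood
#'   concentration
#' @return a [DCEPhantom-class]
#' @examples
#' ph <- generatePhantom(defaultPhantomSpec(noiseSigma = 2, seed = 7),
#'                       AcquisitionProtocol(nDynamics = 60L))
#' @export
generatePhantom <- function(spec, protocol = defaultProtocol(),
                            aif = AIFModel(onset = protocol@injectionStart),
                            hematocrit = 0.42) {
  validObject(spec)
  shape <- spec@gridShape
  tGrid <- frameTimes(protocol)
  nt <- protocol@nDynamics
  cp <- evaluateAIF(aif, tGrid)

  t1map <- array(spec@background$t1, shape)
  m0map <- array(spec@background$m0, shape)
  ktMap <- array(NA_real_, shape); keMap <- ktMap; veMap <- ktMap

  curves <- list()  # per-label noiseless signal curve
  label <- array("background", shape)
  for (r in spec@regions) {
    label[r$mask] <- r$name
    t1map[r$mask] <- r$t1; m0map[r$mask] <- r$m0
    ktMap[r$mask] <- r$ktrans; keMap[r$mask] <- r$kep
    veMap[r$mask] <- r$ktrans / r$kep
    ct <- toftsForward(r$ktrans, r$kep, cp, tGrid)
    curves[[r$name]] <- synthesizeSignal(ct, r$t1, r$m0, protocol, 0)
  }
  if (!is.null(spec@artery$mask)) {
    label[spec@artery$mask] <- "artery"
    t1map[spec@artery$mask] <- spec@artery$t1
    m0map[spec@artery$mask] <- spec@artery$m0
    cb <- cp * (1 - hematocrit)
    curves[["artery"]] <- synthesizeSignal(cb, spec@artery$t1,
                                           spec@artery$m0, protocol, 0)
  }
  curves[["background"]] <- synthesizeSignal(rep(0, nt), spec@background$t1,
                                             spec@background$m0, protocol, 0)

  clean <- array(0, c(shape, nt))
  flat <- matrix(0, prod(shape), nt)
  lab <- as.vector(label)
  for (nm in names(curves)) {
    sel <- lab == nm
    if (any(sel)) flat[sel, ] <- matrix(curves[[nm]], sum(sel), nt, byrow = TRUE)
  }
  clean <- array(flat, c(shape, nt))
  cleanLow <- array(spgrSignal(m0map, t1map, protocol@flipT1map, protocol@tr),
                    shape)

  series <- clean; lowFlip <- cleanLow
  if (spec@noiseSigma > 0) {
    noise <- withSeed(spec@seed,
                      stats::rnorm(length(clean) + length(cleanLow),
                                   sd = spec@noiseSigma))
    series <- clean + array(noise[seq_along(clean)], dim(clean))
    lowFlip <- cleanLow + array(noise[length(clean) + seq_along(cleanLow)],
                                dim(cleanLow))
  }

  masks <- lapply(spec@regions, `[[`, "mask")
  names(masks) <- vapply(spec@regions, `[[`, character(1), "name")
  masks$artery <- spec@artery$mask

  new("DCEPhantom",
      series = series, cleanSeries = clean,
      lowFlip = lowFlip, cleanLowFlip = cleanLow,
      masks = masks,
      truth = list(ktrans = ktMap, kep = keMap, ve = veMap,
                   t1 = t1map, m0 = m0map),
      protocol = protocol, aifModel = aif, hematocrit = hematocrit)
}

setMethod("show", "DCEPhantom", function(object) {
  d <- dim(object@series)
  cat("DCEPhantom: ", paste(d[1:3], collapse = "x"), " grid, ", d[4],
      " dynamics; regions: ",
      paste(names(object@masks), collapse = ", "), "\n", sep = "")
})

#' Write a phantom to disk
#'
#' Writes the dynamic series, low-flip volume, masks (uint8) and
#' ground-truth maps (float32) as NIfTI-1, plus a YAML sidecar with the
#' protocol, AIF model and hematocrit.
#'
#' @param phantom a [DCEPhantom-class]
#' @param dir output directory (created if needed)
#' @return invisibly, the named list of written file paths
#' @export
writePhantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vx <- phantom@protocol@voxelSize
  paths <- list()
  wr <- function(x, name, datatype) {
    p <- file.path(dir, paste0(name, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(x, pixdim = c(vx, 1)[seq_along(dim(x))]),
                       p, datatype = datatype)
    p
  }
  paths$series <- wr(phantom@series, "dynamic_series", "float")
  paths$lowFlip <- wr(phantom@lowFlip, "lowflip_precontrast", "float")
  for (nm in names(phantom@masks))
    paths[[paste0("mask_", nm)]] <- wr(phantom@masks[[nm]] * 1L,
                                       paste0("mask_", nm), "uint8")
  for (nm in names(phantom@truth)) {
    tr <- phantom@truth[[nm]]
    tr[is.na(tr)] <- 0
    paths[[paste0("truth_", nm)]] <- wr(tr, paste0("truth_", nm), "float")
  }
  p <- phantom@protocol
  sidecar <- list(
    protocol = list(tr = p@tr, te = p@te, flip_dynamic = p@flipDynamic,
                    flip_t1map = p@flipT1map, dt = p@dt,
                    n_dynamics = p@nDynamics,
                    injection_start = p@injectionStart,
                    voxel_size = p@voxelSize),
    aif = list(model = phantom@aifModel@model,
               onset = phantom@aifModel@onset,
               parameters = phantom@aifModel@parameters),
    hematocrit = phantom@hematocrit)
  paths$sidecar <- file.path(dir, "phantom.yaml")
  yaml::write_yaml(sidecar, paths$sidecar)
  invisible(paths)
}
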