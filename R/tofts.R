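#' Tofts model forward convolution
#'
#' Tissue concentration under the standard (one-compartment) Tofts model,
#' \deqn{C_t(t) = K^{trans} \int_0^t C_p(\tau) e^{-k_{ep}(t-\tau)} d\tau,}
#' evaluated on the acquisition grid with the plasma curve treated as
#' piecewise linear between samples and the exponential kernel integrated
#' exactly on each interval. For a constant input the scheme reproduces
#' the closed-form step response exactly.
#'
#' @param ktrans volume transfer constant (1/min), positive
#' @param kep efflux rate constant (1/min), positive
#' @param cp plasma concentration (mM) at the grid times
#' @param tGrid sample times (s), strictly increasing, same length as `cp`
#' @return tissue concentration (mM) at the grid times
#' @examples
#' t <- seq(0, 300, by = 2.59)
#' cp <- evaluateAIF(AIFModel(onset = 6), t)
#' ct <- toftsForward(0.37, 0.67, cp, t)
#' @export
toftsForward <- function(ktrans, kep, cp, tGrid) {
  stopIfNot(length(ktrans) == 1 && ktrans > 0, "ktrans must be a single positive rate (1/min)")
  stopIfNot(length(kep) == 1 && kep > 0, "kep must be a single positive rate (1/min)")
  stopIfNot(length(cp) == length(tGrid), "cp and tGrid must have equal length")
  stopIfNot(all(diff(tGrid) > 0), "tGrid must be strictly increasing")
  ktrans * convolveExp(kep, cp, tGrid / 60)
}

# I(t_n) = int_{t_1}^{t_n} cp(tau) exp(-kep (t_n - tau)) dtau for
# piecewise-linear cp; recursive, exact per linear segment. tm in minutes.
convolveExp <- function(kep, cp, tm) {
  n <- length(cp)
  I <- numeric(n)
  if (n < 2) return(I)
  for (i in 2:n) {
    d <- tm[i] - tm[i - 1]
    E <- exp(-kep * d)
    s <- (cp[i] - cp[i - 1]) / d
    I[i] <- I[i - 1] * E +
      cp[i - 1] * (1 - E) / kep +
      s * (d * (1 - E) / kep - (1 - E * (1 + kep * d)) / kep^2)
  }
  I
}

#' Area under the gadolinium concentration curve
#'
#' Trapezoidal integral of the concentration curve over the full
#' acquisition, reported in mM min (rate constants and AUGC are carried in
#' minute units throughout; time grids are in seconds and converted here).
#'
#' @param ct concentration curve (mM), or a [ConcentrationSeries-class]
#'   (one AUGC per curve)
#' @param tGrid sample times (s); ignored when `ct` is a
#'   `ConcentrationSeries`
#' @return AUGC in mM min
#' @examples
#' computeAUGC(rep(0.3, 185), seq(0, by = 2.59, length.out = 185))
#' @export
computeAUGC <- function(ct, tGrid = NULL) {
  if (is(ct, "ConcentrationSeries")) {
    tGrid <- ct@tGrid
    m <- ct@conc
    return(apply(m, 1, function(row) trapz(tGrid / 60, row)))
  }
  stopIfNot(length(tGrid) == length(ct), "ct and tGrid must have equal length")
  stopIfNot(length(ct) >= 2, "need at least two time points")
  trapz(tGrid / 60, ct)
}

#' Fit the Tofts model to one concentration curve
#'
#' Nonlinear least squares in (Ktrans, kep) with ve derived as
#' Ktrans/kep. Initialisation is a deterministic coarse search over a
#' logarithmic kep grid with Ktrans profiled in closed form (the model is
#' linear in Ktrans at fixed kep), followed by bounded Levenberg-Marquardt
#' refinement. Curves with no variance (e.g. all-zero) return a
#' non-converged result with `r_squared = NA`.
#'
#' @param ct concentration curve (mM vector) or a single-curve
#'   [ConcentrationSeries-class]
#' @param aif an [AIF-class] on the same time grid
#' @param init optional starting values `c(ktrans, kep)`; default is the
#'   grid search
#' @param bounds list with elements `ktrans` and `kep`, each `c(lo, hi)`
#'   in 1/min
#' @param tGrid sample times (s) when `ct` is a bare vector; defaults to
#'   the AIF grid
#' @param nGrid number of kep values in the initial log-grid search
#' @return a list of class `PKVoxelResult`: `ktrans`, `kep`, `ve`,
#'   `r_squared`, `augc`, `converged`, `rss`
#' @examples
#' t <- seq(0, 460, by = 2.59)
#' cp <- evaluateAIF(AIFModel(onset = 6), t)
#' ct <- toftsForward(0.37, 0.67, cp, t)
#' fitToftsVoxel(ct, AIF(t, cp))
#' @export
fitToftsVoxel <- function(ct, aif, init = NULL,
                          bounds = list(ktrans = c(1e-4, 5), kep = c(1e-4, 10)),
                          tGrid = NULL, nGrid = 25) {
  if (is(ct, "ConcentrationSeries")) {
    stopIfNot(nrow(ct@conc) == 1, "supply a single curve")
    tGrid <- ct@tGrid
    ct <- as.vector(ct@conc)
  }
  if (is.null(tGrid)) tGrid <- aif@tGrid
  stopIfNot(length(ct) >= 10, "need at least 10 time points to fit")
  stopIfNot(isTRUE(all.equal(tGrid, aif@tGrid)), "ct and aif must share the time grid")
  augc <- if (all(is.finite(ct))) computeAUGC(ct, tGrid) else NA_real_

  bad <- !all(is.finite(ct)) || stats::var(ct) == 0
  if (bad) {
    return(structure(list(ktrans = NA_real_, kep = NA_real_, ve = NA_real_,
                          r_squared = NA_real_, augc = augc,
                          converged = FALSE, rss = NA_real_),
                     class = "PKVoxelResult"))
  }

  tm <- tGrid / 60
  cp <- aif@cp
  if (is.null(init)) {
    g <- gridInit(matrix(ct, nrow = 1), cp, tm, bounds, nGrid)
    init <- c(g$ktrans, g$kep)
  }
  fit <- minpack.lm::nls.lm(
    par = pmin(pmax(init, c(bounds$ktrans[1], bounds$kep[1])),
               c(bounds$ktrans[2], bounds$kep[2])),
    lower = c(bounds$ktrans[1], bounds$kep[1]),
    upper = c(bounds$ktrans[2], bounds$kep[2]),
    fn = function(p) ct - p[1] * convolveExp(p[2], cp, tm),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  p <- fit$par
  rss <- sum(fit$fvec^2)
  sst <- sum((ct - mean(ct))^2)
  r2 <- 1 - rss / sst
  conv <- fit$info %in% 1:4
  structure(list(ktrans = p[1], kep = p[2], ve = p[1] / p[2],
                 r_squared = r2, augc = augc, converged = conv, rss = rss),
            class = "PKVoxelResult")
}

#' @export
print.PKVoxelResult <- function(x, ...) {
  cat("Tofts fit: Ktrans ", signif(x$ktrans, 4), " /min, kep ",
      signif(x$kep, 4), " /min, ve ", signif(x$ve, 4),
      ", R2 ", signif(x$r_squared, 4), ", AUGC ", signif(x$augc, 4),
      " mM min", if (!x$converged) " [not converged]", "\n", sep = "")
  invisible(x)
}

# Coarse deterministic initialisation: for each kep on a log grid the
# optimal Ktrans is the least-squares projection onto the unit-Ktrans
# basis curve. Vectorized over many voxel curves at once.
gridInit <- function(ctMat, cp, tm, bounds, nGrid = 25) {
  keps <- exp(seq(log(max(bounds$kep[1], 1e-3)), log(bounds$kep[2]),
                  length.out = nGrid))
  B <- vapply(keps, function(k) convolveExp(k, cp, tm), numeric(length(tm)))
  bb <- colSums(B^2)                          # K
  num <- ctMat %*% B                          # V x K
  kt <- sweep(num, 2, bb, "/")
  kt <- pmin(pmax(kt, bounds$ktrans[1]), bounds$ktrans[2])
  sse <- -2 * kt * num + kt^2 * matrix(bb, nrow(ctMat), length(keps), byrow = TRUE)
  best <- max.col(-sse, ties.method = "first")
  list(ktrans = kt[cbind(seq_len(nrow(ctMat)), best)], kep = keps[best])
}

#' Voxel-wise Tofts parameter maps
#'
#' Fits the Tofts model at every masked voxel of a concentration volume
#' and assembles Ktrans/kep/ve/R2/AUGC maps. Voxels whose fit did not
#' converge or whose goodness of fit falls below `r2Threshold` are flagged
#' and excluded from the `validMask` that downstream ROI statistics use.
#'
#' @param concArray 4D concentration array (x, y, z, t) in mM, or a
#'   [ConcentrationSeries-class] carrying one curve per masked voxel in
#'   array order
#' @param aif an [AIF-class] on the same grid
#' @param mask 3D logical array of voxels to fit
#' @param r2Threshold goodness-of-fit threshold for retaining a voxel
#' @param bounds,nGrid passed to [fitToftsVoxel()]
#' @return a [ParameterMaps-class]
#' @export
fitParameterMaps <- function(concArray, aif, mask, r2Threshold = 0.7,
                             bounds = list(ktrans = c(1e-4, 5), kep = c(1e-4, 10)),
                             nGrid = 25) {
  d3 <- dim(mask)
  stopIfNot(length(d3) == 3, "mask must be a 3D logical array")
  if (is(concArray, "ConcentrationSeries")) {
    ctMat <- concArray@conc
    curveValid <- concArray@valid
    tGrid <- concArray@tGrid
    stopIfNot(nrow(ctMat) == sum(mask),
              "ConcentrationSeries must carry one curve per masked voxel")
  } else {
    d <- dim(concArray)
    stopIfNot(length(d) == 4 && identical(d[1:3], d3),
              "concArray must be 4D on the mask grid")
    stopIfNot(d[4] == length(aif@tGrid),
              "concentration and AIF grids differ in length")
    ctMat <- seriesToMatrix(concArray, mask)
    curveValid <- rep(TRUE, nrow(ctMat))
    tGrid <- aif@tGrid
  }
  stopIfNot(isTRUE(all.equal(tGrid, aif@tGrid)), "concentration and AIF grids differ")
  stopIfNot(r2Threshold >= 0 && r2Threshold <= 1, "r2Threshold must lie in [0, 1]")

  nv <- nrow(ctMat)
  tm <- tGrid / 60
  blank <- array(NA_real_, d3)
  out <- list(ktrans = blank, kep = blank, ve = blank, r2 = blank, augc = blank)
  conv <- logical(nv)
  vox <- which(mask)

  fitable <- curveValid & apply(ctMat, 1, function(x) all(is.finite(x)) && stats::var(x) > 0)
  res <- matrix(NA_real_, nv, 5,
                dimnames = list(NULL, c("ktrans", "kep", "ve", "r2", "augc")))
  if (any(fitable)) {
    sub <- ctMat[fitable, , drop = FALSE]
    ini <- gridInit(sub, aif@cp, tm, bounds, nGrid)
    idx <- which(fitable)
    for (j in seq_along(idx)) {
      ct <- sub[j, ]
      fit <- minpack.lm::nls.lm(
        par = c(ini$ktrans[j], ini$kep[j]),
        lower = c(bounds$ktrans[1], bounds$kep[1]),
        upper = c(bounds$ktrans[2], bounds$kep[2]),
        fn = function(p) ct - p[1] * convolveExp(p[2], aif@cp, tm),
        control = minpack.lm::nls.lm.control(maxiter = 200))
      rss <- sum(fit$fvec^2)
      r2 <- 1 - rss / sum((ct - mean(ct))^2)
      i <- idx[j]
      res[i, ] <- c(fit$par[1], fit$par[2], fit$par[1] / fit$par[2], r2,
                    trapz(tm, ct))
      conv[i] <- fit$info %in% 1:4
    }
  }
  for (nm in colnames(res)) out[[nm]][vox] <- res[, nm]
  valid <- array(FALSE, d3)
  valid[vox] <- conv & !is.na(res[, "r2"]) & res[, "r2"] >= r2Threshold
  new("ParameterMaps",
      ktrans = out$ktrans, kep = out$kep, ve = out$ve,
      r2 = out$r2, augc = out$augc,
      mask = array(mask, d3), validMask = valid, r2Threshold = r2Threshold)
}

setMethod("show", "ParameterMaps", function(object) {
  nm <- sum(object@mask); nv <- sum(object@validMask)
  cat("ParameterMaps: ", nm, " fitted voxels, ", nv,
      " pass R2 >= ", object@r2Threshold, " (", nm - nv, " excluded)\n",
      sep = "")
  if (nv > 0) {
    ok <- object@validMask
    cat("  median Ktrans ", signif(stats::median(object@ktrans[ok]), 3),
        " /min, kep ", signif(stats::median(object@kep[ok]), 3),
        " /min, ve ", signif(stats::median(object@ve[ok]), 3), "\n", sep = "")
  }
})

#' Parameter map accessors
#'
#' @param object a [ParameterMaps-class]
#' @param name one of `"ktrans"`, `"kep"`, `"ve"`, `"r2"`, `"augc"`
#' @return `parameterMap`: the named 3D map; `validMask`: the logical
#'   array of voxels passing convergence and the R2 filter.
#' @export
setGeneric("parameterMap", function(object, name) standardGeneric("parameterMap"))

#' @rdname parameterMap
#' @export
setMethod("parameterMap", "ParameterMaps", function(object, name) {
  slot(object, match.arg(name, c("ktrans", "kep", "ve", "r2", "augc")))
})

#' @rdname parameterMap
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))

#' @rdname parameterMap
#' @export
setMethod("validMask", "ParameterMaps", function(object) object@validMask)

#' @rdname parameterMap
#' @export
setMethod("validMask", "T1Map", function(object) object@validMask)
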