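test_that("noiseless phantom voxels follow the Tofts forward model exactly", {
  p <- shortProtocol()
  spec <- singleRegionSpec(ktrans = 0.37, kep = 0.67, t1 = 1400)
  ph <- generatePhantom(spec, p)
  t <- frameTimes(p)
  cp <- evaluateAIF(ph@aifModel, t)
  truthSig <- synthesizeSignal(toftsForward(0.37, 0.67, cp, t), 1400, 1000, p)
  vox <- which(ph@masks$tumor, arr.ind = TRUE)
  for (i in c(1, nrow(vox))) {
    expect_equal(ph@cleanSeries[vox[i, 1], vox[i, 2], vox[i, 3], ], truthSig)
  }
  # artery voxels carry blood signal at C_b = C_p (1 - Hct)
  arterySig <- synthesizeSignal(cp * (1 - ph@hematocrit), 1650, 1000, p)
  av <- which(ph@masks$artery, arr.ind = TRUE)[1, ]
  expect_equal(ph@cleanSeries[av[1], av[2], av[3], ], arterySig)
  # ground-truth maps carry the regional truth
  expect_equal(unique(ph@truth$ktrans[ph@masks$tumor]), 0.37)
  expect_equal(unique(ph@truth$ve[ph@masks$tumor]), 0.37 / 0.67)
})

test_that("overlapping masks are a specification error", {
  shape <- c(4L, 4L, 2L)
  m1 <- array(FALSE, shape); m1[1:2, , ] <- TRUE
  m2 <- array(FALSE, shape); m2[2:3, , ] <- TRUE
  expect_error(
    PhantomSpec(shape,
                regions = list(list(name = "a", mask = m1, ktrans = 0.3,
                                    kep = 0.6, t1 = 1000, m0 = 1000)),
                artery = list(mask = m2, t1 = 1650, m0 = 1000)),
    "disjoint")
})

test_that("different seeds change the noise but not the noiseless truth", {
  p <- shortProtocol(30L)
  a <- generatePhantom(singleRegionSpec(noiseSigma = 2, seed = 1), p)
  b <- generatePhantom(singleRegionSpec(noiseSigma = 2, seed = 2), p)
  expect_identical(a@cleanSeries, b@cleanSeries)
  expect_false(identical(a@series, b@series))
  # same seed reproduces the noise exactly
  a2 <- generatePhantom(singleRegionSpec(noiseSigma = 2, seed = 1), p)
  expect_identical(a@series, a2@series)
})

test_that("a two-frame series refuses the kinetic fit", {
  p <- AcquisitionProtocol(nDynamics = 2L, injectionStart = 2)
  ph <- generatePhantom(singleRegionSpec(), p)
  t <- frameTimes(p)
  aif <- AIF(t, evaluateAIF(ph@aifModel, t))
  expect_error(fitToftsVoxel(ph@cleanSeries[2, 2, 1, ], aif, tGrid = t),
               "at least 10 time points")
})

test_that("implausible ve = ktrans/kep > 1 in a region spec warns", {
  shape <- c(4L, 4L, 2L)
  m <- array(FALSE, shape); m[1:2, , ] <- TRUE
  expect_warning(
    PhantomSpec(shape,
                regions = list(list(name = "odd", mask = m, ktrans = 1.2,
                                    kep = 0.6, t1 = 1000, m0 = 1000)),
                artery = list(mask = NULL, t1 = 1650, m0 = 1000)),
    "ve")
})

test_that("phantom NIfTI round trip preserves data at float32 precision", {
  skip_if_not_installed("RNifti")
  p <- shortProtocol(20L)
  ph <- generatePhantom(singleRegionSpec(noiseSigma = 1, seed = 3), p)
  dir <- withr::local_tempdir()
  paths <- writePhantom(ph, dir)
  back <- RNifti::readNifti(paths$series)
  expect_equal(dim(back), dim(ph@series))
  expect_equal(array(back, dim(back)), ph@series, tolerance = 1e-6)
  msk <- RNifti::readNifti(paths$mask_tumor)
  expect_equal(array(msk > 0, dim(msk)), ph@masks$tumor)
  side <- yaml::read_yaml(paths$sidecar)
  expect_equal(side$protocol$tr, 4.0)
  expect_equal(side$hematocrit, 0.42)
})
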