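test_that("noiseless curves at cohort-typical kinetics are recovered within 1%", {
  p <- studyProtocol()
  t <- frameTimes(p)
  cp <- evaluateAIF(AIFModel(onset = p@injectionStart), t)
  aif <- AIF(t, cp)
  for (pars in list(c(0.37, 0.67), c(0.33, 0.64), c(0.1, 1.5))) {
    ct <- toftsForward(pars[1], pars[2], cp, t)
    fit <- fitToftsVoxel(ct, aif)
    expect_true(fit$converged)
    expect_lt(abs(fit$ktrans - pars[1]) / pars[1], 0.01)
    expect_lt(abs(fit$kep - pars[2]) / pars[2], 0.01)
    expect_gt(fit$r_squared, 0.999)
    # ve is derived by the parameterization identity
    expect_identical(fit$ve, fit$ktrans / fit$kep)
  }
})

test_that("ve equals ktrans/kep for every converged voxel of a noisy map", {
  p <- shortProtocol(80L)
  ph <- generatePhantom(singleRegionSpec(noiseSigma = snrSigma(20, 1400),
                                         seed = 21), p)
  t <- frameTimes(p)
  aif <- AIF(t, evaluateAIF(ph@aifModel, t))
  sig <- ToftsPK:::seriesToMatrix(ph@series, ph@masks$tumor)
  conc <- signalToConcentration(sig, t10 = 1400, protocol = p)
  maps <- fitParameterMaps(conc, aif, ph@masks$tumor, r2Threshold = 0)
  ok <- validMask(maps)
  expect_gt(sum(ok), 0)
  expect_equal(maps@ve[ok], maps@ktrans[ok] / maps@kep[ok])
})

test_that("median Ktrans error stays under 10% at SNR 20 over 100 voxels", {
  p <- studyProtocol()
  t <- frameTimes(p)
  cp <- evaluateAIF(AIFModel(onset = p@injectionStart), t)
  aif <- AIF(t, cp)
  ct <- toftsForward(0.37, 0.67, cp, t)
  sigma <- snrSigma(20, 1400) # concentration-scale noise via signal synthesis
  errs <- vapply(seq_len(100), function(i) {
    s <- synthesizeSignal(ct, 1400, 1000, p, noiseSigma = sigma,
                          seed = 5000 + i)
    cs <- signalToConcentration(s, t10 = 1400, protocol = p)
    if (!cs@valid) return(NA_real_)
    fit <- fitToftsVoxel(cs, aif)
    abs(fit$ktrans - 0.37) / 0.37
  }, numeric(1))
  expect_lt(median(errs, na.rm = TRUE), 0.10)
})

test_that("flat or invalid curves yield a flagged, non-converged result", {
  p <- shortProtocol()
  t <- frameTimes(p)
  aif <- AIF(t, evaluateAIF(AIFModel(onset = p@injectionStart), t))
  fit <- fitToftsVoxel(rep(0, p@nDynamics), aif)
  expect_false(fit$converged)
  expect_true(is.na(fit$r_squared))
  expect_true(is.na(fit$ktrans))
})

test_that("the R2 filter excludes noise voxels and extreme thresholds everything", {
  p <- shortProtocol(80L)
  t <- frameTimes(p)
  cp <- evaluateAIF(AIFModel(onset = p@injectionStart), t)
  aif <- AIF(t, cp)
  shape <- c(4L, 4L, 2L)
  mask <- array(TRUE, shape)
  nv <- prod(shape)
  ct <- toftsForward(0.37, 0.67, cp, t)
  # half the voxels carry signal, half pure noise
  set.seed(31)
  conc <- rbind(
    matrix(rep(ct, nv / 2), nv / 2, byrow = TRUE) +
      matrix(rnorm(nv / 2 * length(t), sd = 0.005), nv / 2),
    matrix(rnorm(nv / 2 * length(t), sd = 0.05), nv / 2))
  arr <- array(0, c(shape, length(t)))
  flat <- matrix(arr, nv, length(t)); flat[] <- conc
  arr <- array(flat, c(shape, length(t)))
  maps <- fitParameterMaps(arr, aif, mask, r2Threshold = 0.7)
  okIdx <- which(validMask(maps))
  expect_true(all(okIdx %in% which(mask)[1:(nv / 2)]))
  expect_gt(length(okIdx), nv / 4)       # signal voxels pass
  # uniform noiseless truth: every voxel passes and the map is constant
  flat2 <- matrix(rep(ct, nv), nv, byrow = TRUE)
  arr2 <- array(flat2, c(shape, length(t)))
  maps2 <- fitParameterMaps(arr2, aif, mask, r2Threshold = 0.7)
  expect_true(all(validMask(maps2)))
  expect_lt(diff(range(maps2@ktrans)), 1e-6)
  # r2Threshold = 1 excludes every noisy voxel
  maps3 <- fitParameterMaps(arr, aif, mask, r2Threshold = 1.0)
  expect_false(any(validMask(maps3)[cbind(3:4, 1:2, 1)]))
  expect_equal(sum(validMask(maps3)), 0)
})

test_that("fitting is deterministic given identical inputs", {
  p <- shortProtocol(80L)
  t <- frameTimes(p)
  cp <- evaluateAIF(AIFModel(onset = p@injectionStart), t)
  aif <- AIF(t, cp)
  set.seed(77)
  ct <- toftsForward(0.3, 0.8, cp, t) + rnorm(length(t), sd = 0.01)
  f1 <- fitToftsVoxel(ct, aif)
  f2 <- fitToftsVoxel(ct, aif)
  expect_identical(f1, f2)
})
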