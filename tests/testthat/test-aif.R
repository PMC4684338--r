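test_that("AIF is zero before the bolus onset", {
  aif <- AIFModel(onset = 30)
  t <- seq(0, 25, by = 1)
  expect_equal(evaluateAIF(aif, t), rep(0, length(t)))
  pk <- AIFModel("parker", onset = 30)
  expect_equal(evaluateAIF(pk, t), rep(0, length(t)))
})

test_that("biexponential AIF evaluates to a1 + a2 at the onset", {
  aif <- AIFModel(parameters = list(a1 = 0.5, a2 = 0.3, m1 = 0.2, m2 = 0.01),
                  onset = 10)
  expect_equal(evaluateAIF(aif, c(5, 10))[2], 0.8)
})

test_that("long-horizon integral matches the analytic a1/m1 + a2/m2", {
  aif <- AIFModel(onset = 0)
  p <- aif@parameters
  analytic <- p$a1 / p$m1 + p$a2 / p$m2
  t <- seq(0, 60 * 1500, by = 2)           # 1500 min horizon, mM min
  numeric <- sum(diff(t / 60) * (evaluateAIF(aif, t)[-1] +
                                 evaluateAIF(aif, t)[-length(t)]) / 2)
  expect_lt(abs(numeric - analytic) / analytic, 0.005)
})

test_that("AIF curves are nonnegative and unknown models are rejected", {
  t <- seq(0, 460, by = 2.59)
  expect_true(all(evaluateAIF(AIFModel(onset = 6), t) >= 0))
  expect_true(all(evaluateAIF(AIFModel("parker", onset = 6), t) >= 0))
  expect_error(AIFModel("triexponential"))
  bad <- new("AIFModel", model = "nope", parameters = list(), onset = 0)
  expect_error(evaluateAIF(bad, t), "unknown AIF model")
  expect_error(AIFModel(parameters = list(zz = 1)), "unknown parameter")
})

test_that("AIF extraction divides blood concentration by 1 - hematocrit", {
  p <- shortProtocol()
  t <- frameTimes(p)
  cp <- evaluateAIF(AIFModel(onset = p@injectionStart), t)
  shape <- c(3L, 3L, 2L)
  art <- array(FALSE, shape); art[1:2, 1, ] <- TRUE
  t1b <- 1650
  # artery voxels carry whole-blood signal C_b = C_p (1 - Hct)
  sig <- synthesizeSignal(cp * (1 - 0.42), t1b, 1000, p)
  series <- array(rep(spgrSignal(600, 800, p@flipDynamic, p@tr), prod(shape)),
                  c(shape, p@nDynamics))
  for (v in which(art)) {
    ijk <- arrayInd(v, shape)
    series[ijk[1], ijk[2], ijk[3], ] <- sig
  }
  aif <- extractAIF(series, art, t1Blood = t1b, protocol = p,
                    hematocrit = 0.42)
  expect_equal(aif@cp, cp, tolerance = 1e-6)

  # Hct = 0: plasma equals whole blood
  sig0 <- synthesizeSignal(cp, t1b, 1000, p)
  for (v in which(art)) {
    ijk <- arrayInd(v, shape)
    series[ijk[1], ijk[2], ijk[3], ] <- sig0
  }
  aif0 <- extractAIF(series, art, t1Blood = t1b, protocol = p, hematocrit = 0)
  expect_equal(aif0@cp, cp, tolerance = 1e-6)

  expect_error(extractAIF(series, array(FALSE, shape), t1b, p), "artery mask")
})

test_that("phantom artery round-trips the plasma curve within 1% at zero noise", {
  ph <- generatePhantom(singleRegionSpec(), shortProtocol())
  p <- ph@protocol
  t <- frameTimes(p)
  cp <- evaluateAIF(ph@aifModel, t)
  aif <- extractAIF(ph@cleanSeries, ph@masks$artery, t1Blood = 1650,
                    protocol = p, hematocrit = ph@hematocrit)
  nz <- cp > 1e-6
  expect_lt(max(abs(aif@cp[nz] - cp[nz]) / cp[nz]), 0.01)
})
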