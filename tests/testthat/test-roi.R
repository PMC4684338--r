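test_that("the ROI mean of a constant field is the constant, any mask shape", {
  shape <- c(6L, 6L, 3L)
  map <- array(0.42, shape)
  for (frac in c(0.2, 0.5, 0.9)) {
    set.seed(100 * frac)
    mask <- array(runif(prod(shape)) < frac, shape)
    if (sum(mask) >= 5) expect_equal(roiMean(map, mask), 0.42)
  }
})

test_that("the ROI mean honours the validity filter", {
  shape <- c(4L, 4L, 1L)
  map <- array(seq_len(16), shape)
  mask <- array(TRUE, shape)
  valid <- array(rep(c(TRUE, FALSE), 8), shape)
  expect_equal(roiMean(map, mask, valid), mean(seq(1, 15, by = 2)))
  # below the minimum analyzable size: unanalyzable, NA with warning
  small <- array(FALSE, shape); small[1:2, 1, 1] <- TRUE
  expect_warning(out <- roiMean(map, small, valid), "unanalyzable")
  expect_true(is.na(out))
})

test_that("ROI volume is voxel count times voxel volume in cm^3", {
  m1 <- array(TRUE, c(10L, 10L, 10L))
  expect_equal(roiVolume(m1, c(1, 1, 1)), 1.0)
  m2 <- array(FALSE, c(10L, 10L, 10L)); m2[seq_len(250)] <- TRUE
  expect_equal(roiVolume(m2, c(2, 2, 4)), 4.0)
  expect_error(roiVolume(array(FALSE, c(2L, 2L, 2L)), c(1, 1, 1)), "voxel")
})

test_that("percent change follows 100 (post - pre)/pre and its invariances", {
  expect_equal(percentChange(2, 2), 0)
  # a pre/post AUGC drop from 2.36 to 0.96 is a 59.3% reduction
  expect_equal(round(percentChange(2.36, 0.96), 1), -59.3)
  # +20% crosses a 19.78%-increase decision threshold
  expect_equal(percentChange(2.0, 2.4), 20)
  expect_gt(percentChange(2.0, 2.4), 19.78)
  # scale invariance
  expect_equal(percentChange(3 * 1.7, 5 * 1.7), percentChange(3, 5))
  expect_warning(out <- percentChange(0, 1), "undefined")
  expect_true(is.na(out))
})

test_that("phantom ROI mean recovers the regional truth within 2% at SNR 50", {
  p <- studyProtocol()
  spec <- singleRegionSpec(ktrans = 0.33, kep = 0.64,
                           noiseSigma = snrSigma(50, 1400), seed = 13)
  ph <- generatePhantom(spec, p)
  t <- frameTimes(p)
  aif <- extractAIF(ph@series, ph@masks$artery, t1Blood = 1650,
                    protocol = p, hematocrit = ph@hematocrit)
  sig <- ToftsPK:::seriesToMatrix(ph@series, ph@masks$tumor)
  conc <- signalToConcentration(sig, t10 = 1400, protocol = p)
  maps <- fitParameterMaps(conc, aif, ph@masks$tumor)
  est <- roiMean(parameterMap(maps, "ktrans"), ph@masks$tumor, validMask(maps))
  expect_lt(abs(est - 0.33) / 0.33, 0.02)
})

test_that("site summaries assemble means, volume and analyzability", {
  p <- shortProtocol(80L)
  ph <- generatePhantom(singleRegionSpec(), p)
  t <- frameTimes(p)
  aif <- AIF(t, evaluateAIF(ph@aifModel, t))
  sig <- ToftsPK:::seriesToMatrix(ph@cleanSeries, ph@masks$tumor)
  conc <- signalToConcentration(sig, t10 = 1400, protocol = p)
  maps <- fitParameterMaps(conc, aif, ph@masks$tumor)
  row <- siteSummary(maps, ph@masks$tumor, p@voxelSize, siteId = "tumor")
  expect_true(row$analyzable)
  expect_equal(row$ve, row$ktrans / row$kep, tolerance = 1e-8)
  expect_equal(row$volume, roiVolume(ph@masks$tumor, p@voxelSize))
})
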