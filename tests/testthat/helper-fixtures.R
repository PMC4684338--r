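# shared fixtures: everything generated in code, nothing on disk

# the study protocol (full length) and a short variant for cheap tests
studyProtocol <- function() AcquisitionProtocol()
shortProtocol <- function(n = 60L) AcquisitionProtocol(nDynamics = n)

# noise SD giving a target baseline SNR for a tissue
snrSigma <- function(snr, t1, m0 = 1000, protocol = studyProtocol()) {
  spgrSignal(m0, t1, protocol@flipDynamic, protocol@tr) / snr
}

# a single-region phantom spec with given truth, region of >= nVox voxels
singleRegionSpec <- function(ktrans = 0.37, kep = 0.67, t1 = 1400,
                             noiseSigma = 0, seed = NA, shape = c(8L, 8L, 4L)) {
  blank <- array(FALSE, shape)
  tum <- blank; tum[2:7, 2:7, ] <- TRUE       # 144 voxels
  art <- blank; art[1, 1, ] <- TRUE
  PhantomSpec(gridShape = shape,
              regions = list(list(name = "tumor", mask = tum,
                                  ktrans = ktrans, kep = kep,
                                  t1 = t1, m0 = 1000)),
              artery = list(mask = art, t1 = 1650, m0 = 1000),
              noiseSigma = noiseSigma, seed = seed)
}

# brute-force two-sided Fisher p by hypergeometric enumeration over all
# tables with the observed margins (minimum-likelihood rule)
fisherEnum <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  xs <- max(0, k - n):min(m, k)
  probs <- vapply(xs, function(x) {
    choose(m, x) * choose(n, k - x) / choose(m + n, k)
  }, numeric(1))
  obs <- probs[xs == tab[1, 1]]
  sum(probs[probs <= obs * (1 + 1e-7)])
}
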