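test_that("phantom generation is bit-identical for a fixed seed", {
  a <- generatePhantom(tinySpec(seed = 7L))
  b <- generatePhantom(tinySpec(seed = 7L))
  expect_identical(gasFraction(a), gasFraction(b))
  expect_identical(a@field@field, b@field@field)
  expect_identical(a@tidalTruth, b@tidalTruth)
  c <- generatePhantom(tinySpec(seed = 8L))
  expect_false(identical(gasFraction(a), gasFraction(c)))
})

test_that("generated fractions sum to one and masks are disjoint", {
  truth <- generatePhantom(tinySpec())
  s <- gasFraction(truth) + truth@fractions@tissue + truth@fractions@blood
  expect_equal(max(abs(s - 1)), 0, tolerance = 1e-12)
  expect_false(any(truth@aortaMask & truth@lungMask))
  expect_false(any(truth@muscleMask & truth@lungMask))
  expect_false(any(truth@aortaMask & truth@muscleMask))
})

test_that("gas fraction decreases monotonically along the gravitational axis", {
  truth <- generatePhantom(tinySpec(gasAnterior = 0.95, gasPosterior = 0.05,
                                    vesselCount = 0L,
                                    atelectasisExtent = 0))
  f <- gasFraction(truth)
  idx <- which(truth@lungMask, arr.ind = TRUE)
  j <- idx[, 2]
  band <- cut(j, breaks = seq(min(j) - 0.5, max(j) + 0.5, length.out = 13),
              labels = FALSE)
  means <- tapply(f[truth@lungMask], band, mean)
  expect_length(means, 12L)
  expect_true(all(diff(means) < 0))
})

test_that("switching atelectasis off removes all low-gas voxels outside vessels", {
  truth <- generatePhantom(tinySpec(atelectasisExtent = 0))
  nonVessel <- truth@lungMask & truth@fractions@blood == 0
  expect_true(all(gasFraction(truth)[nonVessel] >= 0.10))
  # and the default spec does contain a dependent atelectatic mass
  withAtel <- generatePhantom(tinySpec())
  expect_gt(sum(gasFraction(withAtel)[withAtel@lungMask &
                                      withAtel@fractions@blood == 0] < 0.10), 0)
})

test_that("vessels carry iodinated blood inside the lung", {
  truth <- generatePhantom(tinySpec())
  vessel <- truth@lungMask & truth@fractions@blood > 0
  expect_gt(sum(vessel), 0)
  expect_true(all(truth@fractions@blood[vessel] ==
                  truth@spec@vesselBloodFraction))
  expect_true(all(gasFraction(truth)[vessel] == 0))
})

test_that("the forward model is the linear HU mixing model", {
  b <- defaultMaterialBasis()
  d <- c(2L, 1L, 1L)
  fr <- makeFractions(array(c(1, 0.5), d), array(c(0, 0.5), d),
                      array(0, d))
  pair <- renderDect(fr, b, noiseSD = c(0, 0))
  expect_equal(voxelData(lowEnergy(pair))[, 1, 1], c(-1000, -470))
  expect_equal(voxelData(highEnergy(pair))[, 1, 1], c(-1000, -480))
})

test_that("raw decomposition of noisy renders is unbiased", {
  set.seed(21)
  n <- 20000L
  f <- randomSimplex(n)
  d <- c(n, 1L, 1L)
  fr <- makeFractions(array(f[1, ], d), array(f[2, ], d), array(f[3, ], d))
  b <- defaultMaterialBasis()
  pair <- renderDect(fr, b, noiseSD = c(10, 10), seed = 22L)
  raw <- decomposeDect(pair, b, project = FALSE)
  for (err in list(gasFraction(raw) - fr@gas,
                   tissueFraction(raw) - fr@tissue,
                   bloodFraction(raw) - fr@blood)) {
    se <- sd(err) / sqrt(n)
    expect_lt(abs(mean(err)), 3 * se)
  }
})

test_that("tidal series hits its extremes and matches the stored truth labels", {
  spec <- tinySpec(framesPerCycle = 16L, cycles = 1L)
  td <- simulateTidalSeries(spec)
  g <- vapply(td$series@frames, frameGasVolume, numeric(1),
              mask = td$series@mask, spacing = spec@spacing)
  expect_equal(td$truth$gas_volume_ml, g, tolerance = 1e-12)
  expect_identical(td$truth$phase[which.min(g)], "expiratory")
  expect_identical(td$truth$phase[which.max(g)], "inspiratory")
  expect_identical(td$truth$phase, bruteForcePhase(g, 0.30))
  expect_identical(classifyFrames(td$series)$phase, td$truth$phase)
})

test_that("a zero-amplitude tidal series is flagged degenerate", {
  td <- simulateTidalSeries(tinySpec(tidalAmplitude = 0))
  expect_true(all(is.na(td$truth$phase)))
  expect_error(classifyFrames(td$series), "degenerate")
  expect_error(simulateTidalSeries(tinySpec(framesPerCycle = 1L,
                                            cycles = 1L)),
               "at least 2 frames")
})

test_that("displacement fields honour profile, bound and interpolation", {
  zero <- generateDisplacementField(tinySpec(peakCaudalMM = 0))
  expect_true(all(zero@field == 0))

  unif <- generateDisplacementField(tinySpec(peakCaudalMM = 6,
                                             displacementProfile = "uniform"))
  expect_equal(max(abs(unif@field[, , , 3] - 6)), 0, tolerance = 1e-12)
  expect_true(all(unif@field[, , , 1:2] == 0))

  mid <- generateDisplacementField(tinySpec(peakCaudalMM = 10))
  expect_lte(max(mid@field[, , , 3]), 10 + 1e-9)
  expect_gte(min(mid@field[, , , 3]), 0)
})

test_that("regional analysis of the generated field matches the stored truth", {
  truth <- generatePhantom(tinySpec())
  cc <- ccDisplacementSlice(truth@field, truth@sliceMask)
  means <- regionalMeans(cc, truth@sliceMask, nRegions = 12L)
  expect_equal(means, truth@regionalDisplacement, tolerance = 1e-6)
})

test_that("invalid phantom specs are rejected", {
  expect_error(PhantomSpec(gasAnterior = 1.2), "fractions")
  expect_error(PhantomSpec(dim = c(0, 4, 4)), "positive")
  expect_error(PhantomSpec(noiseSD = c(-1, 5)), "non-negative")
})
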