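basis <- defaultMaterialBasis()

test_that("ROI calibration takes per-energy ROI means and fixes gas at -1000", {
  d <- c(6L, 6L, 2L)
  lo <- array(0, d); hi <- array(0, d)
  aorta <- array(FALSE, d); aorta[1:2, 1:2, ] <- TRUE
  muscle <- array(FALSE, d); muscle[5:6, 5:6, ] <- TRUE
  lo[aorta] <- 400; hi[aorta] <- 250
  lo[muscle] <- 60; hi[muscle] <- 40
  b <- calibrateBasis(DectPair(lo, hi), aorta, muscle)
  co <- materialCoefficients(b)
  expect_equal(unname(co["iodinated_blood", ]), c(400, 250))
  expect_equal(unname(co["soft_tissue", ]), c(60, 40))
  expect_equal(unname(co["gas", ]), c(-1000, -1000))

  # noisy ROI: coefficient equals the sample mean from a summation oracle
  set.seed(4)
  lo[aorta] <- rnorm(sum(aorta), 400, 20)
  b2 <- calibrateBasis(DectPair(lo, hi), aorta, muscle)
  expect_equal(materialCoefficients(b2)["iodinated_blood", "low"],
               sum(lo[aorta]) / sum(aorta))

  expect_error(calibrateBasis(DectPair(lo, hi), array(FALSE, d), muscle),
               "empty")
})

test_that("a degenerate basis is rejected naming the offending material pair", {
  expect_error(MaterialBasis(softTissue = c(60, 40),
                             iodinatedBlood = c(60, 40 + 1e-9)),
               "soft_tissue / iodinated_blood")
})

test_that("decomposition recovers pure materials at the simplex vertices", {
  co <- materialCoefficients(basis)
  d <- c(3L, 1L, 1L)
  lo <- array(co[, "low"], d)
  hi <- array(co[, "high"], d)
  fr <- decomposeDect(DectPair(lo, hi), basis)
  expect_equal(gasFraction(fr)[1, 1, 1], 1)
  expect_equal(tissueFraction(fr)[2, 1, 1], 1)
  expect_equal(bloodFraction(fr)[3, 1, 1], 1)
  expect_equal(gasFraction(fr)[2, 1, 1], 0)
})

test_that("noise-free forward rendering and decomposition round-trip exactly", {
  set.seed(7)
  f <- randomSimplex(1000)
  d <- c(10L, 10L, 10L)
  fr <- makeFractions(array(f[1, ], d), array(f[2, ], d), array(f[3, ], d))
  pair <- renderDect(fr, basis, noiseSD = c(0, 0))
  est <- decomposeDect(pair, basis)
  expect_lt(max(abs(gasFraction(est) - fr@gas),
                abs(tissueFraction(est) - fr@tissue),
                abs(bloodFraction(est) - fr@blood)), 1e-9)
  expect_equal(max(abs(gasFraction(est) + tissueFraction(est) +
                       bloodFraction(est) - 1)), 0, tolerance = 1e-12)
})

test_that("out-of-simplex solutions are clipped, renormalized and audited", {
  # HU below pure gas at both energies forces a negative tissue solution
  pair <- DectPair(array(-1100, c(1, 1, 1)), array(-1100, c(1, 1, 1)))
  fr <- decomposeDect(pair, basis)
  f <- c(gasFraction(fr)[1], tissueFraction(fr)[1], bloodFraction(fr)[1])
  expect_true(all(f >= 0 & f <= 1))
  expect_equal(sum(f), 1)
  expect_gt(fr@residual[1], 0)
  raw <- decomposeDect(pair, basis, project = FALSE)
  expect_lt(min(gasFraction(raw)[1], tissueFraction(raw)[1],
                bloodFraction(raw)[1]), 0)
})

test_that("relabelling materials in the basis permutes the fraction maps", {
  set.seed(8)
  f <- randomSimplex(50)
  d <- c(50L, 1L, 1L)
  fr <- makeFractions(array(f[1, ], d), array(f[2, ], d), array(f[3, ], d))
  pair <- renderDect(fr, basis, noiseSD = c(0, 0))
  swapped <- MaterialBasis(softTissue = c(400, 250),
                           iodinatedBlood = c(60, 40))
  a <- decomposeDect(pair, basis)
  b <- decomposeDect(pair, swapped)
  expect_equal(tissueFraction(a), bloodFraction(b), tolerance = 1e-9)
  expect_equal(bloodFraction(a), tissueFraction(b), tolerance = 1e-9)
  expect_equal(gasFraction(a), gasFraction(b), tolerance = 1e-9)
})

test_that("masking and non-finite values are handled explicitly", {
  d <- c(2L, 2L, 1L)
  lo <- array(-500, d); hi <- array(-500, d)
  mask <- array(c(TRUE, FALSE, TRUE, FALSE), d)
  fr <- decomposeDect(DectPair(lo, hi), basis, mask)
  expect_true(all(is.na(gasFraction(fr)[!mask])))
  expect_false(anyNA(gasFraction(fr)[mask]))
  # non-finite HU is rejected at volume construction already
  lo[1, 1, 1] <- NaN
  expect_error(DectPair(lo, hi), "finite")
})

test_that("merge volume is the stated linear blend and is linear", {
  p <- DectPair(array(-800, c(1, 1, 1)), array(-600, c(1, 1, 1)))
  expect_equal(voxelData(mergeVolumes(p))[1], -660)
  expect_equal(voxelData(mergeVolumes(p, 1))[1], -600)

  set.seed(9)
  d <- c(4L, 4L, 2L)
  a <- DectPair(array(rnorm(32), d), array(rnorm(32), d))
  b <- DectPair(array(rnorm(32), d), array(rnorm(32), d))
  ab <- DectPair(a@low@voxels + b@low@voxels, a@high@voxels + b@high@voxels)
  expect_equal(voxelData(mergeVolumes(ab)),
               voxelData(mergeVolumes(a)) + voxelData(mergeVolumes(b)))
  # identical energies: blend is a no-op
  same <- DectPair(a@low@voxels, a@low@voxels)
  expect_equal(voxelData(mergeVolumes(same, 0.7)), a@low@voxels)
  expect_error(mergeVolumes(a, 1.2), "\\[0, 1\\]")
})

test_that("non-contrast equivalent HU maps the aeration cutoffs", {
  expect_identical(noncontrastEquivalentHU(c(0.10, 0.50, 0.90)),
                   c(-100, -500, -900))
  expect_identical(noncontrastEquivalentHU(1), -1000)
  expect_error(noncontrastEquivalentHU(1.2), "\\[0, 1\\]")
})
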