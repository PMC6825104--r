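test_that("slice extraction returns the caudal component under the mask", {
  d <- c(6L, 8L, 4L)
  field <- array(0, c(d, 3))
  field[, , , 3] <- 6
  df <- DisplacementField(field)
  mask <- array(FALSE, d); mask[, , 2] <- TRUE
  cc <- ccDisplacementSlice(df, mask)
  expect_true(all(cc[mask] == 6))
  expect_true(all(is.na(cc[!mask])))

  zero <- DisplacementField(array(0, c(d, 3)))
  expect_true(all(ccDisplacementSlice(zero, mask)[mask] == 0))
  expect_error(ccDisplacementSlice(df, array(FALSE, d)), "empty")
})

test_that("regional means divide the mask extent into equal-height bands", {
  d <- c(4L, 24L, 1L)
  cc <- array(rep(as.numeric(1:24), each = 4), d)  # ramp along axis 2
  mask <- array(TRUE, d)
  means <- regionalMeans(cc, mask, nRegions = 12L)
  expect_length(means, 12L)
  expect_true(all(diff(means) > 0))
  # bands of two rows each: means are midpoints 1.5, 3.5, ...
  expect_equal(means, seq(1.5, 23.5, by = 2))

  uniform <- regionalMeans(array(4.2, d), mask, nRegions = 12L)
  expect_true(all(uniform == 4.2))

  # a gap in the mask leaves the corresponding bands missing
  gappy <- mask; gappy[, 9:16, ] <- FALSE
  withNA <- regionalMeans(cc, gappy, nRegions = 12L)
  expect_true(anyNA(withNA))
  expect_false(anyNA(withNA[c(1, 12)]))
  expect_error(regionalMeans(cc, mask, nRegions = 0L), ">= 1")
})

test_that("regional band voxel counts partition the mask", {
  truth <- generatePhantom(tinySpec())
  idx <- which(truth@sliceMask, arr.ind = TRUE)
  j <- idx[, 2]
  band <- ceiling((2 * (j - min(j)) + 1) * 12 / (2 * (max(j) - min(j) + 1)))
  expect_identical(sum(tabulate(band, 12)), sum(truth@sliceMask))
})

test_that("constant-plus-noise fields recover the constant per band", {
  set.seed(71)
  d <- c(20L, 24L, 1L)
  cc <- array(8 + rnorm(prod(d), 0, 0.5), d)
  means <- regionalMeans(cc, array(TRUE, d), nRegions = 12L)
  nPerBand <- prod(d) / 12
  expect_true(all(abs(means - 8) < 3 * 0.5 / sqrt(nPerBand)))
})

test_that("movement fractions bin caudal displacement by slice thickness", {
  expect_equal(unname(movementFractions(c(3, 7, 12, 4))),
               c(0.5, 0.25, 0.25, 0))
  expect_equal(unname(movementFractions(rep(2, 10))), c(1, 0, 0, 0))
  # cranial movement (negative) counts in the first bin
  expect_equal(unname(movementFractions(c(-3, 2))), c(1, 0, 0, 0))
  # 15 mm exactly belongs to the 10-15 bin; beyond is reported separately
  expect_equal(unname(movementFractions(c(15, 16))), c(0, 0, 0.5, 0.5))
  # partition: fractions sum to 1
  set.seed(72)
  v <- runif(500, -5, 20)
  expect_equal(sum(movementFractions(v)), 1)
  # invariant to in-plane permutation of voxels
  expect_equal(movementFractions(sample(v)), movementFractions(v))
  expect_error(movementFractions(1:3, thresholds = c(5, 5, 15)),
               "increasing")
})

test_that("condition summaries use median and linear-interpolation IQR", {
  d <- data.frame(peep = c(5, 5, 5, 5), v = c(1, 2, 3, 4))
  s <- summarizeByCondition(d, "v", "peep")
  expect_equal(s$median, 2.5)
  expect_equal(s$iqr, 1.5)

  single <- summarizeByCondition(data.frame(peep = 10, v = 7), "v", "peep")
  expect_equal(single$median, 7)
  expect_equal(single$iqr, 0)

  # invariant to row re-ordering
  set.seed(73)
  big <- data.frame(peep = rep(c(0, 10, 20), each = 8),
                    injured = rep(c(TRUE, FALSE), 12),
                    v = rnorm(24))
  a <- summarizeByCondition(big, "v", c("peep", "injured"))
  b <- summarizeByCondition(big[sample(24), ], "v", c("peep", "injured"))
  expect_equal(a, b)
})
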