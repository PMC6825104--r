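test_that("density histogram uses 150 left-closed 10-HU bins on [-1000, 500]", {
  h <- densityHistogram(array(-505, c(4, 1, 1)))
  expect_length(binWeights(h), 150L)
  expect_equal(binEdges(h)[1], -1000)
  expect_equal(binEdges(h)[151], 500)
  hit <- which(binWeights(h) > 0)
  expect_length(hit, 1L)
  expect_equal(binEdges(h)[hit], -510)     # bin [-510, -500)
  expect_equal(binWeights(h)[hit], 1)
  # +500 exactly falls in the closed last bin
  h2 <- densityHistogram(array(500, c(1, 1, 1)))
  expect_equal(binWeights(h2)[150], 1)
})

test_that("histogram weights match a brute-force counting oracle", {
  set.seed(51)
  v <- array(runif(500, -1200, 700), c(500, 1, 1))  # includes out-of-range
  h <- densityHistogram(v)
  oracle <- bruteForceHistogram(as.numeric(v), binEdges(h))
  expect_equal(binWeights(h), oracle$weights)
  expect_equal(h@outOfRange, oracle$outOfRange)
  # accounting: oracle's in-range count + out-of-range count = masked voxels
  inRange <- sum(as.numeric(v) >= -1000 & as.numeric(v) <= 500)
  expect_identical(inRange + h@outOfRange, h@nMasked)
  expect_equal(sum(binWeights(h)), 1, tolerance = 1e-9)
})

test_that("fraction histogram spans 0-100% in 1% bins with closed top bin", {
  h <- fractionHistogram(array(0, c(5, 1, 1)))
  expect_length(binWeights(h), 100L)
  expect_equal(binWeights(h)[1], 1)

  h2 <- fractionHistogram(array(c(0.005, 0.015), c(2, 1, 1)))
  expect_equal(binWeights(h2)[1:2], c(0.5, 0.5))

  h3 <- fractionHistogram(array(1, c(3, 1, 1)))
  expect_equal(binWeights(h3)[100], 1)

  set.seed(52)
  f <- array(runif(200), c(200, 1, 1))
  expect_equal(sum(binWeights(fractionHistogram(f))), 1, tolerance = 1e-9)
})

test_that("distribution correlation is Pearson r over the count vectors", {
  mk <- function(w) new("HistogramBins", edges = seq(0, 3),
                        weights = w, outOfRange = 0L, nMasked = 10L,
                        kind = "hu")
  a <- mk(c(0.5, 0.5, 0))
  b <- mk(c(0, 0.5, 0.5))
  expect_equal(distributionCorrelation(a, b), -0.5)
  expect_equal(distributionCorrelation(b, a), -0.5)   # symmetric
  expect_equal(distributionCorrelation(a, a), 1)

  flat <- mk(rep(1 / 3, 3))
  expect_error(distributionCorrelation(a, flat), "zero variance")
  other <- new("HistogramBins", edges = seq(0, 6, 2),
               weights = c(0.5, 0.5, 0), outOfRange = 0L, nMasked = 1L,
               kind = "hu")
  expect_error(distributionCorrelation(a, other), "edges")
})

test_that("mean of normalized histograms is normalized", {
  set.seed(53)
  hs <- lapply(1:4, function(i)
    fractionHistogram(array(runif(50), c(50, 1, 1))))
  m <- meanHistogram(hs)
  expect_equal(sum(binWeights(m)), 1, tolerance = 1e-9)
})

test_that("empty masks are rejected", {
  expect_error(densityHistogram(array(0, c(2, 1, 1)),
                                array(FALSE, c(2, 1, 1))), "empty")
  expect_error(fractionHistogram(array(0, c(2, 1, 1)),
                                 array(FALSE, c(2, 1, 1))), "empty")
})
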