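test_that("variable summaries reproduce uniform and two-region oracles", {
  # uniform phantom: f_gas = 0.6 everywhere, merge -600 HU
  d <- c(4L, 4L, 2L)
  fr <- makeFractions(array(0.6, d), array(0.4, d), array(0, d))
  merge <- CtVolume(array(-600, d))
  lab <- classifyAeration(fr)
  v <- summarizeVariables(merge, fr, lab)
  expect_equal(unname(v["ct_density_hu"]), -600)
  expect_equal(unname(v["fv_gas"]), 60)
  expect_equal(unname(v["fv_normally_aerated"]), 100)
  expect_equal(unname(v["fv_soft_tissue"] + v["fv_gas"] +
                      v["fv_iodinated_blood"]), 100)

  # two regions of unequal size: volume-weighted hand computation
  d2 <- c(10L, 1L, 1L)
  g <- array(c(rep(0.2, 3), rep(0.8, 7)), d2)
  fr2 <- makeFractions(g, 1 - g, array(0, d2))
  hu <- array(c(rep(-200, 3), rep(-800, 7)), d2)
  v2 <- summarizeVariables(CtVolume(hu), fr2, classifyAeration(fr2))
  expect_equal(unname(v2["ct_density_hu"]), (3 * -200 + 7 * -800) / 10)
  expect_equal(unname(v2["fv_gas"]), (3 * 0.2 + 7 * 0.8) / 10 * 100)
  expect_equal(unname(v2["fv_poorly_aerated"]), 30)
  expect_equal(unname(v2["fv_normally_aerated"]), 70)
})

test_that("Bland-Altman reproduces hand-computed limits and CIs", {
  # differences {-1, 0, 1}: sd = 1 by hand
  ba <- blandAltman(c(0, 1, 2), c(1, 1, 1))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$loa_lower, -1.96)
  expect_equal(ba$loa_upper, 1.96)
  expect_equal(ba$sd_diff, 1)
  # CI formulas: t quantile with SE sd/sqrt(n) and sd*sqrt(3/n)
  q <- qt(0.975, 2)
  expect_equal(ba$mean_diff_hi, q / sqrt(3))
  expect_equal(ba$loa_upper_hi, 1.96 + q * sqrt(3 / 3))

  ident <- blandAltman(c(3, 5, 9), c(3, 5, 9))
  expect_equal(ident$mean_diff, 0)
  expect_equal(ident$loa_lower, 0)
  expect_equal(ident$loa_upper, 0)

  expect_error(blandAltman(c(1, 2), c(1, 1)), "at least 3")
})

test_that("confidence intervals shrink with n at fixed SD", {
  mk <- function(n) as.numeric(scale(rnorm(n)))  # mean 0, sd exactly 1
  set.seed(61)
  b10 <- blandAltman(mk(10), rep(0, 10))
  b100 <- blandAltman(mk(100), rep(0, 100))
  expect_lt(b100$mean_diff_hi - b100$mean_diff_lo,
            b10$mean_diff_hi - b10$mean_diff_lo)
  expect_lt(b100$loa_upper_hi - b100$loa_upper_lo,
            b10$loa_upper_hi - b10$loa_upper_lo)
})

test_that("Bland-Altman recovers known Gaussian difference structure", {
  set.seed(62)
  n <- 1e4
  mu <- -30; sigma <- 16
  whole <- rnorm(n, 500, 40)
  dct <- whole + rnorm(n, mu, sigma)
  ba <- blandAltman(dct, whole)
  expect_lt(abs(ba$mean_diff - mu), 3 * sigma / sqrt(n))
  expect_lt(abs(ba$loa_lower - (mu - 1.96 * sigma)),
            0.02 * abs(mu - 1.96 * sigma))
  expect_lt(abs(ba$loa_upper - (mu + 1.96 * sigma)),
            0.02 * (1.96 * sigma))
})

test_that("correlation of means squares Pearson r and ignores affine maps", {
  x <- c(1, 2, 3, 5)
  y <- c(2, 3, 7, 9)
  r <- sum((x - mean(x)) * (y - mean(y))) /
       sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(correlateMeans(x, y), r^2)
  expect_equal(correlateMeans(x, 2 * x - 5), 1)
  expect_equal(correlateMeans(10 - 3 * x, y), correlateMeans(x, y))
})

test_that("phase bias reports per-phase means and paired 95% limits", {
  pb <- phaseBias(expiratory = c(-2, -2), inspiratory = c(1, 1))
  expect_equal(pb$exp_mean, -2)
  expect_equal(pb$insp_mean, 1)
  expect_equal(pb$diff_mean, 3)
  expect_equal(pb$diff_lo, 3)   # SD of paired differences is 0
  expect_equal(pb$diff_hi, 3)

  same <- phaseBias(c(1, 4, 2), c(1, 4, 2))
  expect_equal(same$diff_mean, 0)

  # limits widen monotonically with the SD of the paired differences
  set.seed(63)
  base <- rnorm(20)
  narrow <- phaseBias(base, base + rnorm(20, 1, 0.5))
  wide <- phaseBias(base, base + rnorm(20, 1, 3))
  expect_lt(narrow$diff_hi - narrow$diff_lo, wide$diff_hi - wide$diff_lo)

  expect_error(phaseBias(1:3, 1:4), "paired")
})

test_that("slice-position regression matches a closed-form OLS oracle", {
  # exactly linear: 3 HU per mm
  fit <- slicePositionRegression(c(0, 15, 30), c(0, 5, 10))
  expect_equal(fit$slope_per_mm, 3)
  expect_equal(fit$r_squared, 1)

  flat <- slicePositionRegression(rep(7, 4), c(0, 5, 10, 15))
  expect_equal(flat$slope_per_mm, 0)
  expect_true(is.na(flat$r_squared))

  set.seed(64)
  off <- rep(c(0, 5, 10), each = 8)
  vals <- cbind(a = 3 * off + rnorm(24, 0, 4),
                b = -0.3 * off + rnorm(24, 0, 1))
  fit2 <- slicePositionRegression(vals, off)
  for (k in 1:2) {
    o <- olsOracle(off, vals[, k])
    expect_equal(fit2$slope_per_mm[k], o$slope)
    expect_equal(fit2$r_squared[k], o$r2)
  }
  expect_error(slicePositionRegression(1:3, c(2, 2, 2)), "distinct")
})
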