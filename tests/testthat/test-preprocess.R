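test_that("DVARS matches hand arithmetic, is zero for constant input, and is parcel-order invariant", {
  ts <- TimeSeriesMatrix(rbind(c(0, 3), c(0, 4)))
  expect_equal(computeDvars(ts), c(0, sqrt((9 + 16) / 2)))
  const <- TimeSeriesMatrix(matrix(5, 4, 10))
  expect_equal(computeDvars(const), rep(0, 10))
  set.seed(1)
  x <- matrix(rnorm(50), 5)
  expect_equal(computeDvars(TimeSeriesMatrix(x)),
               computeDvars(TimeSeriesMatrix(x[5:1, ])))
  expect_error(computeDvars(TimeSeriesMatrix(matrix(1, 3, 1))), "2 frames")
})

test_that("scrubbing removes exactly the frames above mean + 2 SD", {
  # level shift at frame 15: a single nonzero DVARS value, which exceeds
  # mean + 2 SD of the series by direct arithmetic
  x <- matrix(0, 3, 30)
  x[, 15:30] <- 10
  ts <- TimeSeriesMatrix(x)
  dv <- computeDvars(ts)
  expect_equal(sum(dv > mean(dv) + 2 * sd(dv)), 1)
  scr <- scrubFrames(ts)
  expect_equal(which(!frameMask(scr)), 15L)
  expect_equal(sum(!frameMask(scr)), sum(dv > mean(dv) + 2 * sd(dv)))
  # equal DVARS everywhere: SD = 0, nothing exceeds the threshold
  ramp <- TimeSeriesMatrix(matrix(seq_len(20), 2, 20, byrow = TRUE))
  expect_true(all(frameMask(scrubFrames(ramp))))
})

test_that("detrending annihilates quadratics and is an orthogonal projection", {
  t <- seq_len(40)
  x <- rbind(2 + 0.5 * t - 0.01 * t^2, -1 + t + 0.05 * t^2)
  out <- detrendTimeSeries(TimeSeriesMatrix(x))
  expect_lt(max(abs(retainedValues(out))), 1e-9)
  set.seed(2)
  noise <- TimeSeriesMatrix(matrix(rnorm(200), 5))
  res <- detrendTimeSeries(noise)
  expect_true(all(apply(retainedValues(res), 1, var) <=
                    apply(retainedValues(noise), 1, var)))
  expect_lt(max(abs(rowMeans(retainedValues(res)))), 1e-9)
  # residuals orthogonal to the trend basis
  u <- 2 * (seq_len(40) - 1) / 39 - 1
  basis <- cbind(1, u, u^2)
  ip <- retainedValues(res) %*% basis
  expect_lt(max(abs(ip)) / max(abs(retainedValues(noise))), 1e-6)
})

test_that("confound regression zeroes self-regression and is the identity at k = 0", {
  set.seed(3)
  ts <- TimeSeriesMatrix(matrix(rnorm(300), 6))
  conf <- matrix(retainedValues(ts)[4, ], ncol = 1)
  out <- regressConfounds(ts, conf)
  expect_lt(max(abs(retainedValues(out)[4, ])), 1e-9)
  # residuals orthogonal to every confound column
  expect_lt(max(abs(retainedValues(out) %*% conf)), 1e-8)
  expect_identical(regressConfounds(ts, NULL), ts)
  expect_warning(regressConfounds(ts, cbind(conf, conf * 2)), "collinear")
})

test_that("CompCor pool tracks the highest-variance parcels", {
  set.seed(4)
  x <- matrix(rnorm(40 * 100), 40)
  x[c(7, 21), ] <- x[c(7, 21), ] * 6
  ts <- TimeSeriesMatrix(x)
  cc <- compCorConfounds(ts, k = 3, poolFraction = 0.1)
  expect_true(all(sprintf("P%03d", c(7, 21)) %in% attr(cc, "pool")))
  expect_equal(ncol(cc), 3)
  expect_warning(compCorConfounds(ts, k = 10, poolFraction = 0.1),
                 "reducing k")
})

test_that("the cleaning pipeline preserves order and normalizes to unit variance", {
  spec <- cohortSpec(nReference = 3, nParcels = 20, nTimepoints = 80,
                     seed = 6)
  ts <- generateReferenceCohort(spec)[[1]]
  clean <- preprocessTimeSeries(ts, compCorK = 2, poolFraction = 0.15)
  sds <- apply(retainedValues(clean), 1, sd)
  expect_equal(unname(sds), rep(1, 20), tolerance = 1e-10)
  expect_true(clean@metadata$detrended)
  expect_true(clean@metadata$normalized)
})
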