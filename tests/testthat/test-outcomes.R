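test_that("response and remission boundaries follow the 47% and <= 12 rules", {
  expect_true(classifyResponse(25, 12))    # 52% decrease
  expect_false(classifyResponse(25, 14))   # 44%
  expect_false(classifyResponse(30, 30))   # zero change
  expect_error(classifyResponse(0, 0), "undefined")
  expect_true(classifyRemission(12))
  expect_false(classifyRemission(13))
  expect_true(classifyRemission(0))
  expect_error(classifyRemission(70), "0, 63")
})

test_that("severity bands match BDI-II conventions", {
  expect_equal(severityBand(25.2), "moderate")
  expect_equal(severityBand(c(13, 14, 19, 20, 28, 29, 63)),
               c("minimal", "mild", "mild", "moderate", "moderate",
                 "severe", "severe"))
})

test_that("response and remission are logically independent", {
  # all four combinations are reachable
  expect_true(classifyResponse(30, 10) && classifyRemission(10))
  expect_true(classifyResponse(40, 20) && !classifyRemission(20))
  expect_true(!classifyResponse(20, 12) && classifyRemission(12))
  expect_true(!classifyResponse(30, 25) && !classifyRemission(25))
})

test_that("cohort summaries use completer denominators at follow-up", {
  rec <- generateOutcomes(26, followUpLoss = 7 / 26, seed = 8)
  s <- summarizeCohort(rec)
  expect_equal(s$n, 26)
  expect_equal(s$nFollowUp, 19)
  expect_equal(s$responseRatePost, 8 / 26)
  expect_equal(s$remissionRatePost, 16 / 26)
  fu <- !is.na(rec$bdi_followup)
  expect_equal(s$remissionRateFu, mean(rec$bdi_followup[fu] <= 12))
  allRemit <- rec
  allRemit$bdi_post <- pmin(allRemit$bdi_post, 12)
  expect_equal(summarizeCohort(allRemit)$remissionRatePost, 1)
})

test_that("rank-sum exact mode reproduces the enumeration oracle", {
  r <- rankSumTest(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)
  expect_equal(r$method, "exact")
  same <- rankSumTest(c(1, 2, 3), c(1, 2, 3))
  expect_gte(same$p, 0.99)
  set.seed(21)
  for (rep in 1:5) {
    a <- round(rnorm(sample(3:6, 1)), 1)
    b <- round(rnorm(sample(3:6, 1)) + rnorm(1), 1)
    mine <- rankSumTest(a, b)
    orac <- oracleRankSum(a, b)
    expect_equal(mine$U, orac$U)
    expect_equal(mine$p, orac$p)
  }
})

test_that("rank-sum agrees with wilcox.test and its approximation stays close", {
  set.seed(22)
  a <- rnorm(8); b <- rnorm(8) + 0.5   # continuous: no ties
  mine <- rankSumTest(a, b)
  ref <- stats::wilcox.test(a, b, exact = TRUE)
  expect_equal(mine$U, unname(ref$statistic))
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  approx <- rankSumTest(a, b, exactMax = 0)
  expect_equal(approx$method, "normal-approximation")
  expect_lt(abs(approx$p - mine$p), 0.02)
})

test_that("rank-sum p is invariant under common monotone transforms", {
  set.seed(23)
  a <- abs(rnorm(6)); b <- abs(rnorm(7)) + 0.3
  expect_equal(rankSumTest(a, b)$p, rankSumTest(exp(a), exp(b))$p)
  expect_error(rankSumTest(numeric(0), b), "non-empty")
})

test_that("TRD comparison runs on percent changes with complete cases", {
  rec <- generateOutcomes(26, seed = 9)
  res <- compareTrd(rec, "post")
  expect_true(res$p >= 0 && res$p <= 1)
  expect_equal(res$nTrd + res$nNonTrd, 26)
  resFu <- compareTrd(rec, "followup")
  expect_equal(resFu$nTrd + resFu$nNonTrd, sum(!is.na(rec$bdi_followup)))
})
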