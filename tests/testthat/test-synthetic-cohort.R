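test_that("reference cohort generation is deterministic and well-shaped", {
  spec <- cohortSpec(nReference = 5, nParcels = 20, nTimepoints = 40,
                     seed = 11)
  a <- generateReferenceCohort(spec)
  b <- generateReferenceCohort(spec)
  expect_length(a, 5)
  for (s in seq_along(a)) {
    expect_identical(values(a[[s]]), values(b[[s]]))
    expect_equal(dim(values(a[[s]])), c(20, 40))
  }
  other <- generateReferenceCohort(cohortSpec(nReference = 5, nParcels = 20,
                                              nTimepoints = 40, seed = 12))
  expect_false(identical(values(a[[1]]), values(other[[1]])))
})

test_that("degenerate cohort specifications are rejected or flagged", {
  expect_error(cohortSpec(noiseSd = 0), "positive")
  expect_error(cohortSpec(nReference = 1), "nReference")
  expect_error(cohortSpec(withinCoupling = 1), "withinCoupling")
  expect_warning(cohortSpec(nParcels = 377),
                 "rank-deficient")
})

test_that("patient generation validates injections and is exchangeable when empty", {
  spec <- cohortSpec(nReference = 5, nParcels = 20, nTimepoints = 60,
                     seed = 3)
  expect_error(injectionSpec(data.frame(i = 2, j = 2, direction = "hyper",
                                        magnitude = 5)), "self-edges")
  expect_error(injectionSpec(data.frame(i = c(1, 3), j = c(3, 1),
                                        direction = "hyper",
                                        magnitude = 5)), "once")
  expect_warning(injectionSpec(data.frame(i = 1, j = 2, direction = "hyper",
                                          magnitude = 0)), "undetectable")
  expect_error(generatePatient(spec, injectionSpec(
    data.frame(i = 1, j = 99, direction = "hyper", magnitude = 2))),
    "outside the atlas")
  # null patient: same marginal scale and same law as a reference subject
  p <- generatePatient(spec, injectionSpec(seed = 5))
  expect_equal(dim(values(p)), c(20, 60))
  refSds <- apply(values(generateReferenceCohort(spec)[[1]]), 1, sd)
  patSds <- apply(values(p), 1, sd)
  expect_equal(mean(patSds / refSds), 1, tolerance = 0.25)
})

test_that("excessive injection magnitudes give an explicit PD error", {
  spec <- cohortSpec(nReference = 5, nParcels = 20, seed = 3)
  expect_error(generatePatient(spec, injectionSpec(
    data.frame(i = 1, j = 2, direction = "hyper", magnitude = 100))),
    "positive-definite")
})

test_that("synthetic atlases straddle the 30-mm cutoff and validate", {
  spec <- cohortSpec(nReference = 5, nParcels = 30, seed = 2)
  atlas <- syntheticAtlas(spec)
  expect_silent(validateAtlas(atlas))
  expect_true(any(atlas$depth_mm < 30) && any(atlas$depth_mm > 30))
  expect_equal(nrow(atlas), 30)
  full <- fullParityAtlas(seed = 1)
  expect_equal(nrow(full), 377)
  expect_equal(sum(full$location == "Subcortical"), 17)
  expect_equal(sum(full$location != "Subcortical"), 180 * 2)
})

test_that("outcome generator hits requested fractions and carries follow-up loss", {
  rec <- generateOutcomes(26, responderFraction = 0, remitterFraction = 0,
                          seed = 4)
  expect_false(any(classifyResponse(rec$bdi_baseline, rec$bdi_post)))
  rec2 <- generateOutcomes(26, followUpLoss = 7 / 26, seed = 5)
  expect_equal(sum(!is.na(rec2$bdi_followup)), 19)
  expect_silent(validateOutcomes(rec2))
  # requested post fractions are met by construction
  expect_equal(sum(classifyResponse(rec2$bdi_baseline, rec2$bdi_post)), 8)
  expect_equal(sum(classifyRemission(rec2$bdi_post)), 16)
})

test_that("baseline BDI distribution matches its target mean", {
  # mean of 20 cohort means of n = 26: SE ~ 7.7 / sqrt(20 * 26) ~ 0.34,
  # asserted at the single-cohort +/-1.5 band
  means <- vapply(1:20, function(s)
    mean(suppressWarnings(generateOutcomes(26, seed = 100 + s))$bdi_baseline),
    1)
  expect_lt(abs(mean(means) - 25.2), 1.5)
})
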