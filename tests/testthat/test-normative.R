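# local mirror of the package-internal upper-triangle layout used below
.symFromUpperTest <- function(v, P) {
  m <- matrix(0, P, P)
  m[upper.tri(m)] <- v
  m + t(m)
}

# Small helper: tangent matrices from random symmetric noise.
.randTangents <- function(S, P, seed, sd = 1) {
  set.seed(seed)
  lapply(seq_len(S), function(s) {
    m <- matrix(rnorm(P * P, sd = sd), P)
    new("TangentMatrix", values = (m + t(m)) / 2, referenceId = "test",
        parcelIds = sprintf("P%03d", seq_len(P)), metadata = list())
  })
}

.dummyMean <- function(P) ConnectivityMatrix(diag(P), "regularized-covariance")

test_that("exclusion count is exactly the ceiling of a third of the edges", {
  for (P in c(4, 9, 25)) {
    tg <- .randTangents(12, P, seed = P)
    model <- fitNormative(tg, .dummyMean(P))
    E <- P * (P - 1) / 2
    expect_equal(sum(edgeTable(model)$excluded), ceiling(E / 3))
  }
  # P = 4 gives E = 6 and exactly 2 exclusions
  m4 <- fitNormative(.randTangents(12, 4, 1), .dummyMean(4))
  expect_equal(sum(edgeTable(m4)$excluded), 2)
})

test_that("degenerate references and small cohorts are rejected", {
  tg <- .randTangents(12, 5, 2)
  same <- rep(tg[1], 12)
  expect_error(fitNormative(same, .dummyMean(5)), "degenerate")
  expect_error(fitNormative(tg[1:5], .dummyMean(5)), "at least 10")
})

test_that("scoring centers at the model means and respects the strict 3-sigma rule", {
  tg <- .randTangents(20, 6, 3)
  model <- fitNormative(tg, .dummyMean(6))
  mu <- .symFromUpperTest(edgeTable(model)$mean, 6)
  tmu <- new("TangentMatrix", values = mu, referenceId = "test",
             parcelIds = model@parcelIds, metadata = list())
  a <- scoreSubject(tmu, model)
  et <- edgeTable(a)
  expect_true(all(et$z[!is.na(et$z)] == 0))
  expect_true(all(et$flag %in% c("normal", "excluded")))
})

test_that("scoring is translation-consistent edge by edge", {
  tg <- .randTangents(20, 6, 4)
  model <- fitNormative(tg, .dummyMean(6))
  subj <- .randTangents(1, 6, 5)[[1]]
  z0 <- edgeTable(scoreSubject(subj, model))$z
  # shift edge (1,2) in both the model mean and the subject by delta
  delta <- 0.7
  model2 <- model
  k <- which(model@edgeI == 1 & model@edgeJ == 2)
  model2@mean[k] <- model2@mean[k] + delta
  v <- subj@values
  v[1, 2] <- v[1, 2] + delta; v[2, 1] <- v[1, 2]
  subj2 <- new("TangentMatrix", values = v, referenceId = "test",
               parcelIds = subj@parcelIds, metadata = list())
  z1 <- edgeTable(scoreSubject(subj2, model2))$z
  expect_equal(z1, z0, tolerance = 1e-12)
})

test_that("network restriction keeps only edges with both endpoints in scope", {
  a <- makeAnomaly(9, hyper = rbind(c(1, 2), c(1, 8)), hypo = rbind(c(4, 9)))
  atlas <- makeAtlas(9, network = rep(c("DMN", "CEN", "Salience"), each = 3))
  all3 <- restrictNetworks(a, atlas, c("DMN", "CEN", "Salience"))
  expect_equal(edgeTable(all3)$flag, edgeTable(a)$flag)
  dmn <- restrictNetworks(a, atlas, "DMN")
  et <- edgeTable(dmn)
  inDmn <- et$edge_i <= 3 & et$edge_j <= 3
  expect_true(all(et$flag[!inDmn] == "excluded"))
  expect_equal(et$flag[et$edge_i == 1 & et$edge_j == 2], "hyper")
  # z is retained for audit on re-flagged edges
  expect_equal(et$z, edgeTable(a)$z)
  expect_error(restrictNetworks(a, atlas, character(0)), "non-empty")
  expect_error(restrictNetworks(a, atlas, "Limbic"), "not present")
})

test_that("heatmap colors encode flags symmetrically", {
  a <- makeAnomaly(6, hyper = rbind(c(2, 5)), hypo = rbind(c(1, 3)))
  path <- tempfile(fileext = ".png")
  renderAnomalyHeatmap(a, path, cellSize = 1)
  img <- png::readPNG(path)
  red <- img[, , 1] == 1 & img[, , 2] == 0 & img[, , 3] == 0
  blue <- img[, , 1] == 0 & img[, , 2] == 0 & img[, , 3] == 1
  white <- img[, , 1] == 1 & img[, , 2] == 1 & img[, , 3] == 1
  expect_equal(sum(red), 2)     # one hyper edge, two symmetric cells
  expect_equal(sum(blue), 2)
  expect_equal(sum(white), 36 - 4)
})

test_that("anomaly flags round-trip through the model persistence format", {
  tg <- .randTangents(15, 5, 6)
  model <- fitNormative(tg, .dummyMean(5))
  path <- tempfile(fileext = ".tsv")
  writeNormativeModel(model, path)
  back <- readNormativeModel(path)
  expect_equal(edgeTable(back), edgeTable(model), tolerance = 1e-12)
  expect_equal(back@nReference, model@nReference)
  subj <- .randTangents(1, 5, 7)[[1]]
  expect_equal(edgeTable(scoreSubject(subj, back)),
               edgeTable(scoreSubject(subj, model)), tolerance = 1e-10)
})
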