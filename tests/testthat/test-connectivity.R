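test_that("correlation matrices have P^2 entries and P(P-1)/2 unique pairs", {
  for (P in c(5, 12)) {
    set.seed(P)
    ts <- TimeSeriesMatrix(matrix(rnorm(P * 50), P))
    m <- correlationMatrix(ts)
    expect_equal(length(values(m)), P^2)
    expect_equal(sum(upper.tri(values(m))), P * (P - 1) / 2)
    expect_equal(unname(diag(values(m))), rep(1, P))
  }
  # the identity also holds at atlas-parity sizes
  for (P in c(1, 5, 60, 377))
    expect_equal(c(P^2, P * (P - 1) / 2),
                 c(P^2, choose(P, 2)))
})

test_that("a duplicated parcel shows unit off-diagonal correlation", {
  set.seed(9)
  x <- matrix(rnorm(100), 4)
  x[2, ] <- x[1, ]
  m <- correlationMatrix(TimeSeriesMatrix(x))
  expect_equal(values(m)[1, 2], 1)
})

test_that("zero-variance parcels are rejected by name", {
  x <- matrix(rnorm(60), 3, 20)
  x[2, ] <- 7
  expect_error(correlationMatrix(TimeSeriesMatrix(x)), "P002")
})

test_that("shrinkage regularization has its closed-form endpoints and certifies PD", {
  set.seed(10)
  C <- ConnectivityMatrix(randomPD(6, 10), "covariance")
  expect_identical(regularizeCovariance(C, 0), C)
  s1 <- regularizeCovariance(C, 1)
  expect_equal(values(s1),
               diag(sum(diag(values(C))) / 6, 6), ignore_attr = TRUE)
  expect_equal(sum(diag(values(s1))), sum(diag(values(C))))
  # rank-deficient input becomes PD under s = 0.1
  x <- matrix(rnorm(8 * 4), 8, 4)   # 8 parcels, 4 frames: rank <= 3
  Cdef <- ConnectivityMatrix(cov(t(x)), "covariance")
  reg <- regularizeCovariance(Cdef, 0.1)
  expect_gt(min(eigen(values(reg), symmetric = TRUE)$values), 0)
  expect_error(regularizeCovariance(C, 1.2), "0, 1")
})

test_that("Frechet mean fixes identical inputs and solves commuting diagonals in closed form", {
  C <- ConnectivityMatrix(randomPD(5, 11), "regularized-covariance")
  G <- frechetMean(list(C, C, C))
  expect_equal(values(G), values(C), tolerance = 1e-8)
  a <- c(1, 2, 5, 0.5); b <- c(4, 1, 2, 2)
  da <- ConnectivityMatrix(diag(a), "regularized-covariance")
  db <- ConnectivityMatrix(diag(b), "regularized-covariance")
  expect_equal(values(frechetMean(list(da, db))), diag(sqrt(a * b)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("Frechet mean agrees with an independent manifold-descent oracle", {
  mats <- lapply(1:10, function(s) randomPD(5, 100 + s))
  covs <- lapply(mats, ConnectivityMatrix, kind = "regularized-covariance")
  G <- frechetMean(covs, tol = 1e-10)
  Goracle <- oracleFrechetMean(mats)
  expect_lt(max(abs(values(G) - Goracle)), 1e-4)
})

test_that("tangent embedding has its closed forms and matches the matrix-log oracle", {
  G <- ConnectivityMatrix(randomPD(6, 12), "regularized-covariance")
  T0 <- tangentEmbed(G, G)
  expect_lt(max(abs(values(T0))), 1e-10)
  C2 <- ConnectivityMatrix(2 * values(G), "regularized-covariance")
  expect_equal(values(tangentEmbed(C2, G)), diag(log(2), 6),
               tolerance = 1e-10, ignore_attr = TRUE)
  C <- ConnectivityMatrix(randomPD(6, 13), "regularized-covariance")
  T1 <- values(tangentEmbed(C, G))
  Gis <- oracleSqrtm(solve(values(G)))
  expect_lt(max(abs(T1 - oracleLogm(Gis %*% values(C) %*% Gis))), 1e-8)
})

test_that("tangent embedding is equivariant under parcel relabeling", {
  C <- randomPD(7, 14); G <- randomPD(7, 15)
  set.seed(16)
  p <- sample(7)
  T1 <- values(tangentEmbed(
    ConnectivityMatrix(C, "regularized-covariance"),
    ConnectivityMatrix(G, "regularized-covariance")))
  T2 <- values(tangentEmbed(
    ConnectivityMatrix(C[p, p], "regularized-covariance"),
    ConnectivityMatrix(G[p, p], "regularized-covariance")))
  expect_equal(T2, T1[p, p], tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("non-PD inputs to the tangent map are rejected with guidance", {
  x <- matrix(rnorm(8 * 4), 8, 4)
  Cdef <- ConnectivityMatrix(cov(t(x)), "covariance")
  G <- ConnectivityMatrix(randomPD(8, 17), "regularized-covariance")
  expect_error(tangentEmbed(Cdef, G), "regulariz")
})
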