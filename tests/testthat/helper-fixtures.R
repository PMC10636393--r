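# Shared fixtures and independent numerical oracles.
# The default-scale normative model is expensive (~5 s), so it is built once
# per test run and cached for every file that needs it.

.fixtureCache <- new.env(parent = emptyenv())

fixtureSpec <- function() cohortSpec(seed = 42)

fixtureModel <- function() {
  if (is.null(.fixtureCache$model)) {
    spec <- fixtureSpec()
    cohort <- generateReferenceCohort(spec)
    .fixtureCache$model <- buildNormativeModel(cohort)
  }
  .fixtureCache$model
}

# Non-excluded cross-network edges between clean (non-amplified) parcels —
# the edge class the injection calibration is defined for.
fixtureCleanCrossEdges <- function(model = fixtureModel(),
                                   spec = fixtureSpec(),
                                   maxArProduct = Inf) {
  et <- edgeTable(model)
  net <- spec$networkPartition
  clean <- which(spec$multiplier == 1)
  keep <- which(!et$excluded &
                  net[et$edge_i] != net[et$edge_j] &
                  et$edge_i %in% clean & et$edge_j %in% clean &
                  spec$arCoef[et$edge_i] * spec$arCoef[et$edge_j] <=
                    maxArProduct)
  keep
}

# Random symmetric positive-definite matrix with moderate conditioning.
randomPD <- function(P, seed) {
  set.seed(seed)
  A <- matrix(rnorm(P * P), P)
  crossprod(A) / P + diag(P)
}

## ---- independent matrix-function oracles ----
## Built from Denman-Beavers square-root iterations plus power series, so
## they share no code path with the package's eigendecomposition routines.

oracleSqrtm <- function(A, iter = 100, tol = 1e-15) {
  Y <- A; Z <- diag(nrow(A))
  for (i in seq_len(iter)) {
    Yn <- (Y + solve(Z)) / 2
    Zn <- (Z + solve(Y)) / 2
    if (max(abs(Yn - Y)) < tol) return(Yn)
    Y <- Yn; Z <- Zn
  }
  Y
}

# Inverse scaling-and-squaring matrix logarithm: repeated square roots until
# the argument is near identity, then the Mercator series.
oracleLogm <- function(A, nSqrt = 10, nTerms = 80) {
  X <- A
  for (s in seq_len(nSqrt)) X <- oracleSqrtm(X)
  E <- X - diag(nrow(X))
  term <- E; total <- E
  for (m in 2:nTerms) {
    term <- term %*% E
    total <- total + (-1)^(m + 1) / m * term
  }
  2^nSqrt * total
}

# Scaling-and-squaring matrix exponential via Taylor series.
oracleExpm <- function(A, j = 10, nTerms = 25) {
  X <- diag(nrow(A)); term <- diag(nrow(A))
  As <- A / 2^j
  for (m in seq_len(nTerms)) {
    term <- term %*% As / m
    X <- X + term
  }
  for (s in seq_len(j)) X <- X %*% X
  X
}

# Small-step manifold gradient descent for the affine-invariant Frechet
# mean, using only the oracle primitives above (step size and start point
# deliberately different from the package's fixed-point iteration).
oracleFrechetMean <- function(mats, step = 0.5, iters = 200, tol = 1e-10) {
  P <- nrow(mats[[1]])
  G <- diag(P) * mean(vapply(mats, function(m) mean(diag(m)), 1))
  for (i in seq_len(iters)) {
    Gs <- oracleSqrtm(G)
    Gis <- solve(Gs)
    M <- Reduce(`+`, lapply(mats, function(C)
      oracleLogm(Gis %*% C %*% Gis))) / length(mats)
    M <- (M + t(M)) / 2
    if (sqrt(sum(M^2)) < tol) break
    G <- Gs %*% oracleExpm(step * M) %*% Gs
    G <- (G + t(G)) / 2
  }
  G
}

# Brute-force Mann-Whitney by pair counting over every group assignment
# (a different computation route than the package's rank-based statistic).
oracleRankSum <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a); N <- length(pooled)
  Ufun <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  U <- Ufun(a, b)
  mu <- n1 * (N - n1) / 2
  Uall <- apply(utils::combn(N, n1), 2, function(ix)
    Ufun(pooled[ix], pooled[-ix]))
  list(U = U, p = mean(abs(Uall - mu) >= abs(U - mu) - 1e-12))
}

# Hand-built anomaly matrix: P parcels, given hyper/hypo edge lists (i, j),
# everything else normal.
makeAnomaly <- function(P, hyper = NULL, hypo = NULL, sigma = 3) {
  idx <- which(upper.tri(matrix(0, P, P)), arr.ind = TRUE)
  ei <- as.integer(idx[, 1]); ej <- as.integer(idx[, 2])
  z <- rep(0, length(ei))
  flag <- rep("normal", length(ei))
  mark <- function(edges, val, lab) {
    for (r in seq_len(NROW(edges))) {
      k <- which(ei == min(edges[r, 1], edges[r, 2]) &
                   ej == max(edges[r, 1], edges[r, 2]))
      z[k] <<- val
      flag[k] <<- lab
    }
  }
  if (!is.null(hyper)) mark(hyper, sigma + 1.5, "hyper")
  if (!is.null(hypo)) mark(hypo, -sigma - 1.5, "hypo")
  new("AnomalyMatrix", edgeI = ei, edgeJ = ej, z = z, flag = flag,
      sigma = sigma, parcelIds = sprintf("P%03d", seq_len(P)),
      networksInScope = character(0), metadata = list())
}

# Minimal atlas for hand-built anomaly matrices.
makeAtlas <- function(P, depth = rep(20, P), network = rep("CEN", P),
                      location = rep("Synthetic cortical area", P)) {
  data.frame(parcel_id = sprintf("P%03d", seq_len(P)),
             name = sprintf("A%03d", seq_len(P)),
             hemisphere = rep(c("L", "R"), length.out = P),
             location = location, network = network, depth_mm = depth,
             x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
}
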