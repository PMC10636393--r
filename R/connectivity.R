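# Symmetric matrix functions via eigendecomposition.  All inputs here are
# symmetric by construction; (A + t(A))/2 guards against float drift.
.symEigen <- function(A) eigen((A + t(A)) / 2, symmetric = TRUE)

.symFun <- function(A, f, minEig = NULL, what = "matrix function") {
  e <- .symEigen(A)
  if (!is.null(minEig) && min(e$values) <= minEig)
    stop(what, " requires a positive-definite matrix (min eigenvalue ",
         signif(min(e$values), 4), "); apply regularizeCovariance() first",
         call. = FALSE)
  e$vectors %*% (f(e$values) * t(e$vectors))
}

.matSqrt <- function(A) .symFun(A, sqrt, 0, "matrix square root")
.matInvSqrt <- function(A) .symFun(A, function(v) 1 / sqrt(v), 0,
                                   "inverse matrix square root")
.matLog <- function(A) .symFun(A, log, 0, "matrix logarithm")
.matExp <- function(A) .symFun(A, exp)

.minEigen <- function(A) min(.symEigen(A)$values)

#' Pearson correlation matrix of a subject
#'
#' Correlation over retained frames.  For P parcels the matrix has P^2
#' entries and P(P-1)/2 unique unordered off-diagonal pairs (142,129 and
#' 70,876 respectively at the full 377-area scale).
#'
#' @param ts a \linkS4class{TimeSeriesMatrix} with >= 3 retained frames.
#' @return a \linkS4class{ConnectivityMatrix} of kind \code{"correlation"}.
#' @export
correlationMatrix <- function(ts) {
  stopifnot(is(ts, "TimeSeriesMatrix"))
  v <- retainedValues(ts)
  if (ncol(v) < 3) stop("correlation needs at least 3 retained frames")
  sds <- apply(v, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance parcel(s): ",
         paste(ts@parcelIds[sds == 0], collapse = ", "))
  ConnectivityMatrix(stats::cor(t(v)), "correlation", ts@parcelIds,
                     metadata = list(nFrames = ncol(v)))
}

#' Sample covariance matrix of a subject
#'
#' @param ts a \linkS4class{TimeSeriesMatrix} with >= 3 retained frames.
#' @return a \linkS4class{ConnectivityMatrix} of kind \code{"covariance"}
#'   (denominator n - 1).
#' @export
covarianceMatrix <- function(ts) {
  stopifnot(is(ts, "TimeSeriesMatrix"))
  v <- retainedValues(ts)
  if (ncol(v) < 3) stop("covariance needs at least 3 retained frames")
  ConnectivityMatrix(stats::cov(t(v)), "covariance", ts@parcelIds,
                     metadata = list(nFrames = ncol(v)))
}

#' Shrink a covariance toward a scaled identity
#'
#' \eqn{(1 - s) C + s\, (\mathrm{tr}(C)/P)\, I}.  For any s > 0 the output is
#' strictly positive definite whenever C is positive semidefinite, which the
#' tangent embedding requires.
#'
#' @param cov a \linkS4class{ConnectivityMatrix}.
#' @param shrinkage s in [0, 1] (default 0.1).
#' @return a \linkS4class{ConnectivityMatrix} of kind
#'   \code{"regularized-covariance"} (the input, unchanged, when s = 0).
#' @export
regularizeCovariance <- function(cov, shrinkage = 0.1) {
  stopifnot(is(cov, "ConnectivityMatrix"))
  if (shrinkage < 0 || shrinkage > 1) stop("shrinkage must be in [0, 1]")
  if (shrinkage == 0) return(cov)
  C <- cov@values
  mu <- sum(diag(C)) / nrow(C)
  out <- (1 - shrinkage) * C + shrinkage * mu * diag(nrow(C))
  md <- cov@metadata
  md$shrinkage <- shrinkage
  ConnectivityMatrix(out, "regularized-covariance", cov@parcelIds, md)
}

#' Affine-invariant Frechet mean of covariance matrices
#'
#' Fixed-point iteration on the manifold of positive-definite matrices:
#' \deqn{G \leftarrow G^{1/2} \exp\!\Big(\tfrac1S \sum_s
#'   \log(G^{-1/2} C_s G^{-1/2})\Big) G^{1/2},}
#' started at the arithmetic mean and stopped when the Frobenius norm of the
#' mean log term falls below \code{tol}.
#'
#' @param covs list of positive-definite \linkS4class{ConnectivityMatrix}
#'   objects of identical shape.
#' @param tol convergence tolerance on the Frobenius norm of the mean
#'   tangent residual (default 1e-6).
#' @param maxIter iteration cap (default 50); non-convergence is an error
#'   carrying the last residual.
#' @return a \linkS4class{ConnectivityMatrix} (kind
#'   \code{"regularized-covariance"}, positive definite by construction).
#' @export
frechetMean <- function(covs, tol = 1e-6, maxIter = 50) {
  stopifnot(length(covs) >= 1, all(vapply(covs, is, TRUE,
                                          "ConnectivityMatrix")))
  P <- nParcels(covs[[1]])
  mats <- lapply(covs, function(c) {
    if (nParcels(c) != P) stop("all matrices must share one shape")
    c@values
  })
  G <- Reduce(`+`, mats) / length(mats)
  if (.minEigen(G) <= 0)
    stop("inputs must be positive definite; apply regularizeCovariance()")
  for (it in seq_len(maxIter)) {
    Gs <- .matSqrt(G)
    Gis <- .matInvSqrt(G)
    M <- Reduce(`+`, lapply(mats, function(C) .matLog(Gis %*% C %*% Gis))) /
      length(mats)
    M <- (M + t(M)) / 2
    res <- sqrt(sum(M^2))
    if (res < tol) {
      return(ConnectivityMatrix(G, "regularized-covariance",
                                covs[[1]]@parcelIds,
                                metadata = list(frechetIterations = it,
                                                frechetResidual = res)))
    }
    G <- Gs %*% .matExp(M) %*% Gs
    G <- (G + t(G)) / 2
  }
  stop("Frechet mean did not converge in ", maxIter,
       " iterations (last residual ", signif(res, 4), ")")
}

#' Tangent-space embedding of a subject covariance
#'
#' Whitened matrix logarithm at the reference mean:
#' \eqn{T = \log(G^{-1/2} C G^{-1/2})}, computed by symmetric
#' eigendecomposition.  \code{tangentEmbed(G, G)} is the zero matrix.
#'
#' @param c subject \linkS4class{ConnectivityMatrix} (positive definite).
#' @param mean reference \linkS4class{ConnectivityMatrix} (positive
#'   definite), normally the cohort Frechet mean.
#' @param referenceId identifier recorded on the result.
#' @return a \linkS4class{TangentMatrix}.
#' @export
tangentEmbed <- function(c, mean, referenceId = "frechet-mean") {
  stopifnot(is(c, "ConnectivityMatrix"), is(mean, "ConnectivityMatrix"))
  if (nParcels(c) != nParcels(mean))
    stop("subject and reference must share one shape")
  Gis <- .matInvSqrt(mean@values)
  W <- Gis %*% c@values %*% Gis
  if (.minEigen(W) <= 0)
    stop("subject matrix is not positive definite relative to the ",
         "reference; apply regularizeCovariance() first")
  T <- .matLog(W)
  T <- (T + t(T)) / 2
  new("TangentMatrix", values = T, referenceId = referenceId,
      parcelIds = c@parcelIds, metadata = list())
}
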