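#' Frame-to-frame signal change (DVARS)
#'
#' DVARS at frame t (t >= 2) is the root mean square over parcels of the
#' signal change from the previous frame; the first frame is 0 by
#' convention.  Computed at parcel resolution, since the pipeline's inputs
#' begin at parcel time series.
#'
#' @param ts a \linkS4class{TimeSeriesMatrix}.
#' @return nonnegative numeric vector, one value per frame.
#' @examples
#' ts <- TimeSeriesMatrix(rbind(c(0, 3), c(0, 4)))
#' computeDvars(ts)   # c(0, sqrt((9 + 16) / 2))
#' @export
computeDvars <- function(ts) {
  stopifnot(is(ts, "TimeSeriesMatrix"))
  v <- ts@values
  if (ncol(v) < 2) stop("DVARS needs at least 2 frames")
  d <- v[, -1L, drop = FALSE] - v[, -ncol(v), drop = FALSE]
  c(0, sqrt(colMeans(d^2)))
}

#' Scrub high-motion frames
#'
#' Frames whose DVARS exceeds mean(DVARS) + sigma * SD(DVARS) are dropped
#' from the retention mask.  The threshold is one-sided (motion only inflates
#' DVARS) and is computed once from the supplied series; re-running on the
#' already-masked object with the same DVARS vector is idempotent.
#'
#' @param ts a \linkS4class{TimeSeriesMatrix}.
#' @param dvars per-frame DVARS, aligned with \code{ts} (default: computed).
#' @param sigma threshold multiplier (default 2).
#' @return the time series with its frame mask updated; scrubbed columns are
#'   set to NA.  Errors if every frame would be scrubbed; warns (and flags in
#'   metadata) if fewer than nParcels + 2 frames remain for covariance
#'   estimation.
#' @export
scrubFrames <- function(ts, dvars = computeDvars(ts), sigma = 2) {
  stopifnot(is(ts, "TimeSeriesMatrix"))
  if (length(dvars) != ncol(ts@values))
    stop("dvars must be aligned with the time series")
  thr <- mean(dvars) + sigma * stats::sd(dvars)
  keep <- ts@frameMask & !(dvars > thr)
  if (!any(keep))
    stop("all frames scrubbed (threshold ", signif(thr, 4),
         "); inspect the DVARS series")
  v <- ts@values
  v[, !keep] <- NA_real_
  md <- ts@metadata
  md$dvarsThreshold <- thr
  md$scrubbed <- sum(ts@frameMask) - sum(keep)
  if (sum(keep) < nrow(v) + 2) {
    warning("fewer than nParcels + 2 retained frames; covariance will be ",
            "rank-deficient")
    md$rankDeficient <- TRUE
  }
  TimeSeriesMatrix(v, ts@parcelIds, keep, md)
}

#' Remove linear and quadratic trends
#'
#' Per parcel, the least-squares fit of an intercept, linear, and quadratic
#' polynomial in frame index (over retained frames) is subtracted.  The
#' retained-frame mean of the output is zero to numerical precision.
#'
#' @param ts a \linkS4class{TimeSeriesMatrix}.
#' @return detrended time series (scrubbed frames stay NA).
#' @export
detrendTimeSeries <- function(ts) {
  stopifnot(is(ts, "TimeSeriesMatrix"))
  keep <- ts@frameMask
  if (sum(keep) < 4) stop("detrending needs at least 4 retained frames")
  idx <- which(keep)
  u <- 2 * (idx - min(idx)) / max(1, diff(range(idx))) - 1  # conditioning
  basis <- cbind(1, u, u^2)
  v <- ts@values
  v[, keep] <- t(.residualize(t(v[, keep, drop = FALSE]), basis))
  md <- ts@metadata
  md$detrended <- TRUE
  TimeSeriesMatrix(v, ts@parcelIds, keep, md)
}

#' CompCor-style confound components at parcel resolution
#'
#' The noise pool is the highest-variance decile of parcels (a parcel-level
#' surrogate for the voxel noise mask); the confounds are the top principal
#' components of their retained-frame time series.
#'
#' @param ts a \linkS4class{TimeSeriesMatrix} (usually already detrended).
#' @param k number of components (default 5; reduced with a warning if the
#'   pool cannot support it).
#' @param poolFraction fraction of parcels in the noise pool (default 0.1).
#' @return retained-frames x k numeric matrix with attribute
#'   \code{"pool"} naming the pool parcels.
#' @export
compCorConfounds <- function(ts, k = 5, poolFraction = 0.1) {
  stopifnot(is(ts, "TimeSeriesMatrix"))
  v <- retainedValues(ts)
  vars <- apply(v, 1, stats::var)
  nPool <- max(1L, ceiling(nrow(v) * poolFraction))
  pool <- order(vars, decreasing = TRUE)[seq_len(nPool)]
  y <- scale(t(v[pool, , drop = FALSE]), center = TRUE, scale = FALSE)
  kMax <- min(dim(y)) - 1L
  if (k > kMax) {
    warning("noise pool supports only ", kMax, " components; reducing k")
    k <- kMax
  }
  s <- svd(y, nu = k, nv = 0)
  comp <- s$u %*% diag(s$d[seq_len(k)], k)
  attr(comp, "pool") <- ts@parcelIds[pool]
  comp
}

#' Regress confounds out of a time series
#'
#' Residualizes every parcel's retained-frame series against the confound
#' matrix plus an intercept.  Collinear confound columns are dropped with a
#' warning.
#'
#' @param ts a \linkS4class{TimeSeriesMatrix}.
#' @param confounds retained-frames x k numeric matrix (k = 0 returns the
#'   input unchanged).
#' @return residualized time series.
#' @export
regressConfounds <- function(ts, confounds) {
  stopifnot(is(ts, "TimeSeriesMatrix"))
  keep <- ts@frameMask
  if (is.null(confounds) || NCOL(confounds) == 0) return(ts)
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != sum(keep))
    stop("confound rows must align with retained frames")
  if (ncol(confounds) >= nrow(confounds))
    stop("confound count must be below the retained frame count")
  X <- cbind(1, confounds)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    warning("dropping ", ncol(X) - qx$rank, " collinear confound column(s)")
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  }
  v <- ts@values
  v[, keep] <- t(.residualize(t(v[, keep, drop = FALSE]), X))
  md <- ts@metadata
  md$nConfounds <- ncol(X) - 1L
  TimeSeriesMatrix(v, ts@parcelIds, keep, md)
}

#' Parcel-level cleaning pipeline
#'
#' Fixed-order driver: DVARS scrubbing, then polynomial detrending, then
#' CompCor-style confound regression, then (optionally) per-parcel scaling to
#' unit variance.  Global signal regression is deliberately not performed.
#' The order is part of the contract — permuting these stages changes the
#' result.
#'
#' @param ts a \linkS4class{TimeSeriesMatrix}.
#' @param dvarsSigma scrubbing threshold multiplier (default 2).
#' @param compCorK number of CompCor components (default 5; 0 disables).
#' @param poolFraction CompCor noise-pool fraction (default 0.1).
#' @param normalize scale each parcel to unit retained-frame variance after
#'   confound regression (default TRUE).
#' @return cleaned \linkS4class{TimeSeriesMatrix}.
#' @export
preprocessTimeSeries <- function(ts, dvarsSigma = 2, compCorK = 5,
                                 poolFraction = 0.1, normalize = TRUE) {
  ts <- scrubFrames(ts, sigma = dvarsSigma)
  ts <- detrendTimeSeries(ts)
  if (compCorK > 0) {
    cc <- compCorConfounds(ts, k = compCorK, poolFraction = poolFraction)
    ts <- regressConfounds(ts, cc)
  }
  if (normalize) {
    keep <- ts@frameMask
    v <- ts@values
    sds <- apply(v[, keep, drop = FALSE], 1, stats::sd)
    if (any(sds < 1e-12))
      stop("zero-variance parcel after confound regression: ",
           paste(ts@parcelIds[sds < 1e-12], collapse = ", "))
    v[, keep] <- v[, keep, drop = FALSE] / sds
    md <- ts@metadata
    md$normalized <- TRUE
    ts <- TimeSeriesMatrix(v, ts@parcelIds, keep, md)
  }
  ts
}
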