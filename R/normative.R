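#' Fit per-edge normative statistics from a reference cohort
#'
#' For every upper-triangle edge the mean and sample SD (denominator n - 1)
#' of the tangent-space value across reference subjects are computed; edges
#' are then ranked by variance (descending, ties broken by ascending edge
#' index) and the top \code{ceiling(E * exclusionFraction)} flagged as too
#' noisy to score.  Variance is measured in tangent space — the space in
#' which subjects are scored.
#'
#' @param tangents list of \linkS4class{TangentMatrix} objects of one shape.
#' @param referenceMean the \linkS4class{ConnectivityMatrix} Frechet mean the
#'   tangents were embedded at (stored for scoring new subjects).
#' @param minReference minimum cohort size (default 10).
#' @param exclusionFraction fraction of edges excluded as high-variance
#'   (default 1/3).
#' @return a \linkS4class{NormativeModel}.
#' @export
fitNormative <- function(tangents, referenceMean, minReference = 10,
                         exclusionFraction = 1 / 3) {
  stopifnot(all(vapply(tangents, is, TRUE, "TangentMatrix")))
  S <- length(tangents)
  if (S < minReference)
    stop("need at least ", minReference, " reference subjects")
  P <- nParcels(tangents[[1]])
  if (any(vapply(tangents, nParcels, 1L) != P))
    stop("all tangent matrices must share one shape")
  E <- P * (P - 1) / 2
  X <- vapply(tangents, function(t) .upperVec(t@values), numeric(E))  # E x S
  mu <- rowMeans(X)
  vars <- rowSums((X - mu)^2) / (S - 1)
  nExcl <- ceiling(E * exclusionFraction)
  excl <- logical(E)
  excl[order(-vars, seq_len(E))[seq_len(nExcl)]] <- TRUE
  sds <- sqrt(vars)
  if (any(sds[!excl] == 0))
    stop("zero SD on a non-excluded edge: the reference cohort is degenerate")
  idx <- .edgeIndex(P)
  new("NormativeModel", edgeI = idx$i, edgeJ = idx$j, mean = mu, sd = sds,
      excluded = excl, nReference = as.integer(S),
      parcelIds = tangents[[1]]@parcelIds, referenceMean = referenceMean,
      metadata = list(exclusionFraction = exclusionFraction,
                      referenceId = tangents[[1]]@referenceId))
}

#' Score a subject against the normative model
#'
#' z = (t - mean) / SD per non-excluded edge; edges with z strictly above
#' \code{sigma} are flagged \code{hyper}, strictly below \code{-sigma}
#' \code{hypo}.  Variance-excluded edges carry no z.
#'
#' @param t the subject's \linkS4class{TangentMatrix} (embedded at the
#'   model's reference mean).
#' @param model a \linkS4class{NormativeModel}.
#' @param sigma outlier threshold in SD units (default 3).
#' @return an \linkS4class{AnomalyMatrix}.
#' @export
scoreSubject <- function(t, model, sigma = 3) {
  stopifnot(is(t, "TangentMatrix"), is(model, "NormativeModel"))
  if (nParcels(t) != nParcels(model))
    stop("subject shape does not match the model")
  v <- .upperVec(t@values)
  z <- (v - model@mean) / model@sd
  z[model@excluded] <- NA_real_
  flag <- rep("normal", length(z))
  flag[!model@excluded & z > sigma] <- "hyper"
  flag[!model@excluded & z < -sigma] <- "hypo"
  flag[model@excluded] <- "excluded"
  new("AnomalyMatrix", edgeI = model@edgeI, edgeJ = model@edgeJ, z = z,
      flag = flag, sigma = sigma, parcelIds = model@parcelIds,
      networksInScope = character(0),
      metadata = list(nReference = model@nReference))
}

#' Restrict an anomaly matrix to named networks
#'
#' Edges with either endpoint outside the selected networks are re-flagged
#' \code{excluded} (their z is retained for audit).  An edge survives only if
#' both endpoints lie in the selected set, matching per-network square
#' anomaly matrices; pass several labels to keep their cross-edges.
#'
#' @param a an \linkS4class{AnomalyMatrix}.
#' @param atlas atlas data.frame (see \code{\link{syntheticAtlas}}) whose
#'   parcel order matches the matrix.
#' @param networks non-empty character vector of network labels.
#' @return a restricted \linkS4class{AnomalyMatrix}.
#' @export
restrictNetworks <- function(a, atlas, networks) {
  stopifnot(is(a, "AnomalyMatrix"))
  validateAtlas(atlas)
  if (length(networks) == 0) stop("network set must be non-empty")
  missing <- setdiff(networks, atlas$network)
  if (length(missing))
    stop("networks not present in the atlas: ",
         paste(missing, collapse = ", "))
  net <- atlas$network[match(a@parcelIds, atlas$parcel_id)]
  inScope <- net %in% networks
  keep <- inScope[a@edgeI] & inScope[a@edgeJ]
  flag <- a@flag
  flag[!keep] <- "excluded"
  new("AnomalyMatrix", edgeI = a@edgeI, edgeJ = a@edgeJ, z = a@z,
      flag = flag, sigma = a@sigma, parcelIds = a@parcelIds,
      networksInScope = as.character(networks), metadata = a@metadata)
}

#' Render an anomaly matrix as a heat map image
#'
#' Red = hyperconnected, blue = hypo-connected, white = within the normal
#' range, black = excluded (too noisy in the reference population or outside
#' the networks in scope).  The diagonal is drawn white.
#'
#' @param a an \linkS4class{AnomalyMatrix}.
#' @param path output PNG path.
#' @param cellSize pixels per matrix cell (default 4).
#' @return the path, invisibly.
#' @export
renderAnomalyHeatmap <- function(a, path, cellSize = 4) {
  stopifnot(is(a, "AnomalyMatrix"))
  P <- nParcels(a)
  cols <- list(hyper = c(1, 0, 0), hypo = c(0, 0, 1),
               normal = c(1, 1, 1), excluded = c(0, 0, 0))
  img <- array(1, dim = c(P, P, 3))
  for (e in seq_along(a@edgeI)) {
    rgb <- cols[[a@flag[e]]]
    img[a@edgeI[e], a@edgeJ[e], ] <- rgb
    img[a@edgeJ[e], a@edgeI[e], ] <- rgb
  }
  if (cellSize > 1) {
    up <- matrix(1, cellSize, cellSize)
    img <- array(c(kronecker(img[, , 1], up), kronecker(img[, , 2], up),
                   kronecker(img[, , 3], up)),
                 dim = c(P * cellSize, P * cellSize, 3))
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Build a normative model from raw reference time series
#'
#' Convenience driver: preprocess every subject, compute shrinkage-regularized
#' covariances, take their Frechet mean, embed each subject in its tangent
#' space, and fit the per-edge model.
#'
#' @param cohort list of raw \linkS4class{TimeSeriesMatrix} objects.
#' @param shrinkage covariance shrinkage (default 0.1).
#' @param dvarsSigma,compCorK,poolFraction,normalize passed to
#'   \code{\link{preprocessTimeSeries}}.
#' @param minReference,exclusionFraction passed to \code{\link{fitNormative}}.
#' @param tol,maxIter passed to \code{\link{frechetMean}}.
#' @return a \linkS4class{NormativeModel} whose metadata records the
#'   preprocessing and shrinkage parameters.
#' @export
buildNormativeModel <- function(cohort, shrinkage = 0.1, dvarsSigma = 2,
                                compCorK = 5, poolFraction = 0.1,
                                normalize = TRUE, minReference = 10,
                                exclusionFraction = 1 / 3, tol = 1e-6,
                                maxIter = 50) {
  covs <- lapply(cohort, function(ts) {
    clean <- preprocessTimeSeries(ts, dvarsSigma = dvarsSigma,
                                  compCorK = compCorK,
                                  poolFraction = poolFraction,
                                  normalize = normalize)
    regularizeCovariance(covarianceMatrix(clean), shrinkage)
  })
  G <- frechetMean(covs, tol = tol, maxIter = maxIter)
  tangents <- lapply(covs, tangentEmbed, mean = G)
  model <- fitNormative(tangents, referenceMean = G,
                        minReference = minReference,
                        exclusionFraction = exclusionFraction)
  model@metadata$shrinkage <- shrinkage
  model@metadata$preprocess <- list(dvarsSigma = dvarsSigma,
                                    compCorK = compCorK,
                                    poolFraction = poolFraction,
                                    normalize = normalize)
  model
}

#' Score a raw patient time series against a normative model
#'
#' Applies the identical preprocessing and embedding route used to build the
#' model, then calls edge anomalies.
#'
#' @param ts raw patient \linkS4class{TimeSeriesMatrix}.
#' @param model a \linkS4class{NormativeModel} built by
#'   \code{\link{buildNormativeModel}}.
#' @param sigma outlier threshold (default 3).
#' @return an \linkS4class{AnomalyMatrix}.
#' @export
scorePatient <- function(ts, model, sigma = 3) {
  pp <- model@metadata$preprocess
  if (is.null(pp)) pp <- list(dvarsSigma = 2, compCorK = 5,
                              poolFraction = 0.1, normalize = TRUE)
  shrink <- model@metadata$shrinkage
  if (is.null(shrink)) shrink <- 0.1
  clean <- preprocessTimeSeries(ts, dvarsSigma = pp$dvarsSigma,
                                compCorK = pp$compCorK,
                                poolFraction = pp$poolFraction,
                                normalize = pp$normalize)
  cov <- regularizeCovariance(covarianceMatrix(clean), shrink)
  t <- tangentEmbed(cov, model@referenceMean)
  scoreSubject(t, model, sigma = sigma)
}
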