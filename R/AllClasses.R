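#' Parcel-by-timepoint BOLD time series
#'
#' Holds one subject's parcellated BOLD signal (parcels in rows, timepoints in
#' columns) together with a per-frame retention mask.  Frames dropped by
#' motion scrubbing stay in the matrix (as \code{NA} once a cleaning step has
#' run) but are excluded from every downstream computation via the mask.
#'
#' @slot values numeric matrix, parcels x timepoints, arbitrary signal units.
#' @slot parcelIds character, one id per row, matching the atlas.
#' @slot frameMask logical, one entry per column; \code{TRUE} = retained.
#' @slot metadata list; provenance (seed, preprocessing steps, flags).
#'
#' @export
setClass("TimeSeriesMatrix",
  representation(values = "matrix", parcelIds = "character",
                 frameMask = "logical", metadata = "list"))

setValidity("TimeSeriesMatrix", function(object) {
  v <- object@values
  if (nrow(v) != length(object@parcelIds))
    return("number of rows must equal length(parcelIds)")
  if (ncol(v) != length(object@frameMask))
    return("number of columns must equal length(frameMask)")
  if (anyDuplicated(object@parcelIds))
    return("parcelIds must be unique")
  if (any(object@frameMask) && anyNA(v[, object@frameMask, drop = FALSE]))
    return("retained frames must not contain NA/NaN")
  TRUE
})

#' Construct a TimeSeriesMatrix
#'
#' @param values parcels x timepoints numeric matrix.
#' @param parcelIds parcel identifiers (defaults to rownames, then P001...).
#' @param frameMask logical retention mask (default: all retained).
#' @param metadata free-form provenance list.
#' @return a \linkS4class{TimeSeriesMatrix}
#' @export
TimeSeriesMatrix <- function(values, parcelIds = NULL,
                             frameMask = rep(TRUE, ncol(values)),
                             metadata = list()) {
  values <- as.matrix(values)
  if (is.null(parcelIds)) {
    parcelIds <- rownames(values)
    if (is.null(parcelIds))
      parcelIds <- sprintf("P%03d", seq_len(nrow(values)))
  }
  rownames(values) <- parcelIds
  new("TimeSeriesMatrix", values = values, parcelIds = as.character(parcelIds),
      frameMask = as.logical(frameMask), metadata = metadata)
}

#' Symmetric subject connectivity matrix
#'
#' @slot values symmetric numeric matrix (parcels x parcels), unitless.
#' @slot kind one of \code{"correlation"}, \code{"covariance"},
#'   \code{"regularized-covariance"}.
#' @slot parcelIds parcel identifiers.
#' @slot metadata provenance list.
#' @export
setClass("ConnectivityMatrix",
  representation(values = "matrix", kind = "character",
                 parcelIds = "character", metadata = "list"))

setValidity("ConnectivityMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (nrow(v) != length(object@parcelIds))
    return("dimension must equal length(parcelIds)")
  if (!object@kind %in% c("correlation", "covariance",
                          "regularized-covariance"))
    return("kind must be correlation, covariance or regularized-covariance")
  if (max(abs(v - t(v))) > 1e-10 * max(1, max(abs(v))))
    return("matrix must be symmetric to 1e-10 (relative)")
  if (object@kind == "correlation" && nrow(v) > 0 &&
      max(abs(diag(v) - 1)) > 1e-8)
    return("correlation matrix must have unit diagonal")
  TRUE
})

#' @rdname ConnectivityMatrix-class
#' @param values,kind,parcelIds,metadata see slots.
#' @return a \linkS4class{ConnectivityMatrix}
#' @export
ConnectivityMatrix <- function(values, kind, parcelIds = NULL,
                               metadata = list()) {
  values <- as.matrix(values)
  values <- (values + t(values)) / 2   # enforce exact symmetry
  if (is.null(parcelIds)) {
    parcelIds <- rownames(values)
    if (is.null(parcelIds))
      parcelIds <- sprintf("P%03d", seq_len(nrow(values)))
  }
  dimnames(values) <- list(parcelIds, parcelIds)
  new("ConnectivityMatrix", values = values, kind = kind,
      parcelIds = as.character(parcelIds), metadata = metadata)
}

#' Tangent-space connectivity deviation matrix
#'
#' The matrix logarithm of a subject's whitened covariance,
#' \eqn{T = \log(G^{-1/2} C G^{-1/2})}, taken at a reference mean \eqn{G}
#' (usually the Frechet mean of the normative cohort).
#'
#' @slot values symmetric numeric matrix.
#' @slot referenceId identifier of the reference mean used for whitening.
#' @slot parcelIds parcel identifiers.
#' @slot metadata provenance list.
#' @export
setClass("TangentMatrix",
  representation(values = "matrix", referenceId = "character",
                 parcelIds = "character", metadata = "list"))

setValidity("TangentMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (nrow(v) != length(object@parcelIds))
    return("dimension must equal length(parcelIds)")
  if (!all(is.finite(v))) return("tangent entries must be finite")
  if (max(abs(v - t(v))) > 1e-8 * max(1, max(abs(v))))
    return("tangent matrix must be symmetric")
  TRUE
})

#' Per-edge normative statistics of a reference cohort
#'
#' Mean and sample SD (denominator n-1) of every upper-triangle tangent-space
#' edge across the reference subjects, plus the exclusion mask flagging the
#' highest-variance third of pairs as too noisy to score.
#'
#' @slot edgeI,edgeJ integer parcel indices (1-based, i < j, column-major
#'   upper-triangle order).
#' @slot mean,sd numeric per-edge statistics.
#' @slot excluded logical; \code{TRUE} = edge not scored.
#' @slot nReference number of reference subjects.
#' @slot parcelIds parcel identifiers.
#' @slot referenceMean the \linkS4class{ConnectivityMatrix} Frechet mean used
#'   to embed subjects, kept so that new subjects can be scored.
#' @slot metadata provenance (shrinkage, exclusion fraction, seeds).
#' @export
setClass("NormativeModel",
  representation(edgeI = "integer", edgeJ = "integer", mean = "numeric",
                 sd = "numeric", excluded = "logical", nReference = "integer",
                 parcelIds = "character", referenceMean = "ConnectivityMatrix",
                 metadata = "list"))

setValidity("NormativeModel", function(object) {
  E <- length(object@edgeI)
  if (length(object@edgeJ) != E || length(object@mean) != E ||
      length(object@sd) != E || length(object@excluded) != E)
    return("edge vectors must have equal length")
  P <- length(object@parcelIds)
  if (E != P * (P - 1) / 2)
    return("edge count must be P*(P-1)/2")
  if (any(object@edgeI >= object@edgeJ))
    return("edges must satisfy i < j")
  frac <- object@metadata$exclusionFraction
  if (is.null(frac)) frac <- 1 / 3
  if (E > 0 && sum(object@excluded) != ceiling(E * frac))
    return("excluded count must be ceiling(E * exclusionFraction)")
  if (any(object@sd[!object@excluded] <= 0))
    return("SD must be positive on all non-excluded edges")
  TRUE
})

#' Edge-level anomaly calls for one subject
#'
#' Signed z-scores against the normative model and a four-level flag per
#' edge: \code{hyper} (z > sigma), \code{hypo} (z < -sigma), \code{normal},
#' or \code{excluded} (variance-masked or outside the networks in scope;
#' z is retained for audit where it was computed).
#'
#' @slot edgeI,edgeJ integer parcel indices (1-based, i < j).
#' @slot z numeric z-scores (NA on variance-excluded edges).
#' @slot flag character, one of hyper/hypo/normal/excluded.
#' @slot sigma the threshold used (default 3).
#' @slot parcelIds parcel identifiers.
#' @slot networksInScope network labels the matrix is restricted to
#'   (character(0) = no restriction).
#' @slot metadata provenance list.
#' @export
setClass("AnomalyMatrix",
  representation(edgeI = "integer", edgeJ = "integer", z = "numeric",
                 flag = "character", sigma = "numeric",
                 parcelIds = "character", networksInScope = "character",
                 metadata = "list"))

setValidity("AnomalyMatrix", function(object) {
  E <- length(object@edgeI)
  if (length(object@edgeJ) != E || length(object@z) != E ||
      length(object@flag) != E)
    return("edge vectors must have equal length")
  if (!all(object@flag %in% c("hyper", "hypo", "normal", "excluded")))
    return("flags must be hyper, hypo, normal or excluded")
  s <- object@sigma
  act <- object@flag != "excluded"
  z <- object@z[act]
  f <- object@flag[act]
  if (anyNA(z)) return("non-excluded edges must carry a z-score")
  bad <- (f == "hyper" & z <= s) | (f == "hypo" & z >= -s) |
         (f == "normal" & abs(z) > s)
  if (any(bad)) return("flags inconsistent with z at the stated sigma")
  TRUE
})

#' Ranked stimulation target prescription
#'
#' @slot targets data.frame with columns parcel_id, protocol, hyper_count,
#'   hypo_count, total_burden, depth_mm, network, rank (at most
#'   \code{parameters$max_targets} rows).
#' @slot parameters list of selection parameters (max_targets, depth_max,
#'   min_burden, tie rule).
#' @slot reason machine-readable reason when the prescription is empty
#'   (\code{""} otherwise).
#' @export
setClass("TargetPrescription",
  representation(targets = "data.frame", parameters = "list",
                 reason = "character"))

setValidity("TargetPrescription", function(object) {
  tg <- object@targets
  need <- c("parcel_id", "protocol", "hyper_count", "hypo_count",
            "total_burden", "depth_mm", "network", "rank")
  if (!all(need %in% names(tg)))
    return(paste("targets must have columns:", paste(need, collapse = ", ")))
  mx <- object@parameters$max_targets
  if (!is.null(mx) && nrow(tg) > mx)
    return("more targets than parameters$max_targets")
  if (nrow(tg) && !all(tg$protocol %in% c("cTBS", "iTBS")))
    return("protocol must be cTBS or iTBS")
  dmax <- object@parameters$depth_max
  if (!is.null(dmax) && nrow(tg) && any(tg$depth_mm > dmax))
    return("target depth exceeds parameters$depth_max")
  TRUE
})

#' Theta-burst pulse train
#'
#' Pulse onset times (seconds from protocol start) for one iTBS or cTBS
#' application: three-pulse 50-Hz bursts repeated every 200 ms (5 Hz), in
#' 2-s trains with 6.3-s inter-train intervals for iTBS, or one continuous
#' train for cTBS.
#'
#' @slot protocol "iTBS" or "cTBS".
#' @slot pulseTimes strictly increasing pulse onsets, seconds.
#' @slot totalPulses pulse count.
#' @slot duration protocol span in seconds (start of first burst to end of
#'   the last train).
#' @slot params the parameter list used (see \code{\link{tbsParams}}).
#' @export
setClass("TBSProtocol",
  representation(protocol = "character", pulseTimes = "numeric",
                 totalPulses = "integer", duration = "numeric",
                 params = "list"))

setValidity("TBSProtocol", function(object) {
  if (!object@protocol %in% c("iTBS", "cTBS"))
    return("protocol must be iTBS or cTBS")
  pt <- object@pulseTimes
  if (length(pt) != object@totalPulses)
    return("totalPulses must equal length(pulseTimes)")
  if (length(pt) > 1 && any(diff(pt) <= 0))
    return("pulse times must be strictly increasing")
  if (length(pt) && pt[length(pt)] > object@duration + 1e-9)
    return("last pulse beyond stated duration")
  TRUE
})

## ---- accessors ----

#' @rdname parcelTBS-generics
#' @export
setMethod("parcelIds", "TimeSeriesMatrix", function(x) x@parcelIds)
#' @rdname parcelTBS-generics
#' @export
setMethod("parcelIds", "ConnectivityMatrix", function(x) x@parcelIds)
#' @rdname parcelTBS-generics
#' @export
setMethod("parcelIds", "TangentMatrix", function(x) x@parcelIds)
#' @rdname parcelTBS-generics
#' @export
setMethod("parcelIds", "NormativeModel", function(x) x@parcelIds)
#' @rdname parcelTBS-generics
#' @export
setMethod("parcelIds", "AnomalyMatrix", function(x) x@parcelIds)

#' @rdname parcelTBS-generics
#' @export
setMethod("values", "TimeSeriesMatrix", function(x) x@values)
#' @rdname parcelTBS-generics
#' @export
setMethod("values", "ConnectivityMatrix", function(x) x@values)
#' @rdname parcelTBS-generics
#' @export
setMethod("values", "TangentMatrix", function(x) x@values)

#' @rdname parcelTBS-generics
#' @export
setMethod("frameMask", "TimeSeriesMatrix", function(x) x@frameMask)

#' @rdname parcelTBS-generics
#' @export
setMethod("nParcels", "TimeSeriesMatrix", function(x) nrow(x@values))
#' @rdname parcelTBS-generics
#' @export
setMethod("nParcels", "ConnectivityMatrix", function(x) nrow(x@values))
#' @rdname parcelTBS-generics
#' @export
setMethod("nParcels", "TangentMatrix", function(x) nrow(x@values))
#' @rdname parcelTBS-generics
#' @export
setMethod("nParcels", "NormativeModel", function(x) length(x@parcelIds))
#' @rdname parcelTBS-generics
#' @export
setMethod("nParcels", "AnomalyMatrix", function(x) length(x@parcelIds))

#' @rdname parcelTBS-generics
#' @export
setMethod("edgeTable", "NormativeModel", function(x) {
  data.frame(edge_i = x@edgeI, edge_j = x@edgeJ, mean = x@mean, sd = x@sd,
             excluded = x@excluded)
})

#' @rdname parcelTBS-generics
#' @export
setMethod("edgeTable", "AnomalyMatrix", function(x) {
  data.frame(edge_i = x@edgeI, edge_j = x@edgeJ, z = x@z, flag = x@flag)
})

#' Retained-frame submatrix of a time series
#'
#' @param ts a \linkS4class{TimeSeriesMatrix}
#' @return numeric matrix of retained columns only
#' @export
retainedValues <- function(ts) {
  stopifnot(is(ts, "TimeSeriesMatrix"))
  ts@values[, ts@frameMask, drop = FALSE]
}

## ---- show methods ----

setMethod("show", "TimeSeriesMatrix", function(object) {
  cat(sprintf("TimeSeriesMatrix: %d parcels x %d frames (%d retained)\n",
              nrow(object@values), ncol(object@values),
              sum(object@frameMask)))
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat(sprintf("ConnectivityMatrix (%s): %d x %d, %d entries, %d unique pairs\n",
              object@kind, nrow(object@values), ncol(object@values),
              length(object@values),
              nrow(object@values) * (nrow(object@values) - 1) / 2))
})

setMethod("show", "TangentMatrix", function(object) {
  cat(sprintf("TangentMatrix: %d x %d, reference '%s'\n",
              nrow(object@values), ncol(object@values), object@referenceId))
})

setMethod("show", "NormativeModel", function(object) {
  E <- length(object@edgeI)
  cat(sprintf(paste0("NormativeModel: %d parcels, %d edges ",
                     "(%d excluded as high-variance), n = %d reference subjects\n"),
              length(object@parcelIds), E, sum(object@excluded),
              object@nReference))
})

setMethod("show", "AnomalyMatrix", function(object) {
  tb <- table(factor(object@flag,
                     levels = c("hyper", "hypo", "normal", "excluded")))
  scope <- if (length(object@networksInScope))
    paste(object@networksInScope, collapse = "+") else "all networks"
  cat(sprintf("AnomalyMatrix (|z| > %g, %s): %d hyper, %d hypo, %d normal, %d excluded\n",
              object@sigma, scope, tb[["hyper"]], tb[["hypo"]],
              tb[["normal"]], tb[["excluded"]]))
})

setMethod("show", "TargetPrescription", function(object) {
  if (nrow(object@targets) == 0) {
    cat(sprintf("TargetPrescription: empty (%s)\n", object@reason))
  } else {
    cat(sprintf("TargetPrescription: %d target(s)\n", nrow(object@targets)))
    print(object@targets, row.names = FALSE)
  }
})

setMethod("show", "TBSProtocol", function(object) {
  cat(sprintf("TBSProtocol %s: %d pulses over %.1f s at %.0f%% RMT\n",
              object@protocol, object@totalPulses, object@duration,
              100 * object@params$intensity))
})
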