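#' Per-parcel anomaly burden
#'
#' Counts, for every parcel, the incident non-excluded edges flagged hyper
#' and hypo.  Summing either column over all parcels gives twice the number
#' of flagged edges (each edge has two endpoints).
#'
#' @param a an \linkS4class{AnomalyMatrix}.
#' @return data.frame with columns parcel_id, hyper_count, hypo_count,
#'   total_burden (one row per parcel, matrix order).
#' @export
anomalyBurden <- function(a) {
  stopifnot(is(a, "AnomalyMatrix"))
  P <- nParcels(a)
  hyper <- hypo <- integer(P)
  for (lvl in c("hyper", "hypo")) {
    sel <- a@flag == lvl
    cnt <- tabulate(c(a@edgeI[sel], a@edgeJ[sel]), nbins = P)
    if (lvl == "hyper") hyper <- cnt else hypo <- cnt
  }
  data.frame(parcel_id = a@parcelIds, hyper_count = hyper, hypo_count = hypo,
             total_burden = hyper + hypo, stringsAsFactors = FALSE)
}

#' Choose the stimulation protocol for a parcel
#'
#' cTBS (inhibitory) when the parcel is mostly hyperconnected, iTBS
#' (excitatory) when mostly hypo-connected.  An exact tie defaults to cTBS,
#' following the strong cTBS predominance in clinical use of this planning
#' rule (91\% of prescribed targets); the tie rule is configurable.
#'
#' @param hyperCount,hypoCount nonnegative incident anomaly counts, not both
#'   zero.
#' @param tie protocol assigned on an exact tie (default "cTBS").
#' @return "cTBS" or "iTBS".
#' @examples
#' assignProtocol(5, 1)  # "cTBS"
#' assignProtocol(0, 4)  # "iTBS"
#' @export
assignProtocol <- function(hyperCount, hypoCount, tie = "cTBS") {
  if (hyperCount < 0 || hypoCount < 0) stop("counts must be nonnegative")
  if (hyperCount == 0 && hypoCount == 0)
    stop("a parcel with no anomalies is not a stimulation candidate")
  if (hyperCount > hypoCount) "cTBS"
  else if (hyperCount < hypoCount) "iTBS"
  else tie
}

#' Select stimulation targets from anomaly burdens
#'
#' Candidates are cortical parcels (subcortical rows, identified by location
#' \code{"Subcortical"}, are never reachable by TMS) with total burden at
#' least \code{minBurden} and scalp depth at most \code{depthMax} mm.
#' Candidates are ranked by total burden descending, ties broken by hyper
#' count descending then parcel id ascending, and truncated to
#' \code{maxTargets}.
#'
#' @param burden data.frame from \code{\link{anomalyBurden}}.
#' @param atlas atlas data.frame covering every parcel in \code{burden}.
#' @param maxTargets prescription cap (default 3).
#' @param depthMax maximum target depth in mm (default 30, the effective
#'   field-strength limit).
#' @param minBurden minimum total burden to qualify (default 3).
#' @param tie tie protocol passed to \code{\link{assignProtocol}}.
#' @return a \linkS4class{TargetPrescription}; empty (with a machine-readable
#'   reason) when no parcel qualifies.
#' @export
selectTargets <- function(burden, atlas, maxTargets = 3, depthMax = 30,
                          minBurden = 3, tie = "cTBS") {
  validateAtlas(atlas)
  m <- match(burden$parcel_id, atlas$parcel_id)
  if (anyNA(m)) stop("burden table contains parcels absent from the atlas")
  cand <- cbind(burden, depth_mm = atlas$depth_mm[m],
                network = atlas$network[m], location = atlas$location[m])
  cand <- cand[cand$location != "Subcortical" &
                 cand$depth_mm <= depthMax &
                 cand$total_burden >= minBurden, , drop = FALSE]
  params <- list(max_targets = maxTargets, depth_max = depthMax,
                 min_burden = minBurden, tie = tie)
  if (nrow(cand) == 0)
    return(new("TargetPrescription",
               targets = data.frame(parcel_id = character(),
                                    protocol = character(),
                                    hyper_count = integer(),
                                    hypo_count = integer(),
                                    total_burden = integer(),
                                    depth_mm = numeric(),
                                    network = character(),
                                    rank = integer()),
               parameters = params, reason = "no_candidates"))
  cand <- cand[order(-cand$total_burden, -cand$hyper_count, cand$parcel_id), ,
               drop = FALSE]
  cand <- utils::head(cand, maxTargets)
  cand$protocol <- vapply(seq_len(nrow(cand)), function(r)
    assignProtocol(cand$hyper_count[r], cand$hypo_count[r], tie), "")
  cand$rank <- seq_len(nrow(cand))
  tg <- cand[, c("parcel_id", "protocol", "hyper_count", "hypo_count",
                 "total_burden", "depth_mm", "network", "rank")]
  rownames(tg) <- NULL
  new("TargetPrescription", targets = tg, parameters = params, reason = "")
}

#' Prescribe targets directly from an anomaly matrix
#'
#' Thin wrapper: burden computation followed by target selection.
#'
#' @param a an \linkS4class{AnomalyMatrix} (typically network-restricted).
#' @param atlas atlas data.frame.
#' @param ... passed to \code{\link{selectTargets}}.
#' @return a \linkS4class{TargetPrescription}.
#' @export
prescribeTargets <- function(a, atlas, ...) {
  selectTargets(anomalyBurden(a), atlas, ...)
}
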