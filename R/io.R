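#' Read and write parcellated time series as TSV
#'
#' Rows are parcels, columns timepoints; the header row carries frame
#' indices (f1, f2, ...) and the first column the parcel id.  The frame mask
#' travels in a companion single-column TSV (\code{<path>.mask.tsv}).
#' write -> read -> write round-trips are byte-identical.
#'
#' @param ts a \linkS4class{TimeSeriesMatrix}.
#' @param path output TSV path.
#' @return \code{writeTimeSeries}: the path, invisibly;
#'   \code{readTimeSeries}: a \linkS4class{TimeSeriesMatrix}.
#' @export
writeTimeSeries <- function(ts, path) {
  stopifnot(is(ts, "TimeSeriesMatrix"))
  df <- data.frame(parcel_id = ts@parcelIds, ts@values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("parcel_id", sprintf("f%d", seq_len(ncol(ts@values))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(retained = as.integer(ts@frameMask)),
                     paste0(path, ".mask.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeTimeSeries
#' @export
readTimeSeries <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  maskPath <- paste0(path, ".mask.tsv")
  mask <- if (file.exists(maskPath))
    as.logical(utils::read.delim(maskPath)$retained)
  else rep(TRUE, ncol(v))
  TimeSeriesMatrix(v, df$parcel_id, mask)
}

#' Read and write an atlas table as TSV
#'
#' @param atlas atlas data.frame (see \code{\link{syntheticAtlas}}).
#' @param path TSV path.
#' @return \code{writeAtlas}: the path, invisibly; \code{readAtlas}: a
#'   validated atlas data.frame.
#' @export
writeAtlas <- function(atlas, path) {
  validateAtlas(atlas)
  utils::write.table(atlas, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeAtlas
#' @export
readAtlas <- function(path) {
  validateAtlas(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Read and write a connectivity matrix as TSV
#'
#' Parcel ids form the header row and first column.
#'
#' @param m a \linkS4class{ConnectivityMatrix}.
#' @param path TSV path.
#' @param kind matrix kind used on read-back.
#' @return \code{writeConnectivity}: the path, invisibly;
#'   \code{readConnectivity}: a \linkS4class{ConnectivityMatrix}.
#' @export
writeConnectivity <- function(m, path) {
  stopifnot(is(m, "ConnectivityMatrix"))
  df <- data.frame(parcel_id = m@parcelIds, m@values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("parcel_id", m@parcelIds)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeConnectivity
#' @export
readConnectivity <- function(path, kind = "covariance") {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ConnectivityMatrix(as.matrix(df[, -1, drop = FALSE]), kind, df$parcel_id)
}

#' Persist a normative model (TSV edge table + JSON metadata)
#'
#' Writes \code{<path>} (edge_i, edge_j, mean, sd, excluded; 1-based
#' indices), \code{<path>.meta.json}, and \code{<path>.mean.tsv} holding the
#' reference Frechet mean.
#'
#' @param model a \linkS4class{NormativeModel}.
#' @param path TSV path.
#' @return \code{writeNormativeModel}: the path, invisibly;
#'   \code{readNormativeModel}: a \linkS4class{NormativeModel}.
#' @export
writeNormativeModel <- function(model, path) {
  stopifnot(is(model, "NormativeModel"))
  utils::write.table(edgeTable(model), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- c(model@metadata,
            list(nReference = model@nReference, parcelIds = model@parcelIds))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  writeConnectivity(model@referenceMean, paste0(path, ".mean.tsv"))
  invisible(path)
}

#' @rdname writeNormativeModel
#' @export
readNormativeModel <- function(path) {
  df <- utils::read.delim(path)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  ids <- meta$parcelIds
  meta$parcelIds <- NULL
  nRef <- meta$nReference
  meta$nReference <- NULL
  G <- readConnectivity(paste0(path, ".mean.tsv"), "regularized-covariance")
  new("NormativeModel", edgeI = as.integer(df$edge_i),
      edgeJ = as.integer(df$edge_j), mean = df$mean, sd = df$sd,
      excluded = as.logical(df$excluded), nReference = as.integer(nRef),
      parcelIds = as.character(ids), referenceMean = G, metadata = meta)
}

#' Persist an anomaly matrix as TSV
#'
#' Columns: edge_i, edge_j (1-based), z, flag.
#'
#' @param a an \linkS4class{AnomalyMatrix}.
#' @param path TSV path.
#' @param sigma,networks restored on read-back.
#' @return \code{writeAnomalies}: the path, invisibly;
#'   \code{readAnomalies}: an \linkS4class{AnomalyMatrix}.
#' @export
writeAnomalies <- function(a, path) {
  stopifnot(is(a, "AnomalyMatrix"))
  utils::write.table(edgeTable(a), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeAnomalies
#' @export
readAnomalies <- function(path, parcelIds, sigma = 3,
                          networks = character(0)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  new("AnomalyMatrix", edgeI = as.integer(df$edge_i),
      edgeJ = as.integer(df$edge_j), z = df$z, flag = df$flag, sigma = sigma,
      parcelIds = as.character(parcelIds), networksInScope = networks,
      metadata = list())
}

#' Write a prescription as JSON
#'
#' @param rx a \linkS4class{TargetPrescription}.
#' @param path JSON path.
#' @param patientId identifier recorded in the file.
#' @param seed seed provenance recorded in the file.
#' @return the path, invisibly.
#' @export
writePrescription <- function(rx, path, patientId = "patient", seed = NA) {
  stopifnot(is(rx, "TargetPrescription"))
  jsonlite::write_json(list(patient_id = patientId, targets = rx@targets,
                            parameters = rx@parameters, reason = rx@reason,
                            seed = seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a TBS protocol as JSON plus a pulse-timestamp CSV
#'
#' JSON carries pulse times in milliseconds, totals, duration and intensity;
#' the CSV (\code{<path>.pulses.csv}) is a flat device-agnostic export.
#'
#' @param protocol a \linkS4class{TBSProtocol}.
#' @param path JSON path.
#' @return the path, invisibly.
#' @export
writeProtocol <- function(protocol, path) {
  stopifnot(is(protocol, "TBSProtocol"))
  jsonlite::write_json(list(protocol = protocol@protocol,
                            pulse_times_ms = protocol@pulseTimes * 1000,
                            total_pulses = protocol@totalPulses,
                            duration_s = protocol@duration,
                            intensity_rmt = protocol@params$intensity),
                       path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(pulse_time_ms = protocol@pulseTimes * 1000),
                   paste0(path, ".pulses.csv"), row.names = FALSE)
  invisible(path)
}

#' Target table transcribed from the source cohort report
#'
#' Nineteen target/protocol rows (label, full name, anatomical location,
#' network, protocol, patient count, printed percentage, outside-dlPFC flag)
#' whose counts sum to 76 targets across 26 patients.  The table is carried
#' verbatim, including its internal oddity: the row labelled "L46 (iTBS)"
#' carries the full name "Right area 46".
#'
#' @return data.frame with 19 rows.
#' @export
table2Fixture <- function() {
  path <- system.file("extdata", "table2_targets.tsv", package = "parcelTBS",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 19, sum(df$n_patients) == 76)
  df
}

#' Summarize the target table
#'
#' Totals, per-protocol totals, per-label patient counts and percentages (one
#' decimal, matching the printed style).
#'
#' @param fixture data.frame from \code{\link{table2Fixture}}.
#' @return list with total, byProtocol, byLabel, and the fixture with a
#'   recomputed pct column.
#' @export
table2Report <- function(fixture = table2Fixture()) {
  need <- c("label", "protocol", "n_patients")
  if (!all(need %in% names(fixture))) stop("malformed fixture")
  total <- sum(fixture$n_patients)
  byProtocol <- tapply(fixture$n_patients, fixture$protocol, sum)
  byLabel <- tapply(fixture$n_patients, fixture$label, sum)
  fixture$pct_recomputed <- round(fixture$n_patients / total * 100, 1)
  list(total = total, byProtocol = byProtocol,
       byLabel = sort(byLabel, decreasing = TRUE), table = fixture)
}
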