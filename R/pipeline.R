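#' Pipeline configuration
#'
#' Collects every stage parameter with defaults that reproduce the planning
#' method's fixed constants: 3-sigma anomaly threshold after excluding the
#' highest-variance third of pairs, at most 3 targets no deeper than 30 mm,
#' and the accelerated 5 x 5 TBS schedule at 80\% RMT.
#'
#' @param spec a \code{\link{cohortSpec}} for the synthetic stage.
#' @param inject an \code{\link{injectionSpec}} for the simulated patient.
#' @param networks networks in scope for target selection.
#' @param dvarsSigma,compCorK,poolFraction DVARS scrubbing threshold and
#'   CompCor settings.
#' @param shrinkage covariance shrinkage.
#' @param frechetTol,frechetMaxIter Frechet-mean stopping rule.
#' @param sigma anomaly threshold in SD units.
#' @param exclusionFraction excluded high-variance edge fraction.
#' @param maxTargets,depthMax,minBurden,tieProtocol target-selection rule.
#' @param tbs a \code{\link{tbsParams}} list.
#' @param schedule a \code{\link{sessionSchedule}}.
#' @param interTargetPause seconds between targets within a session.
#' @param seed master seed.
#' @return config list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(spec = cohortSpec(),
                           inject = injectionSpec(),
                           networks = c("DMN", "CEN", "Salience"),
                           dvarsSigma = 2, compCorK = 5, poolFraction = 0.1,
                           shrinkage = 0.1, frechetTol = 1e-6,
                           frechetMaxIter = 50, sigma = 3,
                           exclusionFraction = 1 / 3, maxTargets = 3,
                           depthMax = 30, minBurden = 3,
                           tieProtocol = "cTBS", tbs = tbsParams(),
                           schedule = sessionSchedule(),
                           interTargetPause = 60, seed = 1L) {
  structure(as.list(environment()), class = "PipelineConfig")
}

#' Run the full planning pipeline
#'
#' Simulate (reference cohort, atlas, patient) -> preprocess -> connectivity
#' -> normative fit -> score -> network restriction -> target prescription ->
#' protocol construction -> reports.  All artifacts, a resolved-config
#' snapshot and the seed are written under \code{outDir}; deterministic
#' stages are bit-identical across reruns with the same config.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir output directory (created if missing); NULL skips writing.
#' @return invisible list: model, anomalies (full and restricted),
#'   prescription, session, course, and paths of written artifacts.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  spec <- config$spec
  atlas <- syntheticAtlas(spec)
  cohort <- generateReferenceCohort(spec)
  patient <- generatePatient(spec, config$inject)
  model <- buildNormativeModel(cohort, shrinkage = config$shrinkage,
                               dvarsSigma = config$dvarsSigma,
                               compCorK = config$compCorK,
                               poolFraction = config$poolFraction,
                               exclusionFraction = config$exclusionFraction,
                               tol = config$frechetTol,
                               maxIter = config$frechetMaxIter)
  anomalies <- scorePatient(patient, model, sigma = config$sigma)
  restricted <- restrictNetworks(anomalies, atlas, config$networks)
  rx <- prescribeTargets(restricted, atlas, maxTargets = config$maxTargets,
                         depthMax = config$depthMax,
                         minBurden = config$minBurden,
                         tie = config$tieProtocol)
  session <- if (nrow(rx@targets))
    buildSession(rx, config$tbs, config$interTargetPause) else NULL
  course <- if (!is.null(session))
    buildCourse(config$schedule, session$duration) else NULL
  out <- list(atlas = atlas, model = model, anomalies = anomalies,
              restricted = restricted, prescription = rx, session = session,
              course = course)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outDir, f)
    writeAtlas(atlas, p("atlas.tsv"))
    writeTimeSeries(patient, p("patient.tsv"))
    writeNormativeModel(model, p("normative_model.tsv"))
    writeAnomalies(anomalies, p("anomalies.tsv"))
    writeAnomalies(restricted, p("anomalies_restricted.tsv"))
    renderAnomalyHeatmap(restricted, p("anomaly_heatmap.png"))
    writePrescription(rx, p("prescription.json"), seed = config$seed)
    if (!is.null(session)) {
      for (k in seq_along(session$protocols))
        writeProtocol(session$protocols[[k]],
                      p(sprintf("protocol_target%d.json", k)))
      utils::write.csv(session$schedule, p("session_schedule.csv"),
                       row.names = FALSE)
      utils::write.csv(course, p("course_calendar.csv"), row.names = FALSE)
    }
    snapshot <- config
    snapshot$spec <- unclass(spec)
    snapshot$inject <- list(edges = config$inject$edges,
                            seed = config$inject$seed)
    snapshot$tbs <- unclass(config$tbs)
    snapshot$schedule <- unclass(config$schedule)
    jsonlite::write_json(lapply(unclass(snapshot), function(x)
      if (is.function(x)) NULL else x), p("config_resolved.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE)
    out$paths <- list.files(outDir, full.names = TRUE)
  }
  invisible(out)
}
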