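#' Theta-burst stimulation parameters
#'
#' Defaults reproduce the treatment protocol: three-pulse 50-Hz bursts
#' repeated every 200 ms (5 Hz), iTBS as 40 two-second trains with a 6.3-s
#' inter-train interval (1200 pulses), cTBS as one continuous train of 600
#' bursts (1800 pulses), at 80\% of the resting motor threshold.  The 2-s
#' iTBS train duration is not free: it is forced by 1200 pulses / 40 trains /
#' 3 pulses per burst at 5 Hz.
#'
#' \code{ctbsMode = "conventional"} switches cTBS to the field-standard
#' 200-burst / 600-pulse variant; \code{"paper"} keeps the printed totals
#' (600 three-pulse bursts).
#'
#' @param pulsesPerBurst pulses in a burst (default 3).
#' @param intraBurstFrequency Hz within a burst (default 50).
#' @param burstPeriod seconds between burst onsets (default 0.2).
#' @param trainDuration iTBS train length, seconds (default 2).
#' @param nTrains iTBS train count (default 40).
#' @param interTrainInterval iTBS gap between trains, seconds (default 6.3).
#' @param nBurstsCtbs cTBS burst count in paper mode (default 600).
#' @param ctbsMode "paper" or "conventional".
#' @param intensity fraction of resting motor threshold in (0, 1]
#'   (default 0.8).
#' @return validated parameter list of class \code{TBSParams}.
#' @export
tbsParams <- function(pulsesPerBurst = 3, intraBurstFrequency = 50,
                      burstPeriod = 0.2, trainDuration = 2, nTrains = 40,
                      interTrainInterval = 6.3, nBurstsCtbs = 600,
                      ctbsMode = c("paper", "conventional"),
                      intensity = 0.8) {
  ctbsMode <- match.arg(ctbsMode)
  vals <- c(pulsesPerBurst, intraBurstFrequency, burstPeriod, trainDuration,
            nTrains, interTrainInterval, nBurstsCtbs)
  if (any(vals <= 0)) stop("all protocol parameters must be positive")
  if (intensity <= 0 || intensity > 1)
    stop("intensity must be a fraction of RMT in (0, 1]")
  burstSpan <- (pulsesPerBurst - 1) / intraBurstFrequency
  if (burstSpan >= burstPeriod)
    stop("a burst (", burstSpan, " s) must fit inside the burst period (",
         burstPeriod, " s)")
  nBurstsPerTrain <- trainDuration / burstPeriod
  if (abs(nBurstsPerTrain - round(nBurstsPerTrain)) > 1e-9)
    stop("trainDuration must be a whole number of burst periods ",
         "(burstPeriod * bursts/train must equal trainDuration)")
  structure(list(pulsesPerBurst = as.integer(pulsesPerBurst),
                 intraBurstFrequency = intraBurstFrequency,
                 burstPeriod = burstPeriod, trainDuration = trainDuration,
                 nTrains = as.integer(nTrains),
                 interTrainInterval = interTrainInterval,
                 nBurstsCtbs = as.integer(if (ctbsMode == "paper")
                   nBurstsCtbs else 200),
                 ctbsMode = ctbsMode, intensity = intensity),
            class = "TBSParams")
}

# Pulse onsets of one burst starting at time t0.
.burstPulses <- function(t0, params) {
  t0 + (seq_len(params$pulsesPerBurst) - 1) / params$intraBurstFrequency
}

#' Build an intermittent theta-burst (iTBS) pulse train
#'
#' Per train, \code{trainDuration / burstPeriod} bursts of
#' \code{pulsesPerBurst} pulses; trains separated by the inter-train
#' interval.  Defaults give 40 trains x 30 pulses = 1200 pulses over a
#' 40 x 2 + 39 x 6.3 = 325.7-s span.
#'
#' @param params a \code{\link{tbsParams}} list.
#' @return a \linkS4class{TBSProtocol}.
#' @export
buildITBS <- function(params = tbsParams()) {
  stopifnot(inherits(params, "TBSParams"))
  nB <- round(params$trainDuration / params$burstPeriod)
  trainOnsets <- (seq_len(params$nTrains) - 1) *
    (params$trainDuration + params$interTrainInterval)
  burstOnsets <- as.vector(vapply(trainOnsets, function(t0)
    t0 + (seq_len(nB) - 1) * params$burstPeriod, numeric(nB)))
  pulses <- as.vector(vapply(burstOnsets, .burstPulses,
                             numeric(params$pulsesPerBurst), params = params))
  duration <- trainOnsets[length(trainOnsets)] + params$trainDuration
  new("TBSProtocol", protocol = "iTBS", pulseTimes = sort(pulses),
      totalPulses = length(pulses), duration = duration,
      params = unclass(params))
}

#' Build a continuous theta-burst (cTBS) pulse train
#'
#' One uninterrupted train of \code{nBurstsCtbs} bursts at 5 Hz.  Paper mode
#' (600 bursts) gives 1800 pulses over 120 s; conventional mode gives the
#' 200-burst / 600-pulse variant.
#'
#' @param params a \code{\link{tbsParams}} list.
#' @return a \linkS4class{TBSProtocol}.
#' @export
buildCTBS <- function(params = tbsParams()) {
  stopifnot(inherits(params, "TBSParams"))
  burstOnsets <- (seq_len(params$nBurstsCtbs) - 1) * params$burstPeriod
  pulses <- as.vector(vapply(burstOnsets, .burstPulses,
                             numeric(params$pulsesPerBurst), params = params))
  new("TBSProtocol", protocol = "cTBS", pulseTimes = sort(pulses),
      totalPulses = length(pulses),
      duration = params$nBurstsCtbs * params$burstPeriod,
      params = unclass(params))
}

#' Assemble one treatment session from a prescription
#'
#' Targets are stimulated in rank order; their protocols are concatenated
#' with a configurable pause between targets.
#'
#' @param rx a non-empty \linkS4class{TargetPrescription}.
#' @param params a \code{\link{tbsParams}} list.
#' @param interTargetPause seconds between consecutive targets (default 60).
#' @return list with \code{protocols} (one \linkS4class{TBSProtocol} per
#'   target), \code{schedule} (data.frame: parcel_id, protocol, start_s,
#'   end_s), \code{duration} (seconds) and \code{totalPulses}.
#' @export
buildSession <- function(rx, params = tbsParams(), interTargetPause = 60) {
  stopifnot(is(rx, "TargetPrescription"))
  tg <- rx@targets
  if (nrow(tg) == 0) stop("cannot build a session from an empty prescription")
  tg <- tg[order(tg$rank), , drop = FALSE]
  protocols <- lapply(tg$protocol, function(p)
    if (p == "iTBS") buildITBS(params) else buildCTBS(params))
  starts <- ends <- numeric(nrow(tg))
  t0 <- 0
  for (k in seq_len(nrow(tg))) {
    starts[k] <- t0
    ends[k] <- t0 + protocols[[k]]@duration
    t0 <- ends[k] + interTargetPause
  }
  list(protocols = protocols,
       schedule = data.frame(parcel_id = tg$parcel_id,
                             protocol = tg$protocol, start_s = starts,
                             end_s = ends, stringsAsFactors = FALSE),
       duration = ends[nrow(tg)],
       totalPulses = sum(vapply(protocols, function(p) p@totalPulses, 1L)))
}

#' Accelerated session schedule
#'
#' @param sessionsPerDay sessions per day (default 5).
#' @param nDays treatment days (default 5).
#' @param interSessionGapH gap between the end of one session and the start
#'   of the next, hours (default 1).
#' @param dayLengthH available hours per day (default 12).
#' @return validated schedule list of class \code{SessionSchedule}.
#' @export
sessionSchedule <- function(sessionsPerDay = 5, nDays = 5,
                            interSessionGapH = 1, dayLengthH = 12) {
  if (sessionsPerDay <= 0 || nDays <= 0 || interSessionGapH <= 0)
    stop("schedule counts and gaps must be positive")
  structure(list(sessionsPerDay = as.integer(sessionsPerDay),
                 nDays = as.integer(nDays),
                 interSessionGapH = interSessionGapH,
                 dayLengthH = dayLengthH),
            class = "SessionSchedule")
}

#' Lay out the full treatment course
#'
#' Defaults give 25 sessions: five per day for five days, consecutive
#' same-day starts separated by the session duration plus a 1-h gap.
#'
#' @param schedule a \code{\link{sessionSchedule}}.
#' @param sessionDuration duration of one session in seconds.
#' @return data.frame with columns day, session, start_s (seconds from the
#'   start of each day).
#' @export
buildCourse <- function(schedule = sessionSchedule(), sessionDuration) {
  stopifnot(inherits(schedule, "SessionSchedule"))
  if (sessionDuration <= 0) stop("sessionDuration must be positive")
  step <- sessionDuration + schedule$interSessionGapH * 3600
  lastEnd <- (schedule$sessionsPerDay - 1) * step + sessionDuration
  if (lastEnd > schedule$dayLengthH * 3600)
    stop("day too short for ", schedule$sessionsPerDay, " sessions of ",
         round(sessionDuration), " s with ", schedule$interSessionGapH,
         "-h gaps")
  expand <- expand.grid(session = seq_len(schedule$sessionsPerDay),
                        day = seq_len(schedule$nDays))
  data.frame(day = expand$day, session = expand$session,
             start_s = (expand$session - 1) * step)
}
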