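#' Classify treatment response (Riedel rule)
#'
#' Response is a decrease of at least 47\% from the BDI baseline:
#' \code{(baseline - later) / baseline >= 0.47}.
#'
#' @param baseline BDI baseline score(s), > 0 (percent change is undefined at
#'   0).
#' @param later BDI score(s) at the later timepoint.
#' @return logical vector.
#' @examples
#' classifyResponse(25, 12)  # TRUE  (52% decrease)
#' classifyResponse(25, 14)  # FALSE (44%)
#' @export
classifyResponse <- function(baseline, later) {
  .checkBdi(baseline); .checkBdi(later)
  if (any(baseline == 0, na.rm = TRUE))
    stop("percent change is undefined at a baseline of 0")
  (baseline - later) / baseline >= 0.47
}

#' Classify remission (Riedel rule)
#'
#' Remission is a BDI score of 12 or below (boundary inclusive).
#'
#' @param score BDI score(s) in [0, 63].
#' @return logical vector.
#' @export
classifyRemission <- function(score) {
  .checkBdi(score)
  score <= 12
}

#' BDI-II severity band
#'
#' 0-13 minimal, 14-19 mild, 20-28 moderate, 29-63 severe.
#'
#' @param score BDI score(s) in [0, 63] (non-integers allowed, e.g. a cohort
#'   mean).
#' @return character vector.
#' @examples
#' severityBand(25.2)  # "moderate"
#' @export
severityBand <- function(score) {
  .checkBdi(score)
  cut(score, breaks = c(-Inf, 13, 19, 28, Inf),
      labels = c("minimal", "mild", "moderate", "severe"),
      right = TRUE) |> as.character()
}

.checkBdi <- function(score) {
  if (any(score < 0 | score > 63, na.rm = TRUE))
    stop("BDI scores must lie in [0, 63]")
  invisible(score)
}

#' Validate a table of outcome records
#'
#' @param records data.frame in the \code{\link{generateOutcomes}} format.
#' @return the records, invisibly.
#' @export
validateOutcomes <- function(records) {
  need <- c("patient_id", "bdi_baseline", "bdi_post", "bdi_followup",
            "eq5d_baseline", "eq5d_post", "eq5d_followup")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("outcome records missing columns: ", paste(miss, collapse = ", "))
  if (anyNA(records$bdi_baseline)) stop("baseline BDI must be present")
  .checkBdi(records$bdi_baseline); .checkBdi(records$bdi_post)
  .checkBdi(records$bdi_followup)
  eq <- c(records$eq5d_baseline, records$eq5d_post, records$eq5d_followup)
  if (any(eq < -1 | eq > 1, na.rm = TRUE))
    stop("EQ-5D indices must lie in [-1, 1]")
  invisible(records)
}

#' Cohort outcome summary
#'
#' Response and remission rates directly after treatment (denominator: all
#' patients) and at follow-up (denominator: follow-up completers only), plus
#' mean/SD per instrument and timepoint.
#'
#' @param records validated outcome records data.frame.
#' @return list of class \code{CohortSummary}: n, nFollowUp, rates, and a
#'   stats data.frame.
#' @export
summarizeCohort <- function(records) {
  validateOutcomes(records)
  n <- nrow(records)
  fu <- !is.na(records$bdi_followup)
  msd <- function(x) c(mean = mean(x, na.rm = TRUE),
                       sd = stats::sd(x, na.rm = TRUE))
  stats <- rbind(
    bdi_baseline = msd(records$bdi_baseline),
    bdi_post = msd(records$bdi_post),
    bdi_followup = msd(records$bdi_followup),
    eq5d_baseline = msd(records$eq5d_baseline),
    eq5d_post = msd(records$eq5d_post),
    eq5d_followup = msd(records$eq5d_followup))
  structure(list(
    n = n, nFollowUp = sum(fu),
    responseRatePost = mean(classifyResponse(records$bdi_baseline,
                                             records$bdi_post)),
    remissionRatePost = mean(classifyRemission(records$bdi_post)),
    responseRateFu = if (any(fu))
      mean(classifyResponse(records$bdi_baseline[fu],
                            records$bdi_followup[fu])) else NA_real_,
    remissionRateFu = if (any(fu))
      mean(classifyRemission(records$bdi_followup[fu])) else NA_real_,
    stats = as.data.frame(stats)), class = "CohortSummary")
}

#' @export
print.CohortSummary <- function(x, ...) {
  cat(sprintf("Cohort of %d patients (%d with follow-up)\n", x$n,
              x$nFollowUp))
  cat(sprintf("  post:      response %.0f%%, remission %.0f%%\n",
              100 * x$responseRatePost, 100 * x$remissionRatePost))
  cat(sprintf("  follow-up: response %.0f%%, remission %.0f%%\n",
              100 * x$responseRateFu, 100 * x$remissionRateFu))
  print(round(x$stats, 2))
  invisible(x)
}

#' Mann-Whitney rank-sum test
#'
#' U statistic for the first group with an exact two-sided p-value by
#' complete enumeration of group assignments whenever both groups have at
#' most \code{exactMax} observations (ties handled by mid-ranks), and the
#' tie-corrected normal approximation with continuity correction otherwise.
#' The exact two-sided p is the probability, over all assignments, of a U at
#' least as far from its null mean as observed.
#'
#' @param groupA,groupB non-empty numeric vectors (e.g. BDI percent changes).
#' @param exactMax enumeration threshold per group (default 8).
#' @return list with \code{U}, \code{p}, and \code{method} ("exact" or
#'   "normal-approximation").
#' @examples
#' rankSumTest(c(1, 2, 3), c(10, 11, 12))  # U = 0, exact p = 0.1
#' @export
rankSumTest <- function(groupA, groupB, exactMax = 8) {
  if (length(groupA) == 0 || length(groupB) == 0)
    stop("both groups must be non-empty")
  n1 <- length(groupA); n2 <- length(groupB)
  pooled <- c(groupA, groupB)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= exactMax && n2 <= exactMax) {
    sets <- utils::combn(n1 + n2, n1)
    Uall <- colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Uall - mu) >= abs(U - mu) - 1e-12)
    method <- "exact"
  } else {
    N <- n1 + n2
    ties <- table(pooled)
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal-approximation"
  }
  list(U = U, p = p, method = method)
}

#' Compare BDI percent change between TRD and non-TRD patients
#'
#' Percent reduction \code{(baseline - later) / baseline * 100} is computed
#' per patient (complete cases at the chosen timepoint) and compared between
#' the treatment-resistant and non-resistant groups with
#' \code{\link{rankSumTest}}.  This deliberately replaces mixed-effects
#' modelling with a descriptive rank-based comparison.
#'
#' @param records outcome records with a logical \code{trd} column.
#' @param timepoint "post" or "followup".
#' @return \code{\link{rankSumTest}} result plus group sizes.
#' @export
compareTrd <- function(records, timepoint = c("post", "followup")) {
  timepoint <- match.arg(timepoint)
  validateOutcomes(records)
  if (is.null(records$trd)) stop("records need a logical 'trd' column")
  later <- if (timepoint == "post") records$bdi_post else records$bdi_followup
  ok <- !is.na(later) & records$bdi_baseline > 0
  pct <- (records$bdi_baseline[ok] - later[ok]) / records$bdi_baseline[ok] * 100
  trd <- records$trd[ok]
  res <- rankSumTest(pct[trd], pct[!trd])
  res$nTrd <- sum(trd)
  res$nNonTrd <- sum(!trd)
  res
}
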