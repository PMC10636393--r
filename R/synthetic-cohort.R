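#' Specification of a synthetic resting-state cohort
#'
#' Defines the generative model for reference subjects and patients: a latent
#' network-factor model in which every parcel loads on its network's latent
#' time series and carries parcel-specific noise.  The implied population
#' covariance is (with per-parcel amplitude \eqn{m_p} and noise scale
#' \eqn{\sigma}):
#' \deqn{Cov(x_p, x_q) = m_p m_q \sigma^2 \sqrt{w_k w_l}\, b_{kl}}
#' for parcels in networks \eqn{k \ne l}, \eqn{m_p m_q \sigma^2 w_k} within a
#' network, and \eqn{m_p^2 \sigma^2} on the diagonal, where \eqn{w_k} is the
#' within-network coupling and \eqn{b_{kl} = b} the between-network latent
#' correlation.  Per-subject, per-network coupling jitter gives true
#' between-subject edge variance; a deterministic subset of parcels (every
#' \code{1/noisyFraction}-th) carries a \code{noisyMultiplier} amplitude,
#' emulating high-variance susceptibility-artifact regions.
#'
#' Defaults mirror the acquisition the pipeline expects: 200 reference
#' subjects, 128 timepoints at a sampling interval of 2.8 s.  The default
#' parcel count is 60 (4 networks of 15) for fast testing; use 377 for
#' full-scale parity.
#'
#' @param nReference number of reference subjects (>= 2).
#' @param nTimepoints frames per run.
#' @param samplingInterval TR in seconds.
#' @param nParcels number of parcels.
#' @param networkPartition character vector of length \code{nParcels} with
#'   labels in \{DMN, CEN, Salience, Other\}; default: four equal consecutive
#'   blocks.
#' @param withinCoupling population correlation of same-network parcels,
#'   in [0, 1).
#' @param betweenCoupling correlation of network latents, in [0, 1).
#' @param noiseSd overall signal scale (> 0).
#' @param couplingJitterSd SD of the per-subject, per-network jitter added to
#'   \code{withinCoupling}.
#' @param noisyFraction fraction of parcels given amplified signal (set 0 to
#'   disable).
#' @param noisyMultiplier amplitude multiplier for noisy parcels.
#' @param arCoefMax maximum parcel AR(1) coefficient.  Each parcel p gets a
#'   fixed temporal-autocorrelation coefficient
#'   \code{arCoefMax * frac(p * golden ratio)} (a deterministic low-discrepancy
#'   sequence), emulating the regionally varying BOLD smoothness that makes
#'   some connectivity pairs genuinely noisier than others — the feature the
#'   highest-variance-third exclusion exists to absorb.  Set 0 for white
#'   noise.
#' @param zCalibration correlation-units-per-tangent-z calibration constant
#'   used by \code{\link{generatePatient}} to convert an injection magnitude
#'   (in normative z units) into a population correlation shift.  The default
#'   was fitted by Monte-Carlo at the default 60-parcel / 200-reference scale
#'   through the full preprocessing + tangent pipeline.
#' @param seed integer seed; all randomness of an operation flows from one
#'   generator seeded with it.
#' @return a \code{CohortSpec} list.
#' @examples
#' spec <- cohortSpec(nReference = 20, nParcels = 20, seed = 1)
#' cohort <- generateReferenceCohort(spec)
#' length(cohort)
#' @export
cohortSpec <- function(nReference = 200, nTimepoints = 128,
                       samplingInterval = 2.8, nParcels = 60,
                       networkPartition = NULL, withinCoupling = 0.3,
                       betweenCoupling = 0.2, noiseSd = 1,
                       couplingJitterSd = 0.05, noisyFraction = 0.1,
                       noisyMultiplier = 3, arCoefMax = 0.7,
                       zCalibration = 0.0667, seed = 1L) {
  if (nReference < 2) stop("nReference must be >= 2")
  if (withinCoupling < 0 || withinCoupling >= 1)
    stop("withinCoupling must be in [0, 1)")
  if (betweenCoupling < 0 || betweenCoupling >= 1)
    stop("betweenCoupling must be in [0, 1)")
  if (noiseSd <= 0)
    stop("noiseSd must be positive (zero-variance parcels are degenerate)")
  if (is.null(networkPartition)) {
    nets <- c("DMN", "CEN", "Salience", "Other")
    networkPartition <- rep(nets, each = ceiling(nParcels / 4))[seq_len(nParcels)]
  }
  if (length(networkPartition) != nParcels)
    stop("networkPartition must have one label per parcel")
  K <- length(unique(networkPartition))
  # K-network equicorrelation of latents is positive definite for
  # b in (-1/(K-1), 1); with b in [0, 1) it always is.
  multiplier <- rep(1, nParcels)
  if (noisyFraction > 0) {
    step <- max(2L, round(1 / noisyFraction))
    if (step <= nParcels)
      multiplier[seq(step, nParcels, by = step)] <- noisyMultiplier
  }
  if (arCoefMax < 0 || arCoefMax >= 1) stop("arCoefMax must be in [0, 1)")
  arCoef <- arCoefMax * ((seq_len(nParcels) * (sqrt(5) - 1) / 2) %% 1)
  rankDeficient <- nTimepoints <= nParcels
  if (rankDeficient)
    warning("nTimepoints <= nParcels: sample covariance is rank-deficient; ",
            "shrinkage regularization is mandatory before tangent embedding")
  structure(list(
    nReference = as.integer(nReference),
    nTimepoints = as.integer(nTimepoints),
    samplingInterval = samplingInterval,
    nParcels = as.integer(nParcels),
    networkPartition = as.character(networkPartition),
    withinCoupling = withinCoupling,
    betweenCoupling = betweenCoupling,
    noiseSd = noiseSd,
    couplingJitterSd = couplingJitterSd,
    noisyFraction = noisyFraction,
    noisyMultiplier = noisyMultiplier,
    arCoefMax = arCoefMax,
    arCoef = arCoef,
    multiplier = multiplier,
    zCalibration = zCalibration,
    rankDeficient = rankDeficient,
    seed = as.integer(seed)
  ), class = "CohortSpec")
}

# Per-subject network couplings: withinCoupling jittered per network,
# clamped away from the degenerate ends.
.drawCouplings <- function(spec, networks) {
  w <- spec$withinCoupling +
    stats::rnorm(length(networks), 0, spec$couplingJitterSd)
  stats::setNames(pmin(pmax(w, 0.02), 0.95), networks)
}

# Implied population covariance for one subject (see cohortSpec for the
# closed form).  `delta` is an optional list of injected edges.
.impliedCovariance <- function(spec, couplings, delta = NULL) {
  P <- spec$nParcels
  net <- spec$networkPartition
  sqw <- sqrt(couplings[net])            # per-parcel sqrt(w_k)
  R <- tcrossprod(sqw) * spec$betweenCoupling
  same <- outer(net, net, "==")
  Rw <- tcrossprod(sqw)                  # sqrt(w_k w_k) = w_k within a network
  R[same] <- Rw[same]
  diag(R) <- 1
  amp <- spec$multiplier * spec$noiseSd
  C <- R * tcrossprod(amp)
  if (!is.null(delta)) {
    for (d in delta) {
      shift <- d$shift * amp[d$i] * amp[d$j]   # correlation-scale -> covariance
      C[d$i, d$j] <- C[d$i, d$j] + shift
      C[d$j, d$i] <- C[d$i, d$j]
    }
  }
  C
}

# One subject from the latent network-factor model.
.factorSubject <- function(spec, id) {
  P <- spec$nParcels
  T <- spec$nTimepoints
  net <- spec$networkPartition
  networks <- unique(net)
  K <- length(networks)
  w <- .drawCouplings(spec, networks)
  SigF <- matrix(spec$betweenCoupling, K, K)
  diag(SigF) <- 1
  F <- matrix(stats::rnorm(T * K), T, K) %*% chol(SigF)  # T x K latents
  colnames(F) <- networks
  load <- sqrt(w[net])
  eps <- matrix(stats::rnorm(P * T), P, T)
  x <- (load * t(F[, net, drop = FALSE])) + sqrt(1 - w[net]) * eps
  x <- .arFilterRows(x, spec$arCoef)
  x <- x * (spec$multiplier * spec$noiseSd)
  dimnames(x) <- NULL
  TimeSeriesMatrix(x, metadata = list(subject = id, seed = spec$seed,
                                      samplingInterval = spec$samplingInterval,
                                      couplings = w))
}

#' Generate a normative reference cohort
#'
#' Draws \code{nReference} subjects from the latent network-factor model of
#' the spec.  Deterministic under a fixed seed.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @return list of \linkS4class{TimeSeriesMatrix}, length \code{nReference}.
#' @export
generateReferenceCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  set.seed(spec$seed)
  lapply(seq_len(spec$nReference),
         function(s) .factorSubject(spec, sprintf("ref%03d", s)))
}

#' Specify edge anomalies to inject into a patient
#'
#' @param edges data.frame with columns \code{i}, \code{j} (1-based parcel
#'   indices), \code{direction} ("hyper" or "hypo") and \code{magnitude}
#'   (target z-units in normative tangent space).
#' @param seed integer seed for the patient's randomness.
#' @return an \code{AnomalyInjectionSpec} list.
#' @export
injectionSpec <- function(edges = data.frame(i = integer(), j = integer(),
                                             direction = character(),
                                             magnitude = numeric()),
                          seed = 1L) {
  edges <- as.data.frame(edges)
  if (nrow(edges)) {
    if (any(edges$i == edges$j)) stop("self-edges cannot be injected")
    if (!all(edges$direction %in% c("hyper", "hypo")))
      stop("direction must be 'hyper' or 'hypo'")
    key <- paste(pmin(edges$i, edges$j), pmax(edges$i, edges$j))
    if (anyDuplicated(key)) stop("each unordered edge may be listed once")
    if (any(edges$magnitude == 0))
      warning("magnitude 0 injections are undetectable by construction")
  }
  structure(list(edges = edges, seed = as.integer(seed)),
            class = "AnomalyInjectionSpec")
}

#' Generate a patient with injected connectivity anomalies
#'
#' The patient is drawn from the multivariate normal law implied by the
#' latent-factor model (identical in distribution to a reference subject)
#' after shifting the population coupling of each injected edge by
#' \code{direction * magnitude * zCalibration} correlation units, so that the
#' edge's expected tangent-space z-score against the normative model is
#' approximately \code{magnitude} with the stated sign.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @param inject an \code{\link{injectionSpec}} (empty = null patient,
#'   statistically exchangeable with the reference cohort).
#' @return a \linkS4class{TimeSeriesMatrix} with the injection ground truth in
#'   its metadata.
#' @export
generatePatient <- function(spec, inject = injectionSpec()) {
  stopifnot(inherits(spec, "CohortSpec"),
            inherits(inject, "AnomalyInjectionSpec"))
  ed <- inject$edges
  if (nrow(ed) && (any(ed$i < 1) || any(pmax(ed$i, ed$j) > spec$nParcels)))
    stop("injected edges reference parcels outside the atlas")
  set.seed(inject$seed)
  networks <- unique(spec$networkPartition)
  w <- .drawCouplings(spec, networks)
  delta <- NULL
  if (nrow(ed)) {
    delta <- lapply(seq_len(nrow(ed)), function(r) {
      sgn <- if (ed$direction[r] == "hyper") 1 else -1
      # the injected shift is applied before AR(1) filtering, which
      # attenuates lag-0 correlation by psi = sqrt((1-pi^2)(1-pj^2))/(1-pipj);
      # the edge's normative SD also grows with its effective-dof loss,
      # ~ sqrt((1+pipj)/(1-pipj)).  Both are known, so one base constant
      # (zCalibration, fitted for white edges) serves every edge.
      pi <- spec$arCoef[min(ed$i[r], ed$j[r])]
      pj <- spec$arCoef[max(ed$i[r], ed$j[r])]
      psi <- sqrt((1 - pi^2) * (1 - pj^2)) / (1 - pi * pj)
      sdInflation <- sqrt((1 + pi * pj) / (1 - pi * pj))
      list(i = min(ed$i[r], ed$j[r]), j = max(ed$i[r], ed$j[r]),
           shift = sgn * ed$magnitude[r] * spec$zCalibration *
             sdInflation / psi)
    })
  }
  C <- .impliedCovariance(spec, w, delta)
  L <- tryCatch(chol(C), error = function(e)
    stop("injected shifts make the implied covariance non-positive-definite; ",
         "reduce the magnitude", call. = FALSE))
  Z <- matrix(stats::rnorm(spec$nParcels * spec$nTimepoints),
              spec$nParcels, spec$nTimepoints)
  x <- crossprod(L, Z)    # t(L) %*% Z has covariance C
  # same per-parcel temporal autocorrelation as the reference model; the
  # (multiplier-free) covariance is injected before filtering, matching the
  # reference subjects' generative order
  amp <- spec$multiplier * spec$noiseSd
  x <- .arFilterRows(x / amp, spec$arCoef) * amp
  TimeSeriesMatrix(x, metadata = list(
    subject = "patient", seed = inject$seed,
    samplingInterval = spec$samplingInterval, couplings = w,
    injected = ed, zCalibration = spec$zCalibration))
}

#' Synthetic parcel atlas with scalp geometry
#'
#' Builds a parcel table (id, name, hemisphere, anatomical location, network,
#' scalp depth in mm, centroid) matching a cohort spec.  Depths are drawn so
#' that parcels fall on both sides of the 30-mm targeting cutoff.  All
#' identifiers are synthetic.
#'
#' @param spec a \code{\link{cohortSpec}} (its partition defines networks).
#' @param depthRange cortical depth range in mm (must straddle 30).
#' @param seed integer seed for geometry.
#' @return data.frame with columns parcel_id, name, hemisphere, location,
#'   network, depth_mm, x, y, z.
#' @export
syntheticAtlas <- function(spec, depthRange = c(8, 38), seed = spec$seed) {
  stopifnot(inherits(spec, "CohortSpec"))
  if (depthRange[1] >= 30 || depthRange[2] <= 30)
    stop("depthRange must straddle the 30-mm cutoff")
  set.seed(seed)
  P <- spec$nParcels
  ids <- sprintf("P%03d", seq_len(P))
  hemi <- rep(c("L", "R"), length.out = P)
  loc <- paste("Synthetic cortical area", seq_len(P))
  depth <- stats::runif(P, depthRange[1], depthRange[2])
  # guarantee representation on both sides of the cutoff
  depth[1] <- min(depth[1], 25)
  depth[P] <- max(depth[P], 32)
  data.frame(parcel_id = ids,
             name = sprintf("%s%03dsyn", hemi, seq_len(P)),
             hemisphere = hemi, location = loc,
             network = spec$networkPartition, depth_mm = depth,
             x = stats::runif(P, -70, 70), y = stats::runif(P, -100, 70),
             z = stats::runif(P, -60, 80), stringsAsFactors = FALSE)
}

#' Full-parity synthetic atlas (377 areas)
#'
#' 180 cortical parcels per hemisphere plus 17 subcortical structures, the
#' area count of the HCP multi-modal parcellation with subcortex.  Labels and
#' geometry are synthetic; subcortical rows carry location "Subcortical" and
#' depths beyond TMS reach.
#'
#' @param seed integer seed for geometry.
#' @return atlas data.frame (377 rows) in the \code{\link{syntheticAtlas}}
#'   format.
#' @export
fullParityAtlas <- function(seed = 1L) {
  set.seed(seed)
  perHemi <- c(DMN = 45, CEN = 45, Salience = 30, Other = 60)
  cortNet <- rep(names(perHemi), perHemi)
  atlas <- do.call(rbind, lapply(c("L", "R"), function(h) {
    data.frame(parcel_id = sprintf("%s%03d", h, seq_len(180)),
               name = sprintf("%s%03dsyn", h, seq_len(180)),
               hemisphere = h,
               location = paste("Synthetic cortical area", seq_len(180)),
               network = cortNet,
               depth_mm = stats::runif(180, 8, 38),
               x = stats::runif(180, if (h == "L") -70 else 5,
                                if (h == "L") -5 else 70),
               y = stats::runif(180, -100, 70),
               z = stats::runif(180, -60, 80), stringsAsFactors = FALSE)
  }))
  sub <- data.frame(parcel_id = sprintf("SC%02d", seq_len(17)),
                    name = sprintf("SC%02dsyn", seq_len(17)),
                    hemisphere = rep(c("L", "R"), length.out = 17),
                    location = "Subcortical", network = "Other",
                    depth_mm = stats::runif(17, 40, 70),
                    x = stats::runif(17, -30, 30),
                    y = stats::runif(17, -40, 20),
                    z = stats::runif(17, -30, 20), stringsAsFactors = FALSE)
  rbind(atlas, sub)
}

#' Validate an atlas table
#'
#' @param atlas data.frame in the \code{\link{syntheticAtlas}} format.
#' @return the atlas, invisibly; errors describe the first violation.
#' @export
validateAtlas <- function(atlas) {
  need <- c("parcel_id", "name", "hemisphere", "location", "network",
            "depth_mm")
  miss <- setdiff(need, names(atlas))
  if (length(miss))
    stop("atlas is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(atlas$parcel_id)) stop("parcel_id must be unique")
  if (any(atlas$depth_mm < 0)) stop("depths must be nonnegative")
  invisible(atlas)
}

#' Generate synthetic outcome records
#'
#' BDI baselines are drawn from a truncated normal around the cohort mean
#' (default 25.2, SD 7.7, bounded to [0, 63]); post-treatment scores are
#' constructed so that the requested responder (>= 47\% decrease) and
#' remitter (BDI <= 12) fractions are met, with remitter-only status assigned
#' to the lowest baselines (a remitter who did not respond needs a modest
#' baseline) and response forcing remission whenever the baseline is too low
#' for a non-remitting response to exist.  Follow-up scores are built the
#' same way among completers.  EQ-5D indices stay in [-1, 1].
#'
#' @param nPatients cohort size.
#' @param responderFraction,remitterFraction requested post-treatment
#'   fractions, in [0, 1].
#' @param followUpLoss fraction of patients without follow-up, in [0, 1].
#' @param fuResponderFraction,fuRemitterFraction follow-up fractions among
#'   completers (default: same as post).
#' @param bdiMean,bdiSd baseline BDI distribution parameters.
#' @param eqMean,eqSd baseline EQ-5D distribution parameters.
#' @param trdFraction fraction flagged as treatment-resistant (>= 2 failed
#'   adequate antidepressant trials); the flag is carried as data.
#' @param seed integer seed.
#' @return data.frame of outcome records (one row per patient) with columns
#'   patient_id, bdi_baseline, bdi_post, bdi_followup, eq5d_baseline,
#'   eq5d_post, eq5d_followup, trd, followup_interval_months.
#' @export
generateOutcomes <- function(nPatients, responderFraction = 8 / 26,
                             remitterFraction = 16 / 26,
                             followUpLoss = 7 / 26,
                             fuResponderFraction = responderFraction,
                             fuRemitterFraction = remitterFraction,
                             bdiMean = 25.2, bdiSd = 7.7,
                             eqMean = 0.524, eqSd = 0.223,
                             trdFraction = 7 / 26, seed = 1L) {
  fr <- c(responderFraction, remitterFraction, followUpLoss,
          fuResponderFraction, fuRemitterFraction, trdFraction)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  set.seed(seed)
  n <- as.integer(nPatients)
  baseline <- round(.rtruncnorm(n, bdiMean, bdiSd, 1, 63))
  post <- .constructScores(baseline, round(responderFraction * n),
                           round(remitterFraction * n))
  completers <- sort(sample.int(n, n - round(followUpLoss * n)))
  fu <- rep(NA_real_, n)
  fu[completers] <- .constructScores(
    baseline[completers],
    round(fuResponderFraction * length(completers)),
    round(fuRemitterFraction * length(completers)))
  eqBase <- .rtruncnorm(n, eqMean, eqSd, -1, 1)
  lift <- ifelse(post <= 12, 0.2, 0.05) + stats::rnorm(n, 0, 0.05)
  eqPost <- pmin(pmax(eqBase + lift, -1), 1)
  eqFu <- rep(NA_real_, n)
  eqFu[completers] <- pmin(pmax(eqPost[completers] +
                                  stats::rnorm(length(completers), 0, 0.05),
                                -1), 1)
  trd <- rep(FALSE, n)
  trd[sample.int(n, round(trdFraction * n))] <- TRUE
  data.frame(patient_id = sprintf("pt%02d", seq_len(n)),
             bdi_baseline = baseline, bdi_post = post, bdi_followup = fu,
             eq5d_baseline = eqBase, eq5d_post = eqPost, eq5d_followup = eqFu,
             trd = trd,
             followup_interval_months =
               ifelse(seq_len(n) %in% completers,
                      pmax(1, round(stats::rnorm(n, 2.6, 1.2), 1)), NA),
             stringsAsFactors = FALSE)
}

# Construct later-timepoint BDI scores achieving the requested responder and
# remitter counts.  Response: score <= 0.53 * baseline (>= 47% decrease);
# remission: score <= 12.  Responders are made remitters first (the usual
# clinical overlap); remitter-only slots go to the lowest baselines, where a
# non-responding remission (0.53*b < score <= 12) exists.
.constructScores <- function(baseline, nResp, nRem) {
  n <- length(baseline)
  nBoth <- min(nResp, nRem)
  nRespOnly <- nResp - nBoth
  nRemOnly <- nRem - nBoth
  ord <- order(baseline)                  # ascending baseline
  lab <- rep("none", n)
  remOnlyPool <- ord[floor(0.53 * baseline[ord]) < 12]
  take <- utils::head(remOnlyPool, nRemOnly)
  if (length(take) < nRemOnly)
    warning("not enough low baselines for the requested remitter-only count; ",
            "remitter fraction will fall short")
  lab[take] <- "remit"
  respOnlyPool <- setdiff(rev(ord), take)  # descending baseline
  respOnlyPool <- respOnlyPool[floor(0.53 * baseline[respOnlyPool]) >= 13]
  take2 <- utils::head(respOnlyPool, nRespOnly)
  if (length(take2) < nRespOnly)
    warning("not enough high baselines for the requested responder-only ",
            "count; responder fraction will fall short")
  lab[take2] <- "resp"
  bothPool <- setdiff(seq_len(n), c(take, take2))
  lab[utils::head(bothPool, nBoth)] <- "both"
  pick <- function(v) if (length(v) == 1L) v else sample(v, 1L)
  score <- numeric(n)
  for (k in seq_len(n)) {
    b <- baseline[k]
    cut <- floor(0.53 * b)                # largest responding score
    score[k] <- switch(lab[k],
      both = pick(seq(0, min(12, cut))),                   # respond + remit
      resp = pick(seq(13, cut)),                           # respond, no remission
      remit = pick(seq(cut + 1, 12)),                      # remit, no response
      none = {
        lo <- min(max(cut + 1, 13), 63)
        pick(seq(lo, max(lo, min(63, b + 5))))
      })
  }
  score
}
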