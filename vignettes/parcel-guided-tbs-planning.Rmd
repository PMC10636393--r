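---
title: "Parcel-guided TBS planning from normative tangent-space connectivity"
author: "parcelTBS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parcel-guided TBS planning from normative tangent-space connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parcelTBS)
```

## The method

parcelTBS plans personalized theta-burst stimulation from parcellated
resting-state BOLD signal.  The pipeline has five stages.

**1. Parcel-level cleaning.**  Frames whose DVARS (root-mean-square
frame-to-frame signal change across parcels) exceeds the series mean plus
two standard deviations are scrubbed; the threshold is one-sided because
motion only inflates DVARS.  Each parcel is then detrended with an
intercept-linear-quadratic fit over retained frames, and CompCor-style
confounds — the top five principal components of the highest-variance decile
of parcels, a parcel-level surrogate for the voxel noise mask — are
regressed out together with an intercept.  Global signal regression is
deliberately not performed.  Finally each parcel is scaled to unit
retained-frame variance; the pipeline order (scrub, detrend, regress,
normalize) is fixed and asserted by the driver, because these operations do
not commute.  Scrubbed frames are dropped, not interpolated: covariance
estimation needs no temporal contiguity.

**2. Tangent-space embedding.**  Subject covariances (equal to correlations
after unit-variance normalization) are shrunk toward a scaled identity,
$(1-s)C + s\,\frac{\mathrm{tr}(C)}{P} I$ with $s = 0.1$ by default, which
guarantees the strict positive definiteness the matrix logarithm requires —
mandatory whenever fewer timepoints than parcels are available (the
full-scale 377-parcel case at 128 volumes).  The reference point is the
affine-invariant Fréchet mean $G$ of the reference cohort, found by the
standard fixed-point iteration
$G \leftarrow G^{1/2}\exp\big(\tfrac1S\sum_s \log(G^{-1/2} C_s
G^{-1/2})\big)G^{1/2}$, started at the arithmetic mean and stopped when the
Frobenius norm of the mean log term falls below $10^{-6}$ (at most 50
iterations; non-convergence is an error that carries the last residual).
Each subject is represented by
$T = \log\!\big(G^{-1/2}\, C\, G^{-1/2}\big)$, a symmetric matrix whose
entries admit edge-wise group statistics.  Covariances, not raw
correlations, enter the tangent map: the construction requires positive
definite inputs, and shrunk covariance embedding is the established tangent
connectivity pipeline.  Raw correlations remain available for reporting.

**3. Normative anomaly detection.**  Per upper-triangle edge, the mean and
sample SD (denominator $n-1$) across the 200-subject reference cohort are
estimated in tangent space — the space in which patients are scored.  Edges
are ranked by variance and the top $\lceil E/3\rceil$ (ties at the cutoff
broken by ascending edge index) are excluded as too noisy to carry a
normal range; exclusion is global, before any network restriction.  A
patient edge with $z = (t - \mu)/\sigma$ strictly above $+3$ is flagged
hyperconnected, strictly below $-3$ hypo-connected.  No further multiplicity
correction is applied: variance exclusion plus the 3-sigma rule *is* the
false-discovery control of this method.  Network restriction keeps an edge
only when both endpoints lie in the selected networks (default scope: DMN,
CEN, salience), mirroring per-network square anomaly matrices; passing
several labels retains their cross-edges.

**4. Target prescription.**  Each parcel's burden is its count of incident
flagged edges.  Candidates need a total burden of at least 3 (the method's
"numerous anomalies" is not quantified; the floor is configurable), must be
cortical, and must lie within 30 mm of the scalp — deeper targets are
outside the effective field of the coil.  Ranking is by total burden
descending, ties by hyper count descending then parcel id ascending, and
the prescription is capped at three targets.  Mostly hyperconnected parcels
receive inhibitory cTBS, mostly hypo-connected parcels excitatory iTBS; an
exact tie defaults to cTBS, following the overwhelming cTBS predominance
(69 of 76 targets, 91%) in the clinical cohort this rule comes from.

**5. Protocol construction.**  Both protocols use three-pulse 50-Hz bursts
repeated every 200 ms (5 Hz) at 80% of resting motor threshold.  iTBS
delivers 40 two-second trains (10 bursts each) with a 6.3-s inter-train
interval: 1200 pulses over 325.7 s.  The 2-s train duration is not stated
anywhere directly; it is forced by 1200 pulses / 40 trains / 3 pulses per
burst at 5 Hz, and the builder validates that consistency.  cTBS is one
continuous train; the printed description ("600 stimuli ... 1800 pulses")
is self-consistent only if the stimuli are bursts, so the default builds
600 three-pulse bursts (1800 pulses, 120 s), and
`tbsParams(ctbsMode = "conventional")` provides the field-standard
200-burst / 600-pulse variant.  Sessions stimulate targets in rank order
with a configurable 60-s pause (an implementation choice, not a clinical
parameter); the accelerated course is five sessions a day for five days
with one-hour gaps.

**Outcomes.**  Response is a BDI decrease of at least 47% from baseline;
remission is BDI $\le 12$ (boundary inclusive); severity bands follow
BDI-II conventions (0–13 minimal, 14–19 mild, 20–28 moderate, 29–63
severe).  Post-treatment rates use all patients as denominator, follow-up
rates only completers.  Group comparison of BDI percent change between
treatment-resistant and non-resistant patients uses a Mann–Whitney
rank-sum test: exact by complete enumeration whenever both groups have at
most eight observations (mid-ranks for ties), otherwise the tie-corrected
normal approximation with continuity correction.  Mixed-effects modelling
with multiple-comparison post hocs is deliberately replaced by descriptive
summaries plus this rank test: those are routine off-the-shelf statistics,
not part of the planning method, and the package's reports label the
substitution.  The treatment-resistance flag is taken as data (two or more
failed adequate antidepressant trials) rather than derived.

## The synthetic cohort

No patient scans ship with the package, so `cohortSpec()` defines a
generative model with the statistical structure the pipeline assumes, and
every stage is tested against it.

Reference subjects follow a latent network-factor model: each of four
networks (DMN, CEN, salience, other) has a unit-variance latent series,
latents of different networks correlate at `betweenCoupling` (default 0.2),
and a parcel in network $k$ is
$x_p = \sqrt{w_k}\, f_k + \sqrt{1-w_k}\,\varepsilon_p$, giving population
correlation $w_k$ (default 0.3) within a network and
$\sqrt{w_k w_l}\,b$ across networks.  Three features make the synthetic
data behave like real parcel series rather than white noise:

* **Per-subject coupling jitter** (SD 0.05 on $w_k$): real subjects differ
  in network coherence, so within-network edges carry true between-subject
  variance, not just sampling noise.
* **Amplified parcels**: every tenth parcel has three times the signal
  amplitude, emulating susceptibility-artifact regions; these parcels form
  a stable CompCor noise pool, and after confound regression their residual
  edges are noisy — exactly the edges the variance exclusion should absorb.
* **Heterogeneous temporal autocorrelation**: parcel $p$ has a fixed AR(1)
  coefficient $0.7\,\mathrm{frac}(p\,\varphi)$ ($\varphi$ the golden ratio
  — a deterministic low-discrepancy sequence), reflecting regionally
  varying BOLD smoothness.  Smoother pairs have fewer effective degrees of
  freedom, hence genuinely higher edge variance.  This matters: if all
  edges had identical true variance, the highest-variance-third exclusion
  would rank pure estimation noise and systematically keep edges whose SD
  is underestimated, inflating every downstream z-score.  With real
  heterogeneity the ranking reflects true variance and that selection bias
  is marginal.

Patients are drawn from the multivariate normal law this model implies
(identical in distribution to a reference subject), after shifting the
population coupling of each injected edge.  The injection magnitude is
expressed in normative z units and converted to a correlation shift by a
single calibration constant (`zCalibration = 0.0667`), fitted once by
Monte-Carlo through the full default pipeline — 60 parcels, 200 reference
subjects, preprocessing included — over random clean cross-network edges,
with a per-edge correction for the known AR(1) attenuation and SD
inflation.  At magnitude 5 the achieved z averages about 5 and recovery at
the 3-sigma threshold exceeds 95% in both directions; magnitude is
monotone in detection frequency.  Very large magnitudes on strongly
autocorrelated edges can make the implied covariance non-positive-definite,
which is an explicit error rather than a silent clip.  The calibration is
defined for clean cross-network edges at the default scale; other edge
classes (within-network, amplified-parcel) have different whitening gains
and are not calibrated.

Outcome records draw BDI baselines from a truncated normal (mean 25.2, SD
7.7 on the 0–63 scale — a moderate-depression cohort) and construct post
and follow-up scores to meet requested responder and remitter fractions.
A remission without response is only arithmetically possible at baselines
of 22 or below, so remitter-only status goes to the lowest baselines, and
the generator warns when a draw leaves too few of them — a feasibility
property of the Riedel rules themselves, not a bug.

**What the generator does not emulate**: voxel-level artifacts and their
spatial structure, hemodynamic response shape, physiological noise
spectra, scanner drift beyond a quadratic, site effects between reference
and patient data, and any real spatial geometry (atlas coordinates and
scalp depths are synthetic, with depths drawn to straddle the 30-mm
cutoff).  Passing tests therefore demonstrate the statistical correctness
of the pipeline's machinery, not clinical validity on scanner data.

## Numerical choices and problem sizes

* Default test scale is 60 parcels (4 x 15) with 200 reference subjects
  and 128 timepoints; a normative model builds in a few seconds, so the
  test suite and the examples run comfortably on one CPU.  The 377-parcel
  configuration is exercised for the bookkeeping identities (377 areas,
  142,129 matrix entries, 70,876 unique pairs, 23,626 excluded edges).
* Fréchet mean: tolerance $10^{-6}$ on the mean-log residual, cap 50
  iterations, arithmetic-mean start.  Commuting inputs recover the
  elementwise geometric mean to $10^{-8}$; a small-step manifold-descent
  oracle agrees to $10^{-4}$.
* Matrix functions use symmetric eigendecompositions; the test oracles use
  Denman–Beavers square roots with Mercator/Taylor series (inverse scaling
  and squaring), a fully independent route that agrees to $10^{-8}$.
* Exclusion ties are broken by ascending edge index; the 3-sigma rule uses
  strict inequalities; "one third" is $\lceil E/3 \rceil$ of the unordered
  pairs (self-pairs are not meaningful anomalies).
* On null patients the observed $|z|>3$ rate is slightly above the
  Gaussian nominal $0.0027$: the z denominator is a 200-subject sample SD
  (Student-type tails contribute about $0.003$), and variance exclusion
  retains a weak selection effect near its cutoff.  Both are properties of
  the prescribed procedure; the calibration test accounts for them within
  its Monte-Carlo band.
* 1-based parcel indices are used throughout, matching R convention, and
  serialized as such.

## Known limitations

* The calibration constant is specific to the default spec; changing
  couplings, timepoint counts or shrinkage requires re-running the
  Monte-Carlo calibration for quantitative injection magnitudes
  (directions and monotonicity are unaffected).
* The Fréchet fixed-point iteration is quadratic near the solution but
  slows for very dispersed cohorts; the log-Euclidean alternative was not
  implemented because the affine-invariant construction is the one the
  tangent-space literature standardizes on.
* `selectTargets()` identifies subcortical parcels by their atlas location
  label; an atlas that encodes subcortex differently must be adapted.
* Follow-up outcome scores are generated conditionally on the same label
  machinery as post scores; longitudinal within-patient correlation beyond
  that is not modelled.
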