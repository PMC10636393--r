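Package: parcelTBS
Title: Parcel-Guided Theta-Burst Stimulation Planning from Normative
    Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Plans personalized repetitive transcranial magnetic stimulation
    from parcellated resting-state BOLD time series. Subject connectivity is
    embedded in the tangent space of the positive-definite manifold at the
    Frechet mean of a normative reference cohort; edge-level anomalies are
    called as three-sigma outliers after excluding the highest-variance third
    of parcel pairs; anomalous parcels are ranked into at most three cortical
    stimulation targets (depth-limited to 30 mm) with continuous or
    intermittent theta-burst protocols assigned by the sign of their anomaly
    burden; full iTBS/cTBS pulse trains and an accelerated five-sessions-a-day,
    five-day schedule are constructed; and depression outcomes are classified
    with the Riedel response and remission rules for the Beck Depression
    Inventory. A synthetic-cohort module generates reference cohorts, patients
    with injected hyper- or hypo-connected edges of calibrated magnitude,
    parcel geometry, and outcome trajectories so the whole pipeline is
    testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1), methods
Imports:
    stats,
    utils,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils-internal.R'
    'synthetic-cohort.R'
    'preprocess.R'
    'connectivity.R'
    'normative.R'
    'targets.R'
    'tbs.R'
    'outcomes.R'
    'io.R'
    'pipeline.R'
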