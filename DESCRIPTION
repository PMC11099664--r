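Package: thalcort
Title: Multimodal Cortical Hotspot Mapping, Normative Seed Connectivity,
    and Thalamocortical Onset-Lag Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for locating a cortical convergence "hotspot" across
    co-registered group-level neuroimaging statistic maps (mirroring,
    intersection, Z-scoring, averaging, surface projection, geodesic
    smoothing, top-fraction thresholding and atlas-parcel ranking), for
    seed-based normative resting-state functional connectivity with
    Fisher r-to-Z transformation and group averaging, and for rule-based
    classification of cortico-thalamic onset lags in two-lead intracranial
    event recordings (band-pass envelope detection, per-channel
    standardization, top-scored event selection, onset-order summaries).
    A synthetic-data generator produces volumetric statistic maps,
    triangulated surface atlases, multi-subject time series with planted
    network structure, and multichannel event recordings with planted
    onsets, so every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    RNifti,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
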