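---
title: "Hotspot convergence mapping, normative connectivity and onset-lag analysis with thalcort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hotspot convergence mapping, normative connectivity and onset-lag analysis with thalcort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thalcort)
```

## What the package computes

`thalcort` implements three linked analyses for studying a severe
generalized epilepsy network (the Lennox–Gastaut phenotype) and for
planning dual thalamo-cortical neuromodulation:

1. **Convergence ("hotspot") mapping.** Several group-level statistic
   maps from different imaging modalities — an EEG-fMRI activation t-map,
   a PET hypometabolism t-map (unilateral, so it is mirrored), and six
   diffusion-MRI correlation maps relating tract connectivity to clinical
   benefit — are brought onto one grid, intersected, Z-scored, averaged,
   projected to a cortical surface, smoothed, and thresholded to the top
   5% of non-zero vertices. Parcels of a cortical atlas are ranked by the
   mean Z inside the thresholded map; the hotspot restricted to the
   top-ranked parcel is the *peak hotspot*.
2. **Normative seed connectivity.** The hotspot (and a centromedian
   thalamic mask) are used as seeds in a large healthy resting-state
   cohort: per subject, Pearson correlation of the mean seed time course
   with every brain voxel, Fisher-transformed (`z = atanh(r)`), then
   averaged across subjects. The question of interest is the *sign
   pattern*: the cortical-hotspot seed shows negative coupling with the
   centromedian region, and vice versa.
3. **Cortico-thalamic onset lags.** Two-lead intracranial event
   recordings are band-pass filtered, an envelope detector marks
   suprathreshold runs, per-lead onsets are compared, and each event is
   labelled *cortical-first*, *thalamic-first* or *simultaneous* using a
   0.25-s rule; the cohort is summarized as counts, percentages and the
   median cortical-lead lag.

Because the patient recordings and the normative cohort are not
distributable, the package ships a synthetic-data module that generates
all inputs with known ("planted") ground truth, so every stage is tested
by parameter recovery rather than by eye.

## The synthetic study conditions

The generator defaults define the conditions under which the test suite
and the reproduction script run. They were chosen once, to be small
enough for seconds-scale tests while preserving the statistical structure
each stage assumes.

| quantity | default | why |
|---|---|---|
| template grid | 32×32×32 voxels at 4 mm | smallest grid on which bumps, hemispheres and parcels are comfortably resolved |
| brain mask | ellipsoid, mirror-symmetric, ~10,000 voxels | symmetry is exact by construction, so mirroring can be tested to machine precision |
| hotspot | Gaussian bump, sigma ≈ 8 mm, unit peak, bilateral | a focal convergence zone; placed on the surface spheres so the mesh samples its peak |
| distractors | amplitude 0.5, modality-specific | make each map's structure partly private, as in real multimodal data |
| map noise | SD 0.3 | bump peak ≥ 3× noise SD, the documented operating point for parcel recovery |
| surface | two UV spheres, ~500 vertices each, 12 parcels | geodesic-Voronoi parcels stand in for an anatomical atlas |
| networks | A around the hotspots, B around deep centromedian-analog centres | two anticorrelated systems, r_within = 0.6, r_between = −0.3 |
| recordings | 250 Hz, 20 s, 2 cortical + 2 thalamic bipolar channels | matches stored-event conventions of the implanted device |
| bursts | 60 Hz, 8× background SD, 3 s | fast-activity-like events inside the detector band |
| lag design | 23 cortex-leading (median 1.5 s), 16 with abs(lag) ≤ 0.1 s, 1 continuously epileptiform | the cohort composition the summary stage should reproduce (57.5 / 40.0 / 2.5%) |

The time series use a latent-factor construction: a network voxel is
`sqrt(r_w)·f + sqrt(1−r_w)·noise` with factor correlation
`rho = r_between/r_within`, which guarantees a positive-definite
correlation structure whenever `|rho| ≤ 1` and hits the planted pairwise
correlations exactly in expectation. Background traces are pink noise
(spectrally shaped white noise), and the burst is a pure sinusoid — the
generator emulates onset, frequency, amplitude and duration structure,
*not* BOLD hemodynamics or realistic EEG morphology. Passing tests
therefore show that the pipeline's rules behave as specified under the
assumed statistical structure; they say nothing about registration error,
physiological artifact or detector behaviour on real device telemetry.

One plumbing choice deserves a note: the atlas generator accepts the
planted truth and anchors one parcel seed at the mesh vertex nearest the
planted hotspot centre. Without this, the hotspot can fall arbitrarily
close to a random parcel boundary and "the parcel containing the
hotspot" stops being a well-defined ground truth. Anchoring affects only
where parcel boundaries fall, not the maps, the noise level, or any
threshold.

## Numerical and rule-level choices

**Z-scoring** uses the population SD (divide by N), the convention for
standardizing statistic maps; the suite checks mean ≤ 1e−10 and
|SD − 1| ≤ 1e−10 over the mask. Z-scores are computed over the
intersection mask only, preserving the intersect-then-standardize stage
order.

**Mirroring** reflects across the template midline plane (x → −x in mm).
A map already exactly symmetric passes through unchanged, which makes the
operation idempotent; asymmetric bilateral input is an error.

**Volume-to-surface sampling** is trilinear interpolation at the vertex
coordinate; no ribbon averaging. Vertices outside the volume clamp to the
boundary by default (an error can be requested instead).

**Surface smoothing** is iterative neighbour-averaging diffusion,
`x ← (1−λ)x + λ·W x` with `W` the row-normalized mesh adjacency. On a
locally flat mesh one step adds per-axis kernel variance `λ·m/2`, where
`m` is the mean squared neighbour distance, so the smoother solves
`n = ceiling(sigma² / (0.8·m/2))` and then sets `λ` to hit `sigma²`
exactly, with `sigma = FWHM/2.355`. The stated 10-mm width is treated as
FWHM (the conventional reading). After ~45 steps the kernel is
effectively Gaussian; on a 1-mm equilateral lattice the measured impulse
FWHM is 10.0 mm. Hemispheres are disjoint mesh components, so no signal
crosses the midline; a disconnected hemisphere triggers a warning only.

**Thresholding** keeps `k = round(fraction·N_nonzero)` vertices by signed
value (not magnitude — positive Z means shared involvement), with ties at
the cutoff broken toward the lower vertex index so the count is exact.

**Parcel ranking** averages over non-zero vertices only, ranks NA
(empty) parcels last, and breaks exact mean ties toward the lower parcel
id. Ranking is computed on the thresholded map, mirroring the stage order
in which the hotspot map itself is ranked.

**Connectivity** clamps r at ±(1 − 1e−7) before `atanh` (the transform
diverges at ±1); zero-variance voxels yield z = 0 plus a flag rather than
NaN propagation. The group statistic is the plain mean of Fisher-z maps —
no random-effects map, and no temporal preprocessing, since the emulated
normative dataset is preprocessed upstream.

**The event detector** band-limits the programmed channel with a
zero-phase (forward-backward) 4th-order Butterworth — zero-phase so
onsets are not systematically delayed — rectifies, and smooths with a
0.1-s moving average. A detection is a maximal run with envelope at or
above `min_amplitude` percent of the channel's full-scale (interpreted as
the maximum absolute value over the recording; the device's internal
full-scale definition is not public) lasting at least `min_duration`.
The per-lead onset is the earliest detection start over that lead's
channels. A recording is *undetermined* when the envelope criterion holds
for more than 90% of the record on both leads — an operationalization of
"continuously epileptiform throughout".

For the synthetic study the default amplitude threshold is 25% of
full-scale. A device-style threshold of 1.56% sits below the band-passed
pink-noise envelope floor at the generator's signal-to-noise ratio, so it
cannot separate burst from background on these synthetic traces; the
printed device settings (33.1–125 Hz, 1.56%, 0.51 s) are still exercised
verbatim on near-silent-background fixtures, where they fire exactly once
at the burst onset.

A monotonicity caveat: raising the amplitude threshold can split one long
suprathreshold run into two shorter qualifying runs, so the *count* of
detections is not globally monotone in the threshold. The monotone
quantity is the *total detected duration* (every new run is contained in
a previously qualifying run), and the count is monotone in
`min_duration`; the property tests assert exactly these.

**Onset classification**: with lag = thalamic − cortical onset, the label
is cortical-first when lag ≥ 0.25 s (boundary inclusive), thalamic-first
when −lag ≥ 0.25 s, otherwise simultaneous; an undetermined flag
overrides. Swapping lead roles swaps the first two labels and fixes
simultaneous. The generator refuses planted lags within two samples of
the boundary unless explicitly building a boundary fixture.

**Event scoring** replaces a trained seizure classifier with min-max
normalized line length over the pool — transparent and monotone in
high-amplitude fast activity, which is all the selection stage needs.
Selection keeps the 10 top-scored recordings per (patient, device), ties
toward the earlier timestamp. Cross-device timing is never compared; the
magnet-swipe trigger offset (~1–2 s between devices) is stored as
metadata only.

## Worked example

```{r example, eval = FALSE}
tpl   <- make_template()
truth <- make_planted_truth(tpl)
atlas <- make_surface_atlas(tpl, 500, 12, seed = 1, truth = truth)

maps <- make_modality_maps(tpl, truth, noise_sd = 0.3, seed = 11)
dwi  <- make_dwi_maps(tpl, truth, seed = 11)
out  <- run_hotspot_pipeline(maps, dwi, tpl, atlas$mesh, atlas$parcellation)
out$result

study <- make_recordings(lag_spec_study(), seed = 7)
sel   <- select_top_events(study$recordings, 10)
calls <- lapply(sel, classify_recording, cortical_settings = detector_settings())
summarize_onsets(calls)
```

## Problem sizes

The default test suite runs the full pipeline on the 32³ template
(~10,000 brain voxels, 964 surface vertices), 100 seeded recovery runs,
a 50-subject × 5,000-timepoint connectivity recovery on a 16³ template,
100 seeded sign checks, and the 40-recording onset study; the whole suite
completes in well under two minutes on one core. These sizes are the
package's chosen study conditions, stated here so results are read at the
scale they were computed.

## Known limitations

- The synthetic surface is a sphere pair, not a folded cortex; geodesic
  distances and parcel shapes are therefore idealized.
- The envelope-rule onset is a deterministic stand-in for expert visual
  onset marking; their correspondence on real recordings is unknown.
- The amplitude percentage is referenced to the observed trace maximum,
  an approximation of device full-scale semantics.
- Nonlinear template registration is out of scope: all inputs are assumed
  co-registered to one grid.
- The diffusion-map generator plants a common positive hotspot; it does
  not model tractography geometry or outcome noise across trials.
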