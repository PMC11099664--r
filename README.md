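# thalcort

Multimodal cortical hotspot mapping, normative seed-based functional
connectivity, and cortico-thalamic onset-lag analysis — with a synthetic
data generator so the whole pipeline is testable against planted ground
truth.

## The problem

In severe generalized epilepsies of the Lennox–Gastaut phenotype,
epileptic activity is expressed diffusely, which has made it hard to
justify any single cortical target for recording or neuromodulation
alongside the established centromedian thalamic target. One way forward
is convergence mapping: take group-level statistic maps from independent
modalities — EEG-fMRI activation during generalized fast activity, PET
hypometabolism, and diffusion-MRI correlates of clinical response to
thalamic stimulation — and ask where they agree. `thalcort` implements
that synthesis, the connectivity characterization of the resulting
hotspot, and the timing analysis of two-lead (cortex + thalamus)
intracranial recordings from devices implanted at such targets.

For users: imaging/EEG methodologists who want a tested, deterministic
reference implementation of these pipeline rules, and anyone who needs a
compact synthetic benchmark with planted hotspots, networks and onsets.

## Methods at a glance

**Hotspot synthesis.** Given co-registered volumetric maps: mirror the
unilateral map across the midline; average the six diffusion correlation
maps and keep positive values; intersect non-zero supports; Z-score each
map within the intersection (`z = (x − mean) / sd_pop`); average;
project to the cortical surface by trilinear sampling; smooth with a
geodesic kernel of 10 mm FWHM; keep the top 5% of non-zero vertices;
rank atlas parcels by the mean Z across non-zero thresholded vertices;
the hotspot restricted to the top parcel is the *peak hotspot*.

**Normative connectivity.** Per subject, `r_v = cor(seed mean
time course, voxel v)`, clamped and Fisher-transformed
(`z = atanh(r)`), then averaged over subjects. Reported per region of
interest as mean z and its sign, and between seeds as the spatial
correlation of the two group maps.

**Onset lags.** Each recording is band-pass filtered (zero-phase
Butterworth), rectified and smoothed into an envelope; detections are
maximal suprathreshold runs of at least the minimum duration; the
per-lead onset is the earliest detection. With
`lag = t_thal − t_cortex`, events are labelled `cortical_first` when
`lag ≥ 0.25 s` (inclusive), `thalamic_first` when `−lag ≥ 0.25 s`, else
`simultaneous`; continuously epileptiform recordings are `undetermined`.
The 10 top-scored recordings per device are summarized as counts,
percentages and median cortical-lead lag.

## Worked example

```r
library(thalcort)

tpl   <- make_template()                      # 32x32x32 @ 4 mm, symmetric mask
truth <- make_planted_truth(tpl)              # planted hotspot + networks
atlas <- make_surface_atlas(tpl, 500, 12, seed = 1, truth = truth)

maps <- make_modality_maps(tpl, truth, noise_sd = 0.3, seed = 11)
dwi  <- make_dwi_maps(tpl, truth, seed = 11)
out  <- run_hotspot_pipeline(maps, dwi, tpl, atlas$mesh, atlas$parcellation)
out$result
#> hotspot_result: 48 hotspot vertices; peak parcel left = 1 , right = 1 ; 48 peak-hotspot vertices
head(out$parcel_table, 2)
#>   hemisphere parcel_id   mean_z n_nonzero_vertices rank
#> 1       left         1 2.308818                 24    1
#> 2      right         1 2.298034                 24    2
```

The top 5% of vertices (48 of 964) all fall inside parcel 1 of each
hemisphere — the parcel that contains the planted hotspot — with mean
Z ≈ 2.3 against a standardized background.

```r
study <- make_recordings(lag_spec_study(), seed = 7)  # 40 planted events
sel   <- select_top_events(study$recordings, 10)      # 10 per device
calls <- lapply(sel, classify_recording, cortical_settings = detector_settings())
summarize_onsets(calls)
#> onset_summary over 40 recordings:
#>   cortical_first  23/40 (57.5%)
#>   thalamic_first   0/40 (0.0%)
#>   simultaneous    16/40 (40.0%)
#>   undetermined     1/40 (2.5%)
#>   median cortical-lead lag: 1.496 s
```

Detection, classification and summarization recover the planted cohort
composition exactly: 57.5% cortex-leading with a median lag of ~1.5 s,
40% simultaneous, one undetermined recording, and no thalamus-leading
events.

See `vignettes/thalcort-methods.Rmd` for the model, parameter and
design-choice documentation.

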