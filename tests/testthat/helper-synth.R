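# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

default_template <- function() fixture("tpl32", function() make_template())

default_truth <- function() {
  fixture("truth32", function() make_planted_truth(default_template()))
}

default_atlas <- function() {
  fixture("atlas32", function() {
    make_surface_atlas(default_template(), 500, 12, seed = 1,
                       truth = default_truth())
  })
}

small_template <- function() {
  fixture("tpl16", function() make_template(c(16, 16, 16), voxel_size = 4))
}

small_truth <- function() {
  fixture("truth16", function() make_planted_truth(small_template()))
}

# parcel id of the vertex nearest a planted hotspot centre
planted_parcel <- function(atlas, truth, hemi = "left") {
  d <- rowSums(sweep(atlas$mesh$vertices, 2, truth$hotspot_center[hemi, ])^2)
  d[atlas$mesh$hemisphere != hemi] <- Inf
  atlas$parcellation$labels[which.min(d)]
}

# mirror-symmetric noise-free diffusion maps (for symmetry invariants)
symmetric_dwi_maps <- function(template, truth) {
  bump <- thalcort:::gaussian_field(template, truth$hotspot_center, c(1, 1),
                                    truth$hotspot_sigma_mm)
  lapply(1:6, function(k) {
    v <- tanh(1.2 * bump)
    v[!template$brain_mask] <- 0
    new_volume_map(v, template$affine, "dwi_corr")
  })
}

# bare sinusoidal-burst recording on a near-silent background, for
# exercising printed detector settings where background must stay
# below a very low amplitude threshold
clean_burst_recording <- function(burst_freq = 60, onset_s = 5,
                                  burst_dur_s = 1, fs = 250,
                                  duration_s = 20, noise_sd = 1e-3,
                                  seed = 1) {
  set.seed(seed)
  n <- round(duration_s * fs)
  t_axis <- (seq_len(n) - 1) / fs
  mk <- function() {
    x <- rnorm(n, sd = noise_sd)
    win <- t_axis >= onset_s & t_axis < onset_s + burst_dur_s
    x[win] <- x[win] + sin(2 * pi * burst_freq * (t_axis[win] - onset_s))
    x
  }
  traces <- rbind(`CX 1-2` = mk(), `CX 3-4` = mk(),
                  `TH 1-2` = mk(), `TH 3-4` = mk())
  thalcort:::new_event_recording(
    traces = traces, fs = fs,
    channel_roles = c(`CX 1-2` = "cortical", `CX 3-4` = "cortical",
                      `TH 1-2` = "thalamic", `TH 3-4` = "thalamic"),
    device_side = "left", trigger_type = "long_episode",
    trigger_time_s = 0, score = 1, patient_id = "P1",
    recording_id = "clean", timestamp = 1
  )
}

# tiny hand-built parcellation over an arbitrary mesh
tiny_parcellation <- function(labels, hemisphere, n_parcels) {
  structure(list(labels = as.integer(labels),
                 hemisphere = factor(hemisphere, levels = c("left", "right")),
                 n_parcels = as.integer(n_parcels)),
            class = "parcellation")
}
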