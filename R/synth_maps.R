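#' Synthetic group-level modality maps
#'
#' Generates the three co-registered statistic maps that feed the hotspot
#' synthesis: an EEG-fMRI-like t-map, a PET-like t-map and (separately, see
#' [make_dwi_maps()]) diffusion correlation maps. All three share a Gaussian
#' bump at the planted bilateral hotspot; each adds modality-specific
#' distractor bumps and i.i.d. Gaussian noise inside the brain mask. The
#' PET-like map is returned unilateral (right hemisphere zeroed) to exercise
#' the mirroring stage.
#'
#' @param template a `template_spec`.
#' @param truth a `planted_truth`.
#' @param noise_sd standard deviation of the additive noise (>= 0); the
#'   planted bump has unit peak amplitude, distractors 0.5.
#' @param seed integer RNG seed; output is bit-reproducible for a fixed seed.
#' @return List of two `volume_map`s named `eeg_fmri_t` and `pet_t`.
#' @export
make_modality_maps <- function(template, truth, noise_sd = 0.3, seed = 1L) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  set.seed(seed)
  sph <- hemisphere_sphere(template)
  sigma <- truth$hotspot_sigma_mm
  mask <- template$brain_mask

  bump <- gaussian_field(template, truth$hotspot_center, c(1, 1), sigma)

  # per-modality distractors, bilateral, amplitude 0.5 (< hotspot amplitude
  # so the noiseless maximum stays at the hotspot centre)
  distract <- list(
    eeg_fmri_t = rbind(c(0, -0.45, 0.25), c(0, 0.45, -0.3)) * sph$r_brain,
    pet_t      = rbind(c(-0.35, 0.35, -0.2), c(0.35, 0.35, -0.2)) * sph$r_brain
  )

  build <- function(modality) {
    v <- bump + gaussian_field(template, distract[[modality]],
                               rep(0.5, nrow(distract[[modality]])), sigma)
    if (noise_sd > 0) v[mask] <- v[mask] + rnorm(sum(mask), sd = noise_sd)
    v[!mask] <- 0
    if (modality == "pet_t") v[template$hemisphere != "left"] <- 0
    new_volume_map(v, template$affine, modality)
  }

  list(eeg_fmri_t = build("eeg_fmri_t"), pet_t = build("pet_t"))
}

#' Synthetic diffusion-MRI correlation maps
#'
#' Six maps of Spearman-correlation-like values (two datasets x three
#' outcomes in the emulated design), each bounded in (-1, 1) via a tanh
#' squash of a bump-plus-noise field. All six are positive around the
#' planted hotspot and mixed-sign elsewhere.
#'
#' @inheritParams make_modality_maps
#' @return List of six `volume_map`s with modality `"dwi_corr"`.
#' @export
make_dwi_maps <- function(template, truth, seed = 1L) {
  set.seed(seed)
  mask <- template$brain_mask
  bump <- gaussian_field(template, truth$hotspot_center, c(1, 1),
                         truth$hotspot_sigma_mm)
  lapply(seq_len(6L), function(k) {
    raw <- 1.2 * bump
    raw[mask] <- raw[mask] + rnorm(sum(mask), sd = 0.35)
    v <- tanh(raw)
    v[!mask] <- 0
    new_volume_map(v, template$affine, "dwi_corr")
  })
}
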