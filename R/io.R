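#' @importFrom utils read.csv write.csv write.table read.delim
NULL

# our affines map 1-based voxel indices to mm; NIfTI uses 0-based indices.
affine_to_nifti <- function(a) {
  a0 <- a
  a0[1:3, 4] <- a[1:3, 4] + a[1:3, 1:3] %*% rep(1, 3)
  a0
}
affine_from_nifti <- function(a0) {
  a <- a0
  a[1:3, 4] <- a0[1:3, 4] - a0[1:3, 1:3] %*% rep(1, 3)
  a
}

#' Write a volumetric map as NIfTI-1
#'
#' @param map a `volume_map`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(map, path) {
  img <- RNifti::asNifti(map$values)
  RNifti::pixdim(img) <- sqrt(colSums(map$affine[1:3, 1:3]^2))
  sf <- structure(affine_to_nifti(map$affine), code = 2L)
  RNifti::`sform<-`(img, sf) -> img
  RNifti::`qform<-`(img, sf) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volumetric map from NIfTI-1
#'
#' @param path a NIfTI file holding a 3-D image with an invertible affine.
#' @param modality modality tag to attach (default `"zscore"`).
#' @return A `volume_map`.
#' @export
read_volume <- function(path, modality = "zscore") {
  img <- RNifti::readNifti(path)
  v <- as.array(img)
  if (length(dim(v)) == 4L && dim(v)[4] == 1L) v <- v[, , , 1]
  if (length(dim(v)) != 3L) {
    stop("shape error: expected a 3-D volume, got ",
         length(dim(v)), "-D in ", path)
  }
  a0 <- unclass(RNifti::xform(img))
  a0 <- rbind(a0[1:3, , drop = FALSE], c(0, 0, 0, 1))
  if (abs(det(a0)) < .Machine$double.eps) {
    stop("format error: non-invertible affine in ", path)
  }
  new_volume_map(v, affine_from_nifti(a0), modality)
}

#' Write / read per-vertex surface values as CSV
#'
#' Plain-text fallback format: columns `vertex_id` (1-based) and `value`.
#'
#' @param map a `surface_map`.
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_surface_map <- function(map, path) {
  write.csv(data.frame(vertex_id = seq_along(map$values), value = map$values),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_surface_map
#' @param mesh the `surface_mesh` the values belong to.
#' @return For the reader: a `surface_map` on `mesh`.
#' @export
read_surface_map <- function(path, mesh) {
  d <- read.csv(path)
  if (!all(c("vertex_id", "value") %in% names(d))) {
    stop("validation error: surface CSV must have columns vertex_id, value")
  }
  if (nrow(d) != nrow(mesh$vertices)) {
    stop("validation error: vertex_id count (", nrow(d),
         ") does not match the mesh (", nrow(mesh$vertices), " vertices)")
  }
  new_surface_map(d$value[order(d$vertex_id)], mesh)
}

#' Write / read an event recording as CSV plus JSON sidecar
#'
#' The CSV holds `time_s` and one column per channel; the sidecar (same
#' path with `.json`) holds `fs`, `channel_roles`, `device_side`,
#' `trigger_type`, `trigger_time_s`, `score`, `patient_id`, `recording_id`.
#'
#' @param rec an `event_recording`.
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  n <- ncol(rec$traces)
  d <- data.frame(time_s = (seq_len(n) - 1) / rec$fs)
  for (ch in rownames(rec$traces)) d[[ch]] <- rec$traces[ch, ]
  write.csv(d, path, row.names = FALSE)
  side <- list(fs = rec$fs, channel_roles = as.list(rec$channel_roles),
               device_side = rec$device_side, trigger_type = rec$trigger_type,
               trigger_time_s = rec$trigger_time_s, score = rec$score,
               patient_id = rec$patient_id, recording_id = rec$recording_id,
               timestamp = rec$timestamp)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  d <- read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(d)) {
    stop("validation error: recording CSV must have a time_s column")
  }
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  for (field in c("fs", "channel_roles", "device_side", "patient_id")) {
    if (is.null(side[[field]])) {
      stop("validation error: sidecar is missing field '", field, "'")
    }
  }
  chans <- setdiff(names(d), "time_s")
  if (!setequal(chans, names(side$channel_roles))) {
    stop("validation error: channel_roles does not match the CSV channels")
  }
  traces <- t(as.matrix(d[chans]))
  if (anyNA(traces)) {
    stop("validation error: channels have unequal lengths or missing samples")
  }
  new_event_recording(
    traces = traces, fs = side$fs,
    channel_roles = unlist(side$channel_roles),
    device_side = side$device_side,
    trigger_type = if (is.null(side$trigger_type)) "long_episode" else side$trigger_type,
    trigger_time_s = if (is.null(side$trigger_time_s)) 0 else side$trigger_time_s,
    score = if (is.null(side$score)) NA_real_ else side$score,
    patient_id = side$patient_id,
    recording_id = if (is.null(side$recording_id)) basename(path) else side$recording_id,
    timestamp = if (is.null(side$timestamp)) 0 else side$timestamp
  )
}

## ---- configuration ---------------------------------------------------------

config_defaults <- function() {
  list(fraction = 0.05, fwhm_mm = 10, onset_threshold_s = 0.25,
       k_per_device = 10L, seed = 1L, verbosity = 1L, out_dir = NULL)
}

#' Validate a pipeline configuration
#'
#' Checks every supplied key against the documented parameter set and its
#' range; unknown keys are rejected by name.
#'
#' @param cfg named list of configuration values.
#' @return The merged configuration (defaults filled in), invisibly typed.
#' @export
validate_config <- function(cfg) {
  defaults <- config_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    stop("validation error: unknown configuration key(s): ",
         paste(unknown, collapse = ", "))
  }
  merged <- utils::modifyList(defaults, cfg)
  check <- function(name, ok, constraint) {
    if (!isTRUE(ok)) {
      stop("validation error: field '", name, "' ", constraint)
    }
  }
  check("fraction", is.numeric(merged$fraction) &&
          merged$fraction > 0 && merged$fraction <= 1, "must be in (0, 1]")
  check("fwhm_mm", is.numeric(merged$fwhm_mm) && merged$fwhm_mm >= 0,
        "must be >= 0")
  check("onset_threshold_s", is.numeric(merged$onset_threshold_s) &&
          merged$onset_threshold_s > 0, "must be > 0")
  check("k_per_device", is.numeric(merged$k_per_device) &&
          merged$k_per_device >= 1, "must be >= 1")
  check("seed", is.numeric(merged$seed) && merged$seed == round(merged$seed),
        "must be an integer")
  merged
}

#' Read a JSON pipeline configuration
#'
#' @param path JSON file of configuration keys.
#' @return Validated configuration list (see [validate_config()]).
#' @export
read_config <- function(path) {
  validate_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Write a parcel ranking table as TSV
#'
#' @param parcel_table output of [parcel_mean_ranking()].
#' @param path output `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_parcel_table <- function(parcel_table, path) {
  write.table(parcel_table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# used by run_hotspot_pipeline(out_dir = ...)
write_pipeline_artifacts <- function(out, template, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(out$mirrored, file.path(out_dir, "mirrored.nii.gz"))
  write_volume(out$dwi_preprocessed, file.path(out_dir, "dwi_mean_pos.nii.gz"))
  write_volume(out$average, file.path(out_dir, "average_z.nii.gz"))
  mask_map <- new_volume_map(array(as.numeric(out$intersection_mask),
                                   dim = template$grid_shape),
                             template$affine, "zscore")
  write_volume(mask_map, file.path(out_dir, "intersection_mask.nii.gz"))
  write_surface_map(out$smoothed, file.path(out_dir, "smoothed_surface.csv"))
  write_surface_map(new_surface_map(as.numeric(out$hotspot_mask),
                                    out$smoothed$mesh),
                    file.path(out_dir, "hotspot_mask.csv"))
  write_parcel_table(out$parcel_table, file.path(out_dir, "parcel_table.tsv"))
  invisible(out_dir)
}
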