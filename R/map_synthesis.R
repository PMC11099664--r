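#' Mirror a unilateral statistic map across the midline
#'
#' Where the input is non-zero the value is kept; where it is zero the value
#' reflected across the template midline plane is used. A map that is
#' already exactly mirror-symmetric passes through unchanged (so the
#' operation is idempotent); a map with asymmetric signal in both
#' hemispheres is rejected, as is an all-zero map.
#'
#' @param map a `volume_map`, non-zero in exactly one hemisphere.
#' @param template the `template_spec` the map lives on.
#' @return A bilateral, exactly mirror-symmetric `volume_map`.
#' @export
mirror_bilateral <- function(map, template) {
  v <- map$values
  refl <- reflect_midline(template, v)
  if (max(abs(v)) == 0) {
    stop("cannot mirror an all-zero map: no hemisphere carries signal")
  }
  if (identical(dim(v), dim(refl)) && max(abs(v - refl)) == 0) {
    return(map)  # already bilateral and symmetric
  }
  left_nz <- any(v[template$hemisphere == "left"] != 0)
  right_nz <- any(v[template$hemisphere == "right"] != 0)
  if (left_nz && right_nz) {
    stop("map is non-zero in both hemispheres; mirroring expects a unilateral map")
  }
  out <- v
  fill <- out == 0
  out[fill] <- refl[fill]
  new_volume_map(out, map$affine, map$modality)
}

#' Average and positively threshold the diffusion correlation maps
#'
#' Voxelwise arithmetic mean of the six correlation maps, with negative
#' mean values set to zero (only correlations in the direction of greater
#' clinical benefit are carried forward).
#'
#' @param maps list of exactly six `volume_map`s on one grid.
#' @return A `volume_map` with modality `"dwi_corr"`.
#' @export
preprocess_dwi <- function(maps) {
  if (length(maps) != 6L) {
    stop("expected exactly 6 diffusion correlation maps, got ", length(maps))
  }
  check_same_grid(maps)
  m <- Reduce(`+`, lapply(maps, `[[`, "values")) / 6
  m[m < 0] <- 0
  new_volume_map(m, maps[[1]]$affine, "dwi_corr")
}

#' Intersection mask of common non-zero voxels
#'
#' @param maps list of >= 2 `volume_map`s on one grid.
#' @return Logical array, `TRUE` exactly where every map is non-zero.
#' @export
intersect_masks <- function(maps) {
  if (length(maps) < 2L) stop("need at least 2 maps to intersect")
  check_same_grid(maps)
  Reduce(`&`, lapply(maps, function(m) m$values != 0))
}

#' Z-score a map within a voxel mask
#'
#' Standardizes to mean 0 and population SD 1 (divide by N) over the mask;
#' voxels outside the mask are set to zero.
#'
#' @param map a `volume_map`.
#' @param mask logical array with >= 2 `TRUE` voxels.
#' @return A `volume_map` with modality `"zscore"`.
#' @export
zscore_within_mask <- function(map, mask) {
  if (sum(mask) < 2L) stop("mask must contain at least 2 voxels")
  x <- map$values[mask]
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))  # population SD
  if (sdev < 1e-12) stop("degenerate input: map is constant within the mask")
  out <- array(0, dim = dim(map$values))
  out[mask] <- (x - mu) / sdev
  new_volume_map(out, map$affine, "zscore")
}

#' Voxelwise average of statistic maps
#'
#' @param maps list of >= 2 `volume_map`s on one grid.
#' @return A `volume_map` with modality `"average_z"`; positive values mark
#'   greater-than-average involvement across the inputs.
#' @export
average_maps <- function(maps) {
  if (length(maps) < 2L) stop("need at least 2 maps to average")
  check_same_grid(maps)
  m <- Reduce(`+`, lapply(maps, `[[`, "values")) / length(maps)
  new_volume_map(m, maps[[1]]$affine, "average_z")
}

#' Sample a volume onto a surface mesh
#'
#' Trilinear interpolation of the volume at each vertex's mm coordinate.
#'
#' @param map a `volume_map`.
#' @param mesh a `surface_mesh` embedded in the same mm space.
#' @param clamp if `TRUE` (default), vertex coordinates outside the volume
#'   are clamped to the boundary; if `FALSE`, such vertices raise an error.
#' @return A `surface_map`.
#' @export
project_to_surface <- function(map, mesh, clamp = TRUE) {
  inv <- solve(map$affine)
  ijk <- t(inv[1:3, 1:3] %*% t(mesh$vertices) + inv[1:3, 4])
  dims <- dim(map$values)
  outside <- sweep(ijk, 2, rep(1, 3), "<") | sweep(ijk, 2, dims, ">")
  if (any(outside)) {
    if (!clamp) stop("mesh vertex outside volume bounds (set clamp = TRUE to clamp)")
    for (k in 1:3) ijk[, k] <- pmin(pmax(ijk[, k], 1), dims[k])
  }
  i0 <- pmin(floor(ijk), matrix(rep(dims - 1L, each = nrow(ijk)), ncol = 3))
  fr <- ijk - i0
  val <- numeric(nrow(ijk))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
         (if (dy) fr[, 2] else 1 - fr[, 2]) *
         (if (dz) fr[, 3] else 1 - fr[, 3])
    val <- val + w * map$values[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  }
  new_surface_map(val, mesh)
}

#' Geodesic surface smoothing calibrated to a target FWHM
#'
#' Iterative neighbour-averaging diffusion on the mesh graph. Each step
#' replaces a vertex value by `(1 - lambda) * value + lambda * mean(neighbours)`;
#' on a locally flat mesh one step adds per-axis kernel variance
#' `lambda * msq / 2`, where `msq` is the mean squared neighbour distance.
#' The number of iterations and `lambda` are solved from the mesh so the
#' accumulated kernel variance equals that of a Gaussian with the requested
#' FWHM. Hemispheres are separate mesh components, so no smoothing crosses
#' the midline.
#'
#' @param map a `surface_map` (carries its mesh).
#' @param fwhm_mm target full width at half maximum in mm; 0 is the identity.
#' @param lambda_max largest admissible per-step mixing weight (stability /
#'   kernel-quality bound).
#' @return A smoothed `surface_map`.
#' @export
smooth_surface <- function(map, fwhm_mm = 10, lambda_max = 0.8) {
  if (fwhm_mm < 0) stop("`fwhm_mm` must be >= 0")
  if (fwhm_mm == 0) return(map)
  mesh <- map$mesh
  ed <- mesh_edges(mesh)
  n <- nrow(mesh$vertices)
  A <- Matrix::sparseMatrix(i = c(ed$i, ed$j), j = c(ed$j, ed$i),
                            x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  if (any(deg == 0)) warning("mesh has isolated vertices; they are left unsmoothed")
  n_comp <- igraph::count_components(mesh_graph(mesh))
  if (n_comp > length(unique(mesh$hemisphere[!is.na(mesh$hemisphere)]))) {
    warning("mesh hemisphere is disconnected; smoothing acts per component")
  }
  D2 <- Matrix::sparseMatrix(i = c(ed$i, ed$j), j = c(ed$j, ed$i),
                             x = c(ed$d2, ed$d2), dims = c(n, n))
  msq <- Matrix::rowSums(D2)[deg > 0] / deg[deg > 0]
  msq_bar <- mean(msq)

  sigma2 <- (fwhm_mm / (2 * sqrt(2 * log(2))))^2
  step_max <- lambda_max * msq_bar / 2
  n_iter <- max(1L, ceiling(sigma2 / step_max))
  lambda <- sigma2 / (n_iter * msq_bar / 2)

  W <- A / pmax(deg, 1)  # row-normalized; isolated rows are all-zero
  x <- map$values
  keep <- deg == 0
  for (it in seq_len(n_iter)) {
    x_new <- (1 - lambda) * x + lambda * as.numeric(W %*% x)
    if (any(keep)) x_new[keep] <- x[keep]
    x <- x_new
  }
  new_surface_map(x, mesh, map$hemisphere)
}

#' Measure a smoother's FWHM from an impulse response
#'
#' Fits a radial Gaussian `log v = a - r^2 / (2 sigma^2)` to the response by
#' value-weighted least squares and returns `2 sqrt(2 log 2) * sigma`.
#'
#' @param mesh the `surface_mesh` the response lives on.
#' @param values impulse-response values (one per vertex, max at the source).
#' @param centre_vertex index of the impulse vertex; defaults to the argmax.
#' @return FWHM in mm.
#' @export
measure_fwhm <- function(mesh, values, centre_vertex = which.max(values)) {
  r2 <- rowSums(sweep(mesh$vertices, 2, mesh$vertices[centre_vertex, ])^2)
  keep <- values > max(values) * 1e-6
  fit <- stats::lm.wfit(x = cbind(1, r2[keep]), y = log(values[keep]),
                        w = values[keep])
  sigma2 <- -1 / (2 * fit$coefficients[2])
  2 * sqrt(2 * log(2)) * sqrt(sigma2)
}

#' Retain the top fraction of non-zero vertices
#'
#' Among vertices with non-zero value, keeps the `k = round(fraction * N)`
#' largest signed values; ties at the cutoff are broken by vertex index
#' (lower index retained) so exactly `k` vertices are kept.
#'
#' @param map a `surface_map` (or numeric vector).
#' @param fraction fraction of non-zero vertices to retain, in (0, 1].
#' @return Logical per-vertex mask.
#' @export
threshold_top_fraction <- function(map, fraction = 0.05) {
  if (!(fraction > 0 && fraction <= 1)) stop("`fraction` must be in (0, 1]")
  v <- if (inherits(map, "surface_map")) map$values else as.numeric(map)
  nz <- which(v != 0)
  mask <- logical(length(v))
  if (length(nz) == 0L) {
    warning("no non-zero vertices: threshold mask is empty")
    return(mask)
  }
  k <- floor(fraction * length(nz) + 0.5)
  if (k > 0L) {
    keep <- nz[order(-v[nz], nz)][seq_len(k)]
    mask[keep] <- TRUE
  }
  mask
}

#' Rank atlas parcels by mean statistic over non-zero vertices
#'
#' Per hemisphere and parcel, the mean of the map over vertices with
#' non-zero value (zero vertices are excluded from the mean). Parcels with
#' no non-zero vertex get `NA` and rank last. The table is sorted by
#' descending mean; exact ties and the NA block are ordered by hemisphere
#' then parcel id.
#'
#' @param map a `surface_map`.
#' @param parcellation a `parcellation` matching the map's mesh.
#' @return `data.frame` with columns `hemisphere`, `parcel_id`, `mean_z`,
#'   `n_nonzero_vertices`, `rank`.
#' @export
parcel_mean_ranking <- function(map, parcellation) {
  if (length(map$values) != length(parcellation$labels)) {
    stop("parcellation does not match the map's mesh")
  }
  v <- map$values
  rows <- expand.grid(parcel_id = seq_len(parcellation$n_parcels),
                      hemisphere = c("left", "right"),
                      stringsAsFactors = FALSE)[, c(2, 1)]
  res <- lapply(seq_len(nrow(rows)), function(r) {
    sel <- parcellation$hemisphere == rows$hemisphere[r] &
      parcellation$labels == rows$parcel_id[r] & v != 0
    n <- sum(sel)
    data.frame(hemisphere = rows$hemisphere[r], parcel_id = rows$parcel_id[r],
               mean_z = if (n > 0) mean(v[sel]) else NA_real_,
               n_nonzero_vertices = n)
  })
  tab <- do.call(rbind, res)
  ord <- order(is.na(tab$mean_z), -ifelse(is.na(tab$mean_z), 0, tab$mean_z),
               tab$hemisphere, tab$parcel_id)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

#' Restrict a hotspot mask to the peak parcel
#'
#' Per hemisphere, the peak parcel is the parcel with the highest mean
#' statistic (ties broken toward the lower parcel id); the peak hotspot is
#' the intersection of the hotspot mask with that parcel's vertices.
#'
#' @param hotspot_mask logical per-vertex mask (from
#'   [threshold_top_fraction()]).
#' @param parcel_table output of [parcel_mean_ranking()].
#' @param parcellation the `parcellation` used to build the table.
#' @return A `hotspot_result`: `hotspot_mask`, `parcel_table`,
#'   `peak_parcel` (named integer vector, one entry per hemisphere) and
#'   `peak_hotspot_mask`.
#' @export
peak_hotspot <- function(hotspot_mask, parcel_table, parcellation) {
  if (!any(hotspot_mask)) {
    warning("empty hotspot mask: peak hotspot is empty")
    return(structure(list(hotspot_mask = hotspot_mask,
                          parcel_table = parcel_table,
                          peak_parcel = c(left = NA_integer_, right = NA_integer_),
                          peak_hotspot_mask = hotspot_mask),
                     class = "hotspot_result"))
  }
  peak <- c(left = NA_integer_, right = NA_integer_)
  peak_mask <- logical(length(hotspot_mask))
  for (h in c("left", "right")) {
    th <- parcel_table[parcel_table$hemisphere == h & !is.na(parcel_table$mean_z), ]
    if (nrow(th) == 0L) next
    best <- th[order(-th$mean_z, th$parcel_id), ][1, ]
    peak[h] <- best$parcel_id
    sel <- parcellation$hemisphere == h & parcellation$labels == best$parcel_id
    peak_mask[sel & hotspot_mask] <- TRUE
  }
  if (!any(peak_mask)) {
    warning("hotspot mask is disjoint from the peak parcel; peak hotspot is empty")
  }
  structure(list(hotspot_mask = hotspot_mask, parcel_table = parcel_table,
                 peak_parcel = peak, peak_hotspot_mask = peak_mask),
            class = "hotspot_result")
}

#' @export
print.hotspot_result <- function(x, ...) {
  cat("hotspot_result:", sum(x$hotspot_mask), "hotspot vertices;",
      "peak parcel left =", x$peak_parcel["left"],
      ", right =", x$peak_parcel["right"], ";",
      sum(x$peak_hotspot_mask), "peak-hotspot vertices\n")
  invisible(x)
}

#' Overlap statistics between two vertex masks
#'
#' @param mask_a,mask_b logical vectors over the same mesh.
#' @return List with counts and `frac_a` (|A&B|/|A|), `frac_b` (|A&B|/|B|)
#'   and `dice`; ratios involving an empty mask are `NA` with a warning.
#' @export
mask_overlap <- function(mask_a, mask_b) {
  if (length(mask_a) != length(mask_b)) stop("masks must live on the same mesh")
  na <- sum(mask_a); nb <- sum(mask_b); ni <- sum(mask_a & mask_b)
  if (na == 0L || nb == 0L) warning("empty mask: overlap ratios are undefined")
  list(n_a = na, n_b = nb, n_intersect = ni,
       frac_a = if (na > 0) ni / na else NA_real_,
       frac_b = if (nb > 0) ni / nb else NA_real_,
       dice = if (na + nb > 0) 2 * ni / (na + nb) else NA_real_)
}

#' Run the full hotspot-synthesis pipeline
#'
#' Orchestrates: mirror the unilateral map, preprocess the diffusion maps,
#' intersect non-zero supports, Z-score each of the three maps within the
#' intersection, average, project to the cortical surface, smooth, threshold
#' the top fraction of non-zero vertices, rank parcels by mean statistic
#' over the thresholded map, and extract the peak hotspot.
#'
#' @param modality_maps list of two `volume_map`s: the EEG-fMRI-like t-map
#'   and the unilateral PET-like t-map (modality `"pet_t"` marks which one
#'   is mirrored).
#' @param dwi_maps list of six `volume_map`s of correlations.
#' @param template the `template_spec`.
#' @param mesh cortical `surface_mesh`.
#' @param parcellation matching `parcellation`.
#' @param fraction top fraction of non-zero vertices retained (default 0.05).
#' @param fwhm_mm surface smoothing width (default 10 mm).
#' @param out_dir optional directory; if given, every intermediate is
#'   written (volumes as NIfTI-1, surface data as CSV, the parcel table as
#'   TSV).
#' @return List of intermediates plus `result`, a `hotspot_result`.
#' @export
run_hotspot_pipeline <- function(modality_maps, dwi_maps, template, mesh,
                                 parcellation, fraction = 0.05, fwhm_mm = 10,
                                 out_dir = NULL) {
  if (length(modality_maps) != 2L) {
    stop("expected 2 modality t-maps (EEG-fMRI and PET), got ",
         length(modality_maps))
  }
  is_pet <- vapply(modality_maps, function(m) m$modality == "pet_t", logical(1))
  if (sum(is_pet) != 1L) stop("exactly one modality map must be tagged 'pet_t'")

  mirrored <- mirror_bilateral(modality_maps[[which(is_pet)]], template)
  dwi <- preprocess_dwi(dwi_maps)
  three <- list(modality_maps[[which(!is_pet)]], mirrored, dwi)
  mask <- intersect_masks(three)
  zmaps <- lapply(three, zscore_within_mask, mask = mask)
  avg <- average_maps(zmaps)
  surf <- project_to_surface(avg, mesh)
  smoothed <- smooth_surface(surf, fwhm_mm)
  hmask <- threshold_top_fraction(smoothed, fraction)
  masked <- new_surface_map(ifelse(hmask, smoothed$values, 0), mesh)
  tab <- parcel_mean_ranking(masked, parcellation)
  result <- peak_hotspot(hmask, tab, parcellation)

  out <- list(mirrored = mirrored, dwi_preprocessed = dwi,
              intersection_mask = mask, zscore_maps = zmaps, average = avg,
              surface = surf, smoothed = smoothed, hotspot_mask = hmask,
              hotspot_map = masked, parcel_table = tab, result = result)
  if (!is.null(out_dir)) write_pipeline_artifacts(out, template, out_dir)
  out
}
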