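#' Synthetic volumetric brain template
#'
#' Builds a small template grid with an ellipsoidal brain mask that is
#' exactly mirror-symmetric across the midline plane (first axis). The
#' template stands in for a common volumetric registration target: all
#' synthetic statistic maps, masks and time series live on this grid.
#'
#' Voxel indices are 1-based; the affine maps 1-based voxel indices to mm
#' coordinates, with the midline plane at x = 0 mm so that the reflection
#' x -> -x corresponds to reversing the first array index.
#'
#' @param grid_shape integer triple, voxels per axis (each >= 16).
#' @param voxel_size voxel edge length in mm.
#' @param seed integer; kept for interface symmetry with the other
#'   generators (the template itself is deterministic).
#' @return A `template_spec`: list with `grid_shape`, `voxel_size`,
#'   `affine` (4x4, 1-based voxel -> mm), `brain_mask` (logical array),
#'   `hemisphere` (character array in left/right/none) and `midline_axis`.
#' @export
#' @examples
#' tpl <- make_template(c(32, 32, 32), voxel_size = 4)
#' sum(tpl$brain_mask)
make_template <- function(grid_shape = c(32L, 32L, 32L), voxel_size = 4, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 16L)) {
    stop("grid too small: each axis of `grid_shape` must be >= 16 voxels")
  }
  if (voxel_size <= 0) stop("`voxel_size` must be positive")

  centre <- (grid_shape + 1) / 2
  affine <- diag(c(rep(voxel_size, 3), 1))
  affine[1:3, 4] <- -centre * voxel_size

  # ellipsoid radii scale with the grid so the mask always fits
  radii <- 0.42 * grid_shape
  ax <- lapply(1:3, function(k) ((seq_len(grid_shape[k]) - centre[k]) / radii[k])^2)
  d2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  brain_mask <- d2 <= 1
  if (!any(brain_mask)) stop("grid too small to contain the brain mask")

  xs_mm <- (seq_len(grid_shape[1]) - centre[1]) * voxel_size
  hemi_x <- ifelse(xs_mm < 0, "left", ifelse(xs_mm > 0, "right", "none"))
  hemisphere <- array("none", dim = grid_shape)
  for (i in seq_len(grid_shape[1])) {
    sl <- brain_mask[i, , ]
    h <- array("none", dim = grid_shape[2:3])
    h[sl] <- hemi_x[i]
    hemisphere[i, , ] <- h
  }

  structure(
    list(
      grid_shape = grid_shape,
      voxel_size = voxel_size,
      affine = affine,
      brain_mask = brain_mask,
      hemisphere = hemisphere,
      midline_axis = 1L
    ),
    class = "template_spec"
  )
}

#' @export
print.template_spec <- function(x, ...) {
  cat("template_spec:", paste(x$grid_shape, collapse = " x "),
      "voxels at", x$voxel_size, "mm;",
      sum(x$brain_mask), "brain voxels\n")
  invisible(x)
}

## ---- coordinate helpers ----------------------------------------------------

#' Convert 1-based voxel indices to mm coordinates
#' @param template a `template_spec`.
#' @param ijk numeric matrix (n x 3) or length-3 vector of voxel indices.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_to_mm <- function(template, ijk) {
  ijk <- rbind_coords(ijk)
  t(template$affine[1:3, 1:3] %*% t(ijk) + template$affine[1:3, 4])
}

#' Convert mm coordinates to continuous 1-based voxel indices
#' @inheritParams voxel_to_mm
#' @param mm numeric matrix (n x 3) or length-3 vector of mm coordinates.
#' @export
mm_to_voxel <- function(template, mm) {
  mm <- rbind_coords(mm)
  inv <- solve(template$affine)
  t(inv[1:3, 1:3] %*% t(mm) + inv[1:3, 4])
}

rbind_coords <- function(x) {
  if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
}

# mm coordinates of every voxel, as an n_voxel x 3 matrix in array order
template_coords_mm <- function(template) {
  g <- template$grid_shape
  ijk <- as.matrix(expand.grid(i = seq_len(g[1]), j = seq_len(g[2]),
                               k = seq_len(g[3])))
  voxel_to_mm(template, ijk)
}

# reflect an array across the template midline plane
reflect_midline <- function(template, values) {
  ax <- template$midline_axis
  idx <- rep(list(quote(expr = )), 3)
  idx[[ax]] <- rev(seq_len(dim(values)[ax]))
  do.call(`[`, c(list(values), idx, list(drop = FALSE)))
}

# geometry of the hemisphere spheres used to embed the surface atlas;
# shared with the default planted truth so planted hotspots lie on the mesh
hemisphere_sphere <- function(template) {
  r_brain <- min(0.42 * template$grid_shape * template$voxel_size)
  list(
    centre_left  = c(-0.52, 0, 0) * r_brain,
    centre_right = c(0.52, 0, 0) * r_brain,
    radius       = 0.41 * r_brain,
    r_brain      = r_brain
  )
}

## ---- volume maps -----------------------------------------------------------

volume_modalities <- c("eeg_fmri_t", "pet_t", "dwi_corr", "zscore", "average_z")

#' Construct a volumetric statistic map
#'
#' @param values 3-D numeric array of statistic values.
#' @param affine 4x4 voxel-to-mm transform (1-based voxel indices).
#' @param modality one of `"eeg_fmri_t"`, `"pet_t"`, `"dwi_corr"`,
#'   `"zscore"`, `"average_z"`.
#' @return A `volume_map`.
#' @export
new_volume_map <- function(values, affine, modality) {
  if (length(dim(values)) != 3L) stop("`values` must be a 3-D array")
  if (!all(is.finite(values))) stop("`values` must be finite")
  if (!identical(dim(affine), c(4L, 4L)) ||
      abs(det(affine)) < .Machine$double.eps) {
    stop("`affine` must be an invertible 4x4 matrix")
  }
  modality <- match.arg(modality, volume_modalities)
  structure(list(values = values, affine = affine, modality = modality),
            class = "volume_map")
}

#' @export
print.volume_map <- function(x, ...) {
  cat("volume_map [", x$modality, "]: ",
      paste(dim(x$values), collapse = " x "),
      "; range [", signif(min(x$values), 4), ", ",
      signif(max(x$values), 4), "]\n", sep = "")
  invisible(x)
}

check_same_grid <- function(maps) {
  d0 <- dim(maps[[1]]$values)
  for (m in maps[-1]) {
    if (!identical(dim(m$values), d0) ||
        max(abs(m$affine - maps[[1]]$affine)) > 1e-8) {
      stop("maps are not aligned: grids or affines differ")
    }
  }
  invisible(TRUE)
}

## ---- planted ground truth --------------------------------------------------

#' Planted ground truth for the synthetic study
#'
#' Fixes the geometry that all generators share: bilateral hotspot centres
#' (placed on the surface-atlas spheres so the cortical mesh passes through
#' them), centromedian-analog deep centres near the midline, and a voxelwise
#' network assignment: network A surrounds the hotspots (the seed network),
#' network B surrounds the deep centres (the anticorrelated network).
#'
#' @param template a `template_spec`.
#' @param r_within planted pairwise correlation within each network, in (0, 1).
#' @param r_between planted cross-network correlation, in (-1, 0].
#' @return A `planted_truth`: hotspot/cm centres (2 x 3 mm matrices, rows
#'   left/right), `network` (character array A/B/none), `hotspot_sigma_mm`,
#'   and the planted correlations.
#' @export
make_planted_truth <- function(template, r_within = 0.6, r_between = -0.3) {
  if (!(r_within > 0 && r_within < 1)) stop("`r_within` must be in (0, 1)")
  if (!(r_between > -1 && r_between <= 0)) stop("`r_between` must be in (-1, 0]")

  sph <- hemisphere_sphere(template)
  u <- c(1, 1, 2) / sqrt(6)
  hot_left <- sph$centre_left + sph$radius * u
  hot_right <- hot_left * c(-1, 1, 1)
  cm_left <- c(-0.15, -0.08, 0) * sph$r_brain
  cm_right <- cm_left * c(-1, 1, 1)

  hotspot_center <- rbind(left = hot_left, right = hot_right)
  cm_center <- rbind(left = cm_left, right = cm_right)
  for (r in 1:2) {
    v <- round(mm_to_voxel(template, hotspot_center[r, ]))
    if (!template$brain_mask[v[1], v[2], v[3]]) {
      stop("planted hotspot centre falls outside the brain mask")
    }
  }

  coords <- template_coords_mm(template)
  dist_to <- function(centres) {
    d <- matrix(Inf, nrow(coords), nrow(centres))
    for (r in seq_len(nrow(centres))) {
      d[, r] <- sqrt(rowSums(sweep(coords, 2, centres[r, ])^2))
    }
    apply(d, 1, min)
  }
  net <- array("none", dim = template$grid_shape)
  r_a <- 0.20 * sph$r_brain
  r_b <- 0.16 * sph$r_brain
  net[dist_to(hotspot_center) <= r_a] <- "A"
  net[dist_to(cm_center) <= r_b] <- "B"
  net[!template$brain_mask] <- "none"

  structure(
    list(
      hotspot_center = hotspot_center,
      cm_center = cm_center,
      network = net,
      hotspot_sigma_mm = 0.15 * sph$r_brain,
      r_within = r_within,
      r_between = r_between
    ),
    class = "planted_truth"
  )
}

# isotropic Gaussian bump field over the template grid (mm scale)
gaussian_field <- function(template, centres, amplitudes, sigma_mm) {
  coords <- template_coords_mm(template)
  v <- numeric(nrow(coords))
  for (r in seq_len(nrow(centres))) {
    d2 <- rowSums(sweep(coords, 2, centres[r, ])^2)
    v <- v + amplitudes[r] * exp(-d2 / (2 * sigma_mm^2))
  }
  array(v, dim = template$grid_shape)
}
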