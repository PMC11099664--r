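#' @importFrom stats cor
NULL

# resolve a seed/ROI specification to row indices of a subject's data matrix
resolve_mask_voxels <- function(voxel_index, mask, what = "mask") {
  if (is.array(mask) || is.logical(mask)) {
    idx <- which(mask)
  } else {
    idx <- as.integer(mask)  # linear template indices
  }
  if (length(idx) == 0L) stop("empty ", what, ": no voxels selected")
  sel <- match(idx, voxel_index)
  sel <- sel[!is.na(sel)]
  if (length(sel) == 0L) stop(what, " does not overlap the brain mask")
  sel
}

#' Mean seed time course within a voxel mask
#'
#' @param ts a `subject_ts`.
#' @param seed_mask logical template-grid array (or linear voxel indices);
#'   must overlap the brain mask.
#' @return Numeric vector, the unweighted mean across seed voxels at each
#'   timepoint.
#' @export
seed_timecourse <- function(ts, seed_mask) {
  sel <- resolve_mask_voxels(ts$voxel_index, seed_mask, "seed mask")
  colMeans(ts$data[sel, , drop = FALSE])
}

#' Single-subject seed-based connectivity map
#'
#' Pearson correlation of every brain voxel's time series with the mean
#' seed time course, clamped to +/- (1 - 1e-7) and Fisher r-to-Z
#' transformed (`z = atanh(r)`). Voxels with zero temporal variance get
#' z = 0 and are flagged in the `zero_variance` attribute.
#'
#' @param ts a `subject_ts`.
#' @param seed_mask as in [seed_timecourse()].
#' @param seed_name label stored on the resulting map.
#' @return A `conn_map`: per-mask-voxel Fisher-z values plus seed metadata.
#' @export
seed_connectivity_subject <- function(ts, seed_mask, seed_name = "seed") {
  tc <- seed_timecourse(ts, seed_mask)
  tc_c <- tc - mean(tc)
  ss_tc <- sum(tc_c^2)
  if (ss_tc < 1e-12) stop("degenerate input: seed time course is constant")
  xc <- ts$data - rowMeans(ts$data)
  ss_x <- rowSums(xc^2)
  r <- as.numeric(xc %*% tc_c) / sqrt(ss_x * ss_tc)
  flat <- ss_x < 1e-12
  r[flat] <- 0
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  z[flat] <- 0
  structure(list(values = z, seed_name = seed_name, n_subjects = 1L,
                 voxel_index = ts$voxel_index, dim = ts$dim,
                 zero_variance = which(flat)),
            class = "conn_map")
}

#' @export
print.conn_map <- function(x, ...) {
  cat("conn_map [seed:", x$seed_name, "]:", length(x$values),
      "voxels, n_subjects =", x$n_subjects, "\n")
  invisible(x)
}

#' Group-average connectivity map
#'
#' Voxelwise arithmetic mean of per-subject Fisher-z maps; invariant to
#' subject order.
#'
#' @param maps list of `conn_map`s on one grid (>= 1).
#' @return A `conn_map` with `n_subjects` equal to the summed count.
#' @export
group_average <- function(maps) {
  if (length(maps) < 1L) stop("need at least 1 map to average")
  vi <- maps[[1]]$voxel_index
  for (m in maps[-1]) {
    if (!identical(m$voxel_index, vi) || !identical(m$dim, maps[[1]]$dim)) {
      stop("connectivity maps are not aligned")
    }
  }
  v <- Reduce(`+`, lapply(maps, `[[`, "values")) / length(maps)
  structure(list(values = v, seed_name = maps[[1]]$seed_name,
                 n_subjects = sum(vapply(maps, `[[`, integer(1), "n_subjects")),
                 voxel_index = vi, dim = maps[[1]]$dim,
                 zero_variance = integer(0)),
            class = "conn_map")
}

#' Mean connectivity within a region of interest
#'
#' @param map a `conn_map`.
#' @param roi_mask logical template-grid array or linear voxel indices.
#' @return List with `mean_z`, its `sign` (-1, 0, 1) and `n_voxels`.
#' @export
roi_mean_connectivity <- function(map, roi_mask) {
  sel <- resolve_mask_voxels(map$voxel_index, roi_mask, "ROI")
  mz <- mean(map$values[sel])
  list(mean_z = mz, sign = sign(mz), n_voxels = length(sel))
}

#' Compare two seed networks
#'
#' Spatial Pearson correlation between two group connectivity maps over the
#' brain voxels, plus a per-ROI table of mean Fisher-z and its sign under
#' each seed.
#'
#' @param map_a,map_b `conn_map`s on one grid.
#' @param rois optional named list of ROI masks.
#' @return List with `spatial_r` and (if ROIs given) `roi_table`.
#' @export
compare_seed_networks <- function(map_a, map_b, rois = NULL) {
  if (!identical(map_a$voxel_index, map_b$voxel_index)) {
    stop("connectivity maps are not aligned")
  }
  out <- list(spatial_r = cor(map_a$values, map_b$values))
  if (!is.null(rois)) {
    out$roi_table <- do.call(rbind, lapply(names(rois), function(nm) {
      a <- roi_mean_connectivity(map_a, rois[[nm]])
      b <- roi_mean_connectivity(map_b, rois[[nm]])
      data.frame(roi = nm,
                 mean_z_a = a$mean_z, sign_a = a$sign,
                 mean_z_b = b$mean_z, sign_b = b$sign)
    }))
  }
  out
}

#' Convert a connectivity map to a volumetric map
#'
#' @param map a `conn_map`.
#' @param template the `template_spec` it was computed on.
#' @return A `volume_map` (zeros outside the brain mask).
#' @export
conn_to_volume <- function(map, template) {
  v <- array(0, dim = template$grid_shape)
  v[map$voxel_index] <- map$values
  new_volume_map(v, template$affine, "zscore")
}
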