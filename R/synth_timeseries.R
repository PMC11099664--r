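#' Synthetic normative resting-state time series
#'
#' Generates per-subject voxel-by-time matrices over the template brain mask
#' with two planted networks. Each network shares a latent factor: a voxel
#' in network A is `sqrt(r_w) * f_A + sqrt(1 - r_w) * noise`, giving
#' pairwise within-network correlation `r_w`; the two factors are
#' correlated `rho = r_between / r_within`, giving cross-network voxel
#' correlation `r_between`. The factor construction guarantees a valid
#' (positive-definite) correlation structure whenever `|rho| <= 1`.
#' Voxels outside both networks are independent unit-variance noise.
#'
#' @param template a `template_spec`.
#' @param truth a `planted_truth` (supplies the network assignment and the
#'   planted correlations).
#' @param n_subjects number of subjects (>= 1).
#' @param n_timepoints timepoints per subject (>= 20).
#' @param seed integer RNG seed.
#' @return List of `subject_ts` objects: `data` (mask-voxel x time matrix),
#'   `voxel_index` (linear indices into the template grid), `subject_id`,
#'   `dim`.
#' @export
make_normative_timeseries <- function(template, truth, n_subjects = 1L,
                                      n_timepoints = 200L, seed = 1L) {
  if (n_subjects < 1L) stop("`n_subjects` must be >= 1")
  if (n_timepoints < 20L) stop("`n_timepoints` must be >= 20")
  rw <- truth$r_within
  rb <- truth$r_between
  rho <- rb / rw
  if (abs(rho) > 1) {
    stop("infeasible correlation structure: |r_between| must be <= r_within")
  }
  idx <- which(template$brain_mask)
  net <- truth$network[template$brain_mask]
  i_a <- which(net == "A")
  i_b <- which(net == "B")
  nv <- length(idx)

  set.seed(seed)
  lapply(seq_len(n_subjects), function(s) {
    f_a <- rnorm(n_timepoints)
    f_b <- rho * f_a + sqrt(1 - rho^2) * rnorm(n_timepoints)
    x <- matrix(rnorm(nv * n_timepoints), nv, n_timepoints)
    if (length(i_a)) {
      x[i_a, ] <- sqrt(rw) * rep(1, length(i_a)) %o% f_a +
        sqrt(1 - rw) * x[i_a, , drop = FALSE]
    }
    if (length(i_b)) {
      x[i_b, ] <- sqrt(rw) * rep(1, length(i_b)) %o% f_b +
        sqrt(1 - rw) * x[i_b, , drop = FALSE]
    }
    structure(list(data = x, voxel_index = idx,
                   subject_id = sprintf("sub%03d", s),
                   dim = template$grid_shape),
              class = "subject_ts")
  })
}

#' @export
print.subject_ts <- function(x, ...) {
  cat("subject_ts", x$subject_id, ":", nrow(x$data), "voxels x",
      ncol(x$data), "timepoints\n")
  invisible(x)
}

# network masks as logical template-grid arrays, for use as seeds/ROIs
#' Network voxel mask from planted truth
#' @param truth a `planted_truth`.
#' @param which_net `"A"` (hotspot analog) or `"B"` (centromedian analog).
#' @return Logical array over the template grid.
#' @export
network_mask <- function(truth, which_net = c("A", "B")) {
  which_net <- match.arg(which_net)
  truth$network == which_net
}
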