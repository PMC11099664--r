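make_map <- function(values, tpl = default_template(), modality = "zscore") {
  new_volume_map(values, tpl$affine, modality)
}

test_that("mirroring reflects a unilateral map and is idempotent", {
  tpl <- default_template()
  truth <- default_truth()
  pet <- make_modality_maps(tpl, truth, noise_sd = 0, seed = 1)$pet_t

  m1 <- mirror_bilateral(pet, tpl)
  expect_identical(m1$values, thalcort:::reflect_midline(tpl, m1$values))
  # left-hemisphere bump reappears at the reflected right coordinates
  vl <- round(mm_to_voxel(tpl, truth$hotspot_center["left", ]))
  vr <- round(mm_to_voxel(tpl, truth$hotspot_center["right", ]))
  expect_equal(m1$values[vr[1], vr[2], vr[3]], pet$values[vl[1], vl[2], vl[3]])

  expect_identical(mirror_bilateral(m1, tpl)$values, m1$values)

  zero <- make_map(array(0, dim = tpl$grid_shape))
  expect_error(mirror_bilateral(zero, tpl), "all-zero")
  asym <- pet
  asym$values[20, 16, 16] <- 0.5  # right-hemisphere voxel
  expect_error(mirror_bilateral(asym, tpl), "both hemispheres")
})

test_that("diffusion preprocessing averages six maps and zeroes negatives", {
  tpl <- default_template()
  g <- tpl$grid_shape
  vals <- c(0.3, -0.3, 0.3, -0.3, 0.3, -0.3)
  maps <- lapply(vals, function(v) make_map(array(v, g), modality = "dwi_corr"))
  out <- preprocess_dwi(maps)
  expect_true(all(out$values == 0))  # mean 0 retained as 0

  neg <- lapply(1:6, function(i) make_map(array(-0.5, g), modality = "dwi_corr"))
  expect_true(all(preprocess_dwi(neg)$values == 0))

  same <- make_dwi_maps(tpl, default_truth(), seed = 1)[[1]]
  out2 <- preprocess_dwi(rep(list(same), 6))
  expect_equal(out2$values, pmax(same$values, 0))

  expect_error(preprocess_dwi(rep(list(same), 5)), "exactly 6")
})

test_that("mask intersection retains common non-zero voxels", {
  tpl <- default_template()
  g <- tpl$grid_shape
  base <- array(0, g)
  # nested supports of sizes 100 > 80 > 60
  a <- base; a[1:100] <- 1
  b <- base; b[1:80] <- 2
  c3 <- base; c3[1:60] <- -1
  m <- intersect_masks(list(make_map(a), make_map(b), make_map(c3)))
  expect_equal(sum(m), 60)
  expect_equal(which(m), 1:60)

  d <- base; d[101:160] <- 1
  expect_equal(sum(intersect_masks(list(make_map(a), make_map(d)))), 0)
  expect_equal(which(intersect_masks(list(make_map(a), make_map(a)))), 1:100)
  # order invariance
  expect_identical(intersect_masks(list(make_map(a), make_map(b), make_map(c3))),
                   intersect_masks(list(make_map(c3), make_map(a), make_map(b))))
})

test_that("Z-scoring uses the population SD within the mask", {
  tpl <- default_template()
  g <- tpl$grid_shape
  v <- array(0, g); v[1:3] <- c(1, 2, 3)
  mask <- array(FALSE, g); mask[1:3] <- TRUE
  z <- zscore_within_mask(make_map(v), mask)
  expect_equal(z$values[1:3], c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_true(all(z$values[-(1:3)] == 0))
  # mean 0, population SD 1 to near machine precision
  expect_lt(abs(mean(z$values[mask])), 1e-10)
  expect_lt(abs(sqrt(mean(z$values[mask]^2)) - 1), 1e-10)
  # idempotent on already-standardized values
  expect_equal(zscore_within_mask(z, mask)$values, z$values, tolerance = 1e-12)

  flat <- array(0, g); flat[1:3] <- 5
  expect_error(zscore_within_mask(make_map(flat), mask), "degenerate")
})

test_that("map averaging is the voxelwise mean and order-invariant", {
  tpl <- default_template()
  g <- tpl$grid_shape
  m1 <- make_map(array(1, g)); m2 <- make_map(array(2, g)); m6 <- make_map(array(6, g))
  expect_true(all(average_maps(list(m1, m2, m6))$values == 3))
  expect_equal(average_maps(list(m1, m1))$values, m1$values)
  neg <- make_map(-m6$values)
  expect_true(all(average_maps(list(m6, neg))$values == 0))
  expect_equal(average_maps(list(m1, m2, m6))$values,
               average_maps(list(m6, m1, m2))$values)
})

test_that("surface projection is trilinear sampling at vertex coordinates", {
  tpl <- default_template()
  g <- tpl$grid_shape
  const <- make_map(array(4.2, g))
  mesh <- default_atlas()$mesh
  expect_true(all(abs(project_to_surface(const, mesh)$values - 4.2) < 1e-12))

  # vertex exactly at a voxel centre picks that voxel's value
  v <- array(0, g); v[17, 17, 17] <- 7
  mm1 <- voxel_to_mm(tpl, c(17, 17, 17))
  small_mesh <- thalcort:::new_surface_mesh(rbind(mm1, mm1 + c(0, 0, 2)),
                                            matrix(c(1, 2, 1), 1), c("left", "left"))
  expect_equal(project_to_surface(make_map(v), small_mesh)$values[1], 7)

  # midway between voxel centres valued 0 and 2 -> 1
  v2 <- array(0, g); v2[18, 17, 17] <- 2
  mid <- voxel_to_mm(tpl, c(17.5, 17, 17))
  mesh_mid <- thalcort:::new_surface_mesh(rbind(mid, mid + c(0, 0, 2)),
                                          matrix(c(1, 2, 1), 1), c("left", "left"))
  expect_equal(project_to_surface(make_map(v2), mesh_mid)$values[1], 1)

  far <- thalcort:::new_surface_mesh(rbind(c(1e4, 0, 0), c(0, 0, 0)),
                                     matrix(c(1, 2, 1), 1), c("left", "left"))
  expect_error(project_to_surface(const, far, clamp = FALSE), "outside volume")
  expect_equal(project_to_surface(const, far, clamp = TRUE)$values[1], 4.2)
})

test_that("top-fraction threshold keeps exactly k signed-largest vertices", {
  vals <- c(1:100)  # distinct
  mask <- threshold_top_fraction(vals, 0.05)
  expect_equal(which(mask), 96:100)

  set.seed(42)
  for (i in 1:20) {
    v <- sample(c(rnorm(300), numeric(sample(0:50, 1))))
    f <- runif(1, 0.01, 1)
    msk <- threshold_top_fraction(v, f)
    nnz <- sum(v != 0)
    k <- floor(f * nnz + 0.5)
    expect_equal(sum(msk), k)
    # retained values are the k largest (full-sort oracle)
    if (k > 0) {
      expect_equal(sort(v[msk]), sort(v[v != 0], decreasing = TRUE)[k:1])
    }
  }
  # fraction 1 keeps exactly the non-zero support
  v <- c(0, 3, -1, 0, 2)
  expect_equal(threshold_top_fraction(v, 1), v != 0)
  # ties at the cutoff resolved toward the lower vertex index
  expect_equal(which(threshold_top_fraction(c(5, 5, 5, 5), 0.5)), 1:2)
  expect_warning(threshold_top_fraction(numeric(10), 0.05), "empty")
})

test_that("parcel ranking averages non-zero vertices and ranks NA parcels last", {
  mesh <- make_flat_mesh(3, 2, 1)  # 6 vertices
  parc <- tiny_parcellation(c(1, 1, 1, 2, 2, 2), rep("left", 6), 2)
  map <- new_surface_map(c(0, 2, 4, 0, 0, 0), mesh)
  tab <- parcel_mean_ranking(map, parc)
  expect_equal(tab$mean_z[tab$hemisphere == "left" & tab$parcel_id == 1], 3)
  expect_true(is.na(tab$mean_z[tab$hemisphere == "left" & tab$parcel_id == 2]))
  expect_equal(tab$rank[tab$hemisphere == "left" & tab$parcel_id == 1], 1)
  na_ranks <- tab$rank[is.na(tab$mean_z)]
  expect_equal(sort(na_ranks), (nrow(tab) - length(na_ranks) + 1):nrow(tab))

  map2 <- new_surface_map(c(1, 1, 1, 2, 2, 2), mesh)
  tab2 <- parcel_mean_ranking(map2, parc)
  expect_equal(tab2$parcel_id[tab2$rank == 1], 2)  # higher mean ranks first
})

test_that("peak hotspot intersects the top parcel with documented tie-break", {
  mesh <- make_flat_mesh(4, 2, 1)  # 8 vertices
  parc <- tiny_parcellation(c(1, 1, 2, 2, 1, 1, 2, 2),
                            rep(c("left", "right"), each = 4), 2)
  map <- new_surface_map(c(1, 1, 3, 3, 2, 2, 2, 2), mesh)
  tab <- parcel_mean_ranking(map, parc)
  hmask <- rep(TRUE, 8)
  res <- peak_hotspot(hmask, tab, parc)
  expect_equal(unname(res$peak_parcel["left"]), 2L)
  expect_equal(unname(res$peak_parcel["right"]), 1L)  # tie 2 vs 2 -> lower id
  expect_true(all(which(res$peak_hotspot_mask) %in% c(3, 4, 5, 6)))

  # hotspot mask disjoint from the top parcel -> empty peak with warning
  hmask2 <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
  map3 <- new_surface_map(c(1, 1, 3, 3, 0, 0, 0, 0), mesh)
  tab3 <- parcel_mean_ranking(map3, parc)
  expect_warning(res3 <- peak_hotspot(hmask2, tab3, parc), "disjoint")
  expect_false(any(res3$peak_hotspot_mask[3:4]))
  expect_warning(peak_hotspot(rep(FALSE, 8), tab, parc), "empty")
})

test_that("mask overlap reports intersection fractions and Dice", {
  a <- c(rep(TRUE, 100), rep(FALSE, 100))
  b <- c(rep(FALSE, 75), rep(TRUE, 50), rep(FALSE, 75))
  ov <- mask_overlap(a, b)
  expect_equal(ov$n_intersect, 25)
  expect_equal(ov$frac_a, 0.25)
  expect_equal(ov$frac_b, 0.5)
  expect_equal(ov$dice, 1 / 3)

  same <- mask_overlap(a, a)
  expect_equal(c(same$frac_a, same$frac_b, same$dice), c(1, 1, 1))
  disj <- mask_overlap(a, !a)
  expect_equal(c(disj$frac_a, disj$frac_b, disj$dice), c(0, 0, 0))
  expect_warning(ov0 <- mask_overlap(rep(FALSE, 10), a[1:10]), "empty")
  expect_true(is.na(ov0$frac_a))
})

test_that("pipeline recovers the planted parcel and is deterministic", {
  tpl <- default_template()
  truth <- default_truth()
  atlas <- default_atlas()
  mm <- make_modality_maps(tpl, truth, noise_sd = 0.3, seed = 11)
  dw <- make_dwi_maps(tpl, truth, seed = 11)
  out <- run_hotspot_pipeline(mm, dw, tpl, atlas$mesh, atlas$parcellation)
  expect_equal(unname(out$result$peak_parcel["left"]),
               planted_parcel(atlas, truth, "left"))
  expect_equal(unname(out$result$peak_parcel["right"]),
               planted_parcel(atlas, truth, "right"))
  expect_true(all(which(out$result$peak_hotspot_mask) %in%
                    which(out$result$hotspot_mask)))

  out2 <- run_hotspot_pipeline(mm, dw, tpl, atlas$mesh, atlas$parcellation)
  expect_identical(out$smoothed$values, out2$smoothed$values)
  expect_identical(out$result$peak_parcel, out2$result$peak_parcel)

  expect_error(run_hotspot_pipeline(mm[1], dw, tpl, atlas$mesh,
                                    atlas$parcellation), "expected 2")
  expect_error(run_hotspot_pipeline(mm, dw[1:4], tpl, atlas$mesh,
                                    atlas$parcellation), "6")
})

test_that("symmetric inputs give a mirror-symmetric average map and surface", {
  tpl <- default_template()
  truth <- default_truth()
  atlas <- default_atlas()
  mm <- make_modality_maps(tpl, truth, noise_sd = 0, seed = 1)
  dw <- symmetric_dwi_maps(tpl, truth)
  out <- run_hotspot_pipeline(mm, dw, tpl, atlas$mesh, atlas$parcellation)
  expect_equal(out$average$values,
               thalcort:::reflect_midline(tpl, out$average$values),
               tolerance = 1e-10)
  n <- sum(atlas$mesh$hemisphere == "left")
  expect_equal(out$smoothed$values[1:n], out$smoothed$values[(n + 1):(2 * n)],
               tolerance = 1e-6)
})
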