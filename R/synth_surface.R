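#' @importFrom stats rnorm median sd
NULL

new_surface_mesh <- function(vertices, faces, hemisphere) {
  structure(
    list(vertices = vertices, faces = faces,
         hemisphere = factor(hemisphere, levels = c("left", "right"))),
    class = "surface_mesh"
  )
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces),
      "faces (", sum(x$hemisphere == "left"), "left /",
      sum(x$hemisphere == "right"), "right )\n")
  invisible(x)
}

#' Construct a per-vertex surface map
#'
#' @param values numeric vector, one value per mesh vertex.
#' @param mesh the `surface_mesh` the values live on.
#' @param hemisphere optional hemisphere tag (`"left"`, `"right"`, `"both"`).
#' @return A `surface_map`.
#' @export
new_surface_map <- function(values, mesh, hemisphere = NULL) {
  if (length(values) != nrow(mesh$vertices)) {
    stop("surface map must carry one value per mesh vertex")
  }
  if (!all(is.finite(values))) stop("surface map values must be finite")
  structure(list(values = as.numeric(values), mesh = mesh,
                 hemisphere = if (is.null(hemisphere)) "both" else hemisphere),
            class = "surface_map")
}

#' @export
print.surface_map <- function(x, ...) {
  cat("surface_map:", length(x$values), "vertices; range [",
      signif(min(x$values), 4), ",", signif(max(x$values), 4), "]\n")
  invisible(x)
}

# undirected edge list (i, j, squared length) from the face matrix
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  d2 <- rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                 mesh$vertices[e[, 2], , drop = FALSE])^2)
  list(i = e[, 1], j = e[, 2], d2 = d2)
}

mesh_graph <- function(mesh) {
  ed <- mesh_edges(mesh)
  igraph::graph_from_data_frame(
    data.frame(from = ed$i, to = ed$j, weight = sqrt(ed$d2)),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(mesh$vertices)))
  )
}

# latitude/longitude sphere with ~n_target vertices; returns unit vertices
# and a consistent triangulation (pole fans + split quads)
build_uv_sphere <- function(n_target) {
  nlat <- max(4L, round(sqrt(n_target / 2)))
  nlon <- 2L * nlat
  theta <- seq(0, pi, length.out = nlat + 1L)[-c(1L, nlat + 1L)]
  phi <- seq(0, 2 * pi, length.out = nlon + 1L)[-(nlon + 1L)]
  ring <- function(th) cbind(sin(th) * cos(phi), sin(th) * sin(phi),
                             rep(cos(th), nlon))
  verts <- rbind(c(0, 0, 1), do.call(rbind, lapply(theta, ring)), c(0, 0, -1))
  n_ring <- length(theta)
  idx <- function(r, c) 1L + (r - 1L) * nlon + ((c - 1L) %% nlon) + 1L
  faces <- list()
  for (c in seq_len(nlon)) faces[[length(faces) + 1L]] <- c(1L, idx(1, c), idx(1, c + 1))
  for (r in seq_len(n_ring - 1L)) {
    for (c in seq_len(nlon)) {
      a <- idx(r, c); b <- idx(r, c + 1); d <- idx(r + 1, c); e <- idx(r + 1, c + 1)
      faces[[length(faces) + 1L]] <- c(a, b, d)
      faces[[length(faces) + 1L]] <- c(b, e, d)
    }
  }
  south <- nrow(verts)
  for (c in seq_len(nlon)) {
    faces[[length(faces) + 1L]] <- c(south, idx(n_ring, c + 1), idx(n_ring, c))
  }
  list(vertices = verts, faces = do.call(rbind, faces))
}

#' Synthetic cortical surface atlas
#'
#' Builds two sphere-derived hemisphere meshes embedded in template mm space
#' (the right hemisphere is the exact mirror image of the left) and a
#' parcellation assigning every vertex to its nearest seed vertex by
#' geodesic (graph shortest-path) distance. Seed vertices are drawn once
#' from the given RNG seed and reused on both hemispheres, so parcel `k` on
#' the right is the mirror image of parcel `k` on the left.
#'
#' @param template a `template_spec`; fixes the embedding geometry.
#' @param n_vertices_per_hemi approximate vertex count per hemisphere
#'   (must be >= 10 * `n_parcels`).
#' @param n_parcels parcels per hemisphere (>= 1).
#' @param seed integer RNG seed.
#' @param truth optional `planted_truth`. When given, the mesh vertex
#'   nearest the planted hotspot centre is forced to be one of the parcel
#'   seed vertices, so the planted hotspot lies in the interior of a
#'   well-defined parcel rather than arbitrarily close to a parcel
#'   boundary — the planted-parcel ground truth is then meaningful.
#' @return List with `mesh` (a `surface_mesh` over both hemispheres) and
#'   `parcellation` (class `parcellation`: integer `labels`, `hemisphere`
#'   factor, `n_parcels`).
#' @export
make_surface_atlas <- function(template, n_vertices_per_hemi = 500L,
                               n_parcels = 12L, seed = 1L, truth = NULL) {
  if (n_parcels < 1L) stop("`n_parcels` must be >= 1")
  if (n_vertices_per_hemi < 10L * n_parcels) {
    stop("`n_vertices_per_hemi` must be >= 10 * `n_parcels`")
  }
  sph <- hemisphere_sphere(template)
  unit <- build_uv_sphere(n_vertices_per_hemi)
  n <- nrow(unit$vertices)
  left <- sweep(unit$vertices * sph$radius, 2, sph$centre_left, "+")
  right <- left %*% diag(c(-1, 1, 1))
  mesh <- new_surface_mesh(
    vertices = rbind(left, right),
    faces = rbind(unit$faces, unit$faces + n),
    hemisphere = rep(c("left", "right"), each = n)
  )

  set.seed(seed)
  seed_idx <- sort(sample.int(n, n_parcels))
  if (!is.null(truth)) {
    hot_v <- which.min(rowSums(sweep(left, 2, truth$hotspot_center["left", ])^2))
    if (!hot_v %in% seed_idx) {
      # replace the sampled seed nearest the hotspot vertex
      drop <- which.min(rowSums(sweep(left[seed_idx, , drop = FALSE], 2,
                                      left[hot_v, ])^2))
      seed_idx <- sort(c(seed_idx[-drop], hot_v))
    }
  }
  g <- mesh_graph(mesh)
  d <- igraph::distances(g, v = seed_idx, to = seq_len(n))
  if (any(!is.finite(apply(d, 2, min)))) {
    stop("topology error: some vertices are unreachable from every parcel seed")
  }
  labels_left <- apply(d, 2, which.min)   # ties -> lower parcel id
  labels <- c(labels_left, labels_left)   # right hemisphere mirrors the left

  parcellation <- structure(
    list(labels = as.integer(labels), hemisphere = mesh$hemisphere,
         n_parcels = as.integer(n_parcels)),
    class = "parcellation"
  )
  list(mesh = mesh, parcellation = parcellation)
}

#' Flat triangulated calibration mesh
#'
#' An equilateral (hexagonal-lattice) triangulation of a rectangle in the
#' z = 0 plane. Interior vertices have six neighbours at exactly `spacing`
#' mm, so the neighbour-averaging smoother's step kernel is isotropic; used
#' to calibrate and measure the smoother's FWHM.
#'
#' @param nx,ny vertices per row / number of rows.
#' @param spacing lattice constant in mm.
#' @return A `surface_mesh` (single hemisphere, labelled left), centred on
#'   the origin.
#' @export
make_flat_mesh <- function(nx = 41L, ny = 47L, spacing = 1) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  stopifnot(nx >= 2L, ny >= 2L, spacing > 0)
  xy <- do.call(rbind, lapply(seq_len(ny) - 1L, function(j) {
    cbind((seq_len(nx) - 1L + (j %% 2L) / 2) * spacing,
          j * sqrt(3) / 2 * spacing)
  }))
  verts <- cbind(sweep(xy, 2, colMeans(xy)), 0)
  v <- function(i, j) j * nx + i + 1L  # i, j 0-based
  faces <- list()
  for (j in 0:(ny - 2L)) {
    for (i in 0:(nx - 2L)) {
      if (j %% 2L == 0L) {
        faces[[length(faces) + 1L]] <- c(v(i, j), v(i + 1L, j), v(i, j + 1L))
        faces[[length(faces) + 1L]] <- c(v(i + 1L, j), v(i + 1L, j + 1L), v(i, j + 1L))
      } else {
        faces[[length(faces) + 1L]] <- c(v(i, j), v(i + 1L, j), v(i + 1L, j + 1L))
        faces[[length(faces) + 1L]] <- c(v(i, j), v(i + 1L, j + 1L), v(i, j + 1L))
      }
    }
  }
  new_surface_mesh(verts, do.call(rbind, faces), rep("left", nrow(verts)))
}
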