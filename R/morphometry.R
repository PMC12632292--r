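#' Corresponded outer/inner surface pair
#'
#' The outer mesh samples the CP/SP boundary and the inner mesh the SP/IZ
#' boundary. Both must share one face list so that vertex `i` of the inner
#' surface corresponds to vertex `i` of the outer surface; thickness is then
#' a per-index distance.
#'
#' @param outer,inner [tri_mesh()] objects with identical face lists.
#' @return An object of class `surface_pair`.
#' @export
surface_pair <- function(outer, inner) {
  stopifnot(inherits(outer, "tri_mesh"), inherits(inner, "tri_mesh"))
  if (n_vertices(outer) != n_vertices(inner) ||
      !identical(outer$faces, inner$faces))
    stop("outer and inner meshes must share an identical face list (vertex correspondence)")
  structure(list(outer = outer, inner = inner), class = "surface_pair")
}

#' @export
print.surface_pair <- function(x, ...) {
  cat("surface_pair:", n_vertices(x$outer), "corresponded vertices,",
      nrow(x$outer$faces), "faces\n")
  invisible(x)
}

#' Voxel label volume
#'
#' Integer 3-D grid of region labels on an isotropic voxel grid. Voxel centers
#' follow the half-voxel convention: the center of voxel `[i,j,k]` sits at
#' `origin + (c(i,j,k) - 0.5) * voxel_size` in world mm.
#'
#' @param grid 3-D integer array, 0 = background.
#' @param voxel_size isotropic voxel edge length (mm), > 0.
#' @param origin world coordinate of the grid corner (mm).
#' @param label_map optional named integer vector mapping region names to ids.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(grid, voxel_size, origin = c(0, 0, 0), label_map = NULL) {
  stopifnot(length(dim(grid)) == 3L, voxel_size > 0, length(origin) == 3L)
  structure(list(grid = grid, voxel_size = voxel_size, origin = origin,
                 label_map = label_map), class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("label_volume:", paste(dim(x$grid), collapse = " x "),
      "voxels @", x$voxel_size, "mm,", sum(x$grid != 0), "labeled\n")
  invisible(x)
}

#' Write / read a label volume as NIfTI
#'
#' @param volume a [label_volume()].
#' @param path output `.nii` path.
#' @return `write_label_volume()` returns `path` invisibly;
#'   `read_label_volume()` a [label_volume()].
#' @export
write_label_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$grid,
                         pixdim = rep(volume$voxel_size, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  label_volume(array(as.integer(round(img)), dim = dim(img)),
               voxel_size = RNifti::pixdim(img)[1])
}

#' Taubin shrink-compensated mesh smoothing
#'
#' Alternates uniform-Laplacian steps with a positive factor `lambda` and a
#' negative factor `mu`, which damps high-frequency surface noise while
#' keeping the low-frequency shape (and hence enclosed volume) nearly fixed,
#' unlike plain Laplacian smoothing which shrinks the mesh.
#'
#' @param mesh a [tri_mesh()].
#' @param lambda positive smoothing factor; requires `0 < lambda < -mu < 1`.
#' @param mu negative un-shrinking factor.
#' @param iterations number of lambda/mu step pairs.
#' @return smoothed [tri_mesh()] with identical topology and labels.
#' @export
taubin_smooth <- function(mesh, lambda = 0.5, mu = -0.53, iterations = 10L) {
  if (!(lambda > 0 && mu < 0 && lambda < -mu && -mu < 1))
    stop("require 0 < lambda < -mu < 1")
  if (!is_closed_mesh(mesh)) stop("taubin_smooth expects a closed manifold mesh")
  adj <- vertex_adjacency(mesh)
  v <- mesh$vertices
  lap_step <- function(v, factor) {
    nb_mean <- t(vapply(adj, function(ii) colMeans(v[ii, , drop = FALSE]),
                        numeric(3)))
    v + factor * (nb_mean - v)
  }
  for (it in seq_len(iterations)) {
    v <- lap_step(v, lambda)
    v <- lap_step(v, mu)
  }
  tri_mesh(v, mesh$faces, mesh$vertex_labels, mesh$vertex_hemi)
}

#' Per-vertex subplate thickness
#'
#' Euclidean distance between corresponding inner and outer surface vertices.
#'
#' @param pair a [surface_pair()].
#' @return numeric vector of non-negative distances (mm), one per vertex.
#' @export
vertex_thickness <- function(pair) {
  stopifnot(inherits(pair, "surface_pair"))
  sqrt(rowSums((pair$outer$vertices - pair$inner$vertices)^2))
}

#' Area-preserving surface inflation
#'
#' Iterative uniform-Laplacian smoothing with a per-iteration global rescale
#' (about the centroid) that restores the total surface area. The fixed point
#' is a sphere-like surface of the same area; it serves as the smooth
#' reference from which sulcal/SP depth is measured.
#'
#' @param mesh closed [tri_mesh()].
#' @param iterations smoothing iterations.
#' @param step Laplacian step size in (0, 1].
#' @return inflated [tri_mesh()] with unchanged topology.
#' @export
inflate_surface <- function(mesh, iterations = 100L, step = 0.5) {
  if (!is_closed_mesh(mesh)) stop("inflate_surface expects a closed mesh")
  stopifnot(step > 0, step <= 1)
  adj <- vertex_adjacency(mesh)
  area0 <- surface_area(mesh)$total
  v <- mesh$vertices
  for (it in seq_len(iterations)) {
    nb_mean <- t(vapply(adj, function(ii) colMeans(v[ii, , drop = FALSE]),
                        numeric(3)))
    v <- v + step * (nb_mean - v)
    ctr <- colMeans(v)
    s <- sqrt(area0 / surface_area(tri_mesh(v, mesh$faces))$total)
    v <- t(ctr + (t(v) - ctr) * s)
  }
  tri_mesh(v, mesh$faces, mesh$vertex_labels, mesh$vertex_hemi)
}

#' Subplate depth from an inflated reference surface
#'
#' Signed displacement from each inflated vertex to its corresponding original
#' vertex, projected on the inflated vertex normal, then rescaled by
#' subtracting the minimum over all vertices (both hemispheres) so the
#' subject minimum is exactly zero.
#'
#' @param mesh original outer [tri_mesh()].
#' @param inflated inflated version of `mesh` with identical topology.
#' @return numeric vector of depths (mm), minimum exactly 0.
#' @export
sp_depth <- function(mesh, inflated) {
  if (n_vertices(mesh) != n_vertices(inflated) ||
      !identical(mesh$faces, inflated$faces))
    stop("mesh and inflated surface must share topology and vertex correspondence")
  nrm <- vertex_normals(inflated)
  disp <- rowSums((mesh$vertices - inflated$vertices) * nrm)
  disp - min(disp)
}

#' Total and per-region surface area
#'
#' Sum of triangle areas. With labels, each triangle is assigned to the
#' majority label of its three vertices (ties broken toward the lowest region
#' id) so that per-region areas partition the total exactly.
#'
#' @param mesh a [tri_mesh()].
#' @param labels optional per-vertex region labels (defaults to
#'   `mesh$vertex_labels`); use `NULL` for total area only.
#' @return list with `total` (mm^2) and, when labels are available,
#'   `by_region` (named numeric vector).
#' @export
surface_area <- function(mesh, labels = mesh$vertex_labels) {
  fg <- face_geometry(mesh)
  out <- list(total = sum(fg$area))
  if (!is.null(labels)) {
    f <- mesh$faces
    lab3 <- cbind(labels[f[, 1]], labels[f[, 2]], labels[f[, 3]])
    tri_lab <- apply(lab3, 1, function(l) {
      tb <- table(l)
      cand <- as.integer(names(tb)[tb == max(tb)])
      min(cand)
    })
    s <- rowsum(fg$area, tri_lab)
    out$by_region <- stats::setNames(s[, 1], rownames(s))
  }
  out
}

#' Regional volumes from a label volume
#'
#' Voxel count per label multiplied by the voxel volume; the whole-brain total
#' is the sum over all nonzero labels.
#'
#' @param volume a [label_volume()].
#' @return list with `by_region` (named mm^3 vector) and `total` (mm^3).
#' @export
region_volume <- function(volume) {
  stopifnot(inherits(volume, "label_volume"))
  vv <- volume$voxel_size^3
  tb <- table(volume$grid[volume$grid != 0L])
  by_region <- stats::setNames(as.numeric(tb) * vv, names(tb))
  list(by_region = by_region, total = sum(by_region))
}

#' Per-region medians of a vertex field
#'
#' Median of the per-vertex values within each region (over the vertices of
#' that region in the supplied labeling). Excluded labels are dropped; a
#' region with no vertices yields `NA`, never 0.
#'
#' @param values numeric per-vertex field.
#' @param labels per-vertex region labels (same length).
#' @param exclude labels to drop (e.g. a cingular-pole label).
#' @return named numeric vector of medians, one per retained region.
#' @export
regional_median <- function(values, labels, exclude = NULL) {
  if (length(values) != length(labels)) stop("values and labels lengths differ")
  keep <- !(labels %in% exclude) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  regs <- sort(unique(labels))
  out <- vapply(regs, function(r) {
    v <- values[labels == r]
    if (length(v) == 0L) NA_real_ else stats::median(v)
  }, numeric(1))
  stats::setNames(out, regs)
}

#' Discrete mean curvature (cotangent weights)
#' @keywords internal
#' @noRd
mean_curvature <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- n_vertices(mesh)
  Hvec <- matrix(0, n, 3)
  area <- numeric(n)
  fg <- face_geometry(mesh)
  # accumulate cot-weighted edge vectors: for each face corner k (apex),
  # the opposite edge (i,j) receives weight cot(angle at k)
  for (k in 1:3) {
    i <- f[, (k %% 3) + 1]
    j <- f[, ((k + 1) %% 3) + 1]
    a <- f[, k]
    u <- v[i, , drop = FALSE] - v[a, , drop = FALSE]
    w <- v[j, , drop = FALSE] - v[a, , drop = FALSE]
    cosang <- rowSums(u * w)
    cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                u[, 3] * w[, 1] - u[, 1] * w[, 3],
                u[, 1] * w[, 2] - u[, 2] * w[, 1])
    sinang <- sqrt(rowSums(cr^2))
    cot <- cosang / pmax(sinang, .Machine$double.eps)
    eij <- v[j, , drop = FALSE] - v[i, , drop = FALSE]
    for (d in 1:3) {
      Hvec[, d] <- Hvec[, d] + tapply_sum(cot * eij[, d], i, n)
      Hvec[, d] <- Hvec[, d] + tapply_sum(-cot * eij[, d], j, n)
    }
    area <- area + tapply_sum(fg$area / 3, a, n)
  }
  # |mean curvature normal| / 2 gives |H| per vertex
  sqrt(rowSums(Hvec^2)) / (4 * pmax(area, .Machine$double.eps))
}

#' Surface quality metrics against a label volume
#'
#' `smoothness_error` is the mean over vertices of the absolute difference
#' between a vertex's discrete mean curvature and the mean curvature of its
#' one-ring neighbors (cotangent-weighted discretization).
#' `boundary_distance_error` is the mean Euclidean distance from each vertex
#' to the nearest voxel center on the label boundary (labeled voxels with at
#' least one 6-neighbor outside the labeling).
#'
#' @param mesh a [tri_mesh()] in the world frame of `volume`.
#' @param volume a [label_volume()] in the same frame.
#' @return list with `smoothness_error` and `boundary_distance_error` (mm).
#' @export
surface_qc <- function(mesh, volume) {
  stopifnot(inherits(volume, "label_volume"))
  H <- mean_curvature(mesh)
  adj <- vertex_adjacency(mesh)
  nb <- vapply(adj, function(ii) mean(H[ii]), numeric(1))
  smoothness <- mean(abs(H - nb))

  bnd <- boundary_voxel_centers(volume)
  if (nrow(bnd) == 0L) stop("label volume has an empty boundary mask")
  d <- nn_distance(mesh$vertices, bnd)
  list(smoothness_error = smoothness, boundary_distance_error = mean(d))
}

# world-mm centers of labeled voxels adjacent to background (6-connectivity)
boundary_voxel_centers <- function(volume) {
  g <- volume$grid != 0L
  dm <- dim(g)
  pad <- array(FALSE, dm + 2L)
  pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- g
  core <- pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)]
  nb_all <-
    pad[1:dm[1], 2:(dm[2] + 1), 2:(dm[3] + 1)] &
    pad[3:(dm[1] + 2), 2:(dm[2] + 1), 2:(dm[3] + 1)] &
    pad[2:(dm[1] + 1), 1:dm[2], 2:(dm[3] + 1)] &
    pad[2:(dm[1] + 1), 3:(dm[2] + 2), 2:(dm[3] + 1)] &
    pad[2:(dm[1] + 1), 2:(dm[2] + 1), 1:dm[3]] &
    pad[2:(dm[1] + 1), 2:(dm[2] + 1), 3:(dm[3] + 2)]
  idx <- which(core & !nb_all, arr.ind = TRUE)
  t(volume$origin + t((idx - 0.5) * volume$voxel_size))
}

# chunked brute-force nearest-neighbor distances from points to a target set
nn_distance <- function(points, targets, chunk = 512L) {
  np <- nrow(points)
  out <- numeric(np)
  t2 <- rowSums(targets^2)
  for (s in seq(1L, np, by = chunk)) {
    e <- min(s + chunk - 1L, np)
    P <- points[s:e, , drop = FALSE]
    cp <- tcrossprod(P, targets)              # n_chunk x n_targets
    d2 <- outer(rowSums(P^2), t2, "+") - 2 * cp
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}
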