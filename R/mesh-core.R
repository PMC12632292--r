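#' Triangle mesh in world millimetres
#'
#' Lightweight container for a closed triangle surface. Vertices are stored as
#' an `n x 3` numeric matrix of world coordinates (mm), faces as an `m x 3`
#' integer matrix of 1-based vertex indices with consistent (outward)
#' orientation. Optional per-vertex region labels and hemisphere codes carry
#' the parcellation used by the regional morphometry operations.
#'
#' @param vertices numeric `n x 3` matrix of vertex coordinates (mm).
#' @param faces integer `m x 3` matrix of 1-based vertex indices.
#' @param vertex_labels optional integer region id per vertex.
#' @param vertex_hemi optional character per-vertex hemisphere, `"L"`/`"R"`.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, vertex_labels = NULL, vertex_hemi = NULL) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  n <- nrow(vertices)
  if (any(faces < 1L) || any(faces > n)) stop("faces index vertices outside 1..n")
  if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
          faces[, 1] == faces[, 3]))
    stop("degenerate faces (repeated vertex index)")
  if (!is.null(vertex_labels) && length(vertex_labels) != n)
    stop("vertex_labels length must equal number of vertices")
  if (!is.null(vertex_hemi) && length(vertex_hemi) != n)
    stop("vertex_hemi length must equal number of vertices")
  structure(list(vertices = vertices, faces = faces,
                 vertex_labels = if (is.null(vertex_labels)) NULL else as.integer(vertex_labels),
                 vertex_hemi = vertex_hemi),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat("tri_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces")
  if (!is.null(x$vertex_labels))
    cat(",", length(unique(x$vertex_labels)), "vertex label(s)")
  cat("\n")
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

#' Per-face areas and normals
#' @keywords internal
#' @noRd
face_geometry <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm <- sqrt(rowSums(cr^2))
  list(area = nrm / 2, normal = cr / pmax(nrm, .Machine$double.eps))
}

#' Outward unit vertex normals
#'
#' Area-weighted average of incident face normals, normalized to unit length.
#'
#' @param mesh a [tri_mesh()].
#' @return `n x 3` matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  fg <- face_geometry(mesh)
  n <- n_vertices(mesh)
  acc <- matrix(0, n, 3L)
  w <- fg$area
  for (k in 1:3) {
    idx <- mesh$faces[, k]
    for (d in 1:3)
      acc[, d] <- acc[, d] + unname(tapply_sum(w * fg$normal[, d], idx, n))
  }
  len <- sqrt(rowSums(acc^2))
  acc / pmax(len, .Machine$double.eps)
}

# rowsum() keyed on a full 1..n index range
tapply_sum <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Vertex one-ring adjacency
#' @keywords internal
#' @noRd
vertex_adjacency <- function(mesh) {
  f <- mesh$faces
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  edges <- rbind(edges, edges[, 2:1])
  edges <- unique(edges)
  split(edges[, 2], factor(edges[, 1], levels = seq_len(n_vertices(mesh))))
}

#' Test whether a mesh is closed (every edge shared by exactly two faces)
#' @param mesh a [tri_mesh()].
#' @return logical scalar.
#' @export
is_closed_mesh <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Icosphere mesh
#'
#' Regular icosahedron subdivided `subdivisions` times, vertices projected to
#' radius `radius`. Subdivision `s` gives `20 * 4^s` faces. The vertex set is
#' symmetric under reflection about each coordinate plane, which the
#' parcellation fixtures rely on for exact left/right mirroring.
#'
#' @param radius sphere radius (mm).
#' @param subdivisions number of 1-to-4 triangle subdivisions (>= 0).
#' @return a [tri_mesh()].
#' @export
icosphere <- function(radius = 1, subdivisions = 3L) {
  stopifnot(radius > 0, subdivisions >= 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    keys <- edge_key(e[, 1], e[, 2])
    uk <- unique(keys)
    mid_idx <- match(keys, uk) + nrow(v)
    ue <- e[!duplicated(keys), , drop = FALSE]
    mids <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
    v <- rbind(v, mids)
    m12 <- mid_idx[seq_len(nrow(f))]
    m23 <- mid_idx[nrow(f) + seq_len(nrow(f))]
    m31 <- mid_idx[2 * nrow(f) + seq_len(nrow(f))]
    f <- rbind(cbind(f[, 1], m12, m31),
               cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23),
               cbind(m12, m23, m31))
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  tri_mesh(v, f)
}

#' Read / write Wavefront OBJ surfaces
#'
#' Plain-text mesh interchange. Per-vertex labels, when present, are written
#' to a sidecar CSV (`<path>.labels.csv` with columns `vertex,label,hemi`)
#' and picked up again by [read_obj()].
#'
#' @param mesh a [tri_mesh()].
#' @param path file path for the `.obj` file.
#' @return `write_obj()` returns `path` invisibly; `read_obj()` a [tri_mesh()].
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d",
                     mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
  if (!is.null(mesh$vertex_labels)) {
    lab <- data.frame(vertex = seq_len(n_vertices(mesh)),
                      label = mesh$vertex_labels,
                      hemi = if (is.null(mesh$vertex_hemi)) NA_character_ else mesh$vertex_hemi)
    utils::write.csv(lab, paste0(path, ".labels.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_obj
#' @export
read_obj <- function(path) {
  ln <- readLines(path)
  vl <- ln[startsWith(ln, "v ")]
  fl <- ln[startsWith(ln, "f ")]
  v <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(p) as.numeric(p[2:4])))
  f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(p) as.integer(sub("/.*", "", p[2:4]))))
  labels <- NULL; hemi <- NULL
  side <- paste0(path, ".labels.csv")
  if (file.exists(side)) {
    lab <- utils::read.csv(side)
    labels <- lab$label[order(lab$vertex)]
    if (!all(is.na(lab$hemi))) hemi <- as.character(lab$hemi[order(lab$vertex)])
  }
  tri_mesh(v, f, vertex_labels = labels, vertex_hemi = hemi)
}
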