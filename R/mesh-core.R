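# Core mesh container and geometric primitives.
#
# A SurfaceMesh is the universal carrier for the pipeline: vertex
# coordinates in mm (model frame: +x mesial, +y labial, +z incisal),
# triangle connectivity, and an optional per-vertex binary material
# label (1 = enamel, 0 = dentin/cementum).

#' Construct a surface mesh
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle,
#'   consistently wound (counter-clockwise seen from outside).
#' @param material optional numeric vector of length n with per-vertex
#'   material values in `[0, 1]` (1 = enamel, 0 = dentin).
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, material = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L)
    stop("vertices must be an n x 3 matrix", call. = FALSE)
  if (nrow(vertices) == 0L)
    stop("invalid input: mesh has no vertices", call. = FALSE)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L)
    stop("faces must be an m x 3 matrix", call. = FALSE)
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range", call. = FALSE)
  if (!is.null(material)) {
    material <- as.numeric(material)
    if (length(material) != nrow(vertices))
      stop("material must have one value per vertex", call. = FALSE)
  }
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces, material = material),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh: %d vertices, %d faces%s>\n",
              nrow(x$vertices), nrow(x$faces),
              if (is.null(x$material)) "" else ", material labels"))
  invisible(x)
}

#' Number of vertices / faces
#' @param mesh a `surface_mesh`.
#' @return integer count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

# ---- cleaning ---------------------------------------------------------------

#' Merge duplicate vertices and drop degenerate faces
#'
#' Vertices coincident within `tol` are merged (the lowest index is kept;
#' vertex order is otherwise preserved) and faces with repeated vertices
#' or zero area are dropped. STL files store a vertex soup, so this is
#' applied at load time. The default tolerance is far below micro-CT
#' scan resolution (~30 um).
#'
#' @param mesh a `surface_mesh`.
#' @param tol merge tolerance in mm.
#' @return cleaned `surface_mesh`.
#' @export
clean_mesh <- function(mesh, tol = 1e-9) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  # map every vertex to the first occurrence of its key
  remap <- match(key, key[first])
  keep_idx <- which(first)
  new_v <- v[keep_idx, , drop = FALSE]
  new_f <- matrix(remap[mesh$faces], ncol = 3L)
  mat <- if (is.null(mesh$material)) NULL else mesh$material[keep_idx]
  # drop faces that collapsed onto fewer than 3 distinct vertices
  degen <- new_f[, 1] == new_f[, 2] | new_f[, 2] == new_f[, 3] |
    new_f[, 1] == new_f[, 3]
  if (any(!degen)) {
    nf <- new_f[!degen, , drop = FALSE]
    # also drop exactly zero-area faces (collinear vertices)
    a <- new_v[nf[, 2], , drop = FALSE] - new_v[nf[, 1], , drop = FALSE]
    b <- new_v[nf[, 3], , drop = FALSE] - new_v[nf[, 1], , drop = FALSE]
    cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                a[, 1] * b[, 2] - a[, 2] * b[, 1])
    zero <- rowSums(cr * cr) == 0
    nf <- nf[!zero, , drop = FALSE]
  } else {
    nf <- new_f[0, , drop = FALSE]
  }
  surface_mesh(new_v, nf, mat)
}

# ---- area / volume ----------------------------------------------------------

face_cross <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Total surface area
#'
#' @param mesh a `surface_mesh`.
#' @return area in mm^2 (sum of triangle areas).
#' @export
surface_area <- function(mesh) {
  cr <- face_cross(mesh)
  sum(sqrt(rowSums(cr * cr))) / 2
}

#' Enclosed volume of a closed mesh
#'
#' Signed-tetrahedron sum over faces (divergence theorem); the absolute
#' value is returned so the result does not depend on global winding
#' direction. The mesh must be closed: every edge shared by exactly two
#' faces with opposite orientation.
#'
#' @param mesh a closed, consistently wound `surface_mesh`.
#' @return volume in mm^3.
#' @export
enclosed_volume <- function(mesh) {
  nb <- n_boundary_edges(mesh)
  if (nb > 0L)
    stop(sprintf("precondition failed: mesh is not closed (%d boundary edges)", nb),
         call. = FALSE)
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  det6 <- p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
    p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
    p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
  abs(sum(det6)) / 6
}

# ---- edges ------------------------------------------------------------------

# undirected edge table: one row per (face, edge), columns lo, hi, face
edge_table <- function(mesh) {
  f <- mesh$faces
  e <- rbind(cbind(f[, 1], f[, 2]),
             cbind(f[, 2], f[, 3]),
             cbind(f[, 3], f[, 1]))
  data.frame(lo = pmin(e[, 1], e[, 2]),
             hi = pmax(e[, 1], e[, 2]),
             face = rep(seq_len(nrow(f)), 3L))
}

edge_keys <- function(mesh) {
  et <- edge_table(mesh)
  list(key = et$lo * (n_vertices(mesh) + 1) + et$hi, table = et)
}

#' Number of boundary edges (edges used by exactly one face)
#' @param mesh a `surface_mesh`.
#' @return integer count.
#' @export
n_boundary_edges <- function(mesh) {
  ek <- edge_keys(mesh)
  tab <- table(ek$key)
  sum(tab == 1L)
}

#' Is the mesh closed?
#' @param mesh a `surface_mesh`.
#' @return `TRUE` if every edge is shared by exactly two faces.
#' @export
is_closed <- function(mesh) {
  ek <- edge_keys(mesh)
  tab <- table(ek$key)
  all(tab == 2L)
}

#' Median edge length
#' @param mesh a `surface_mesh`.
#' @return median undirected edge length in mm.
#' @export
median_edge_length <- function(mesh) {
  ek <- edge_keys(mesh)
  et <- ek$table[!duplicated(ek$key), ]
  d <- mesh$vertices[et$lo, , drop = FALSE] - mesh$vertices[et$hi, , drop = FALSE]
  stats::median(sqrt(rowSums(d * d)))
}

# ---- adjacency --------------------------------------------------------------

#' Edge-sharing face adjacency
#'
#' For each face, the indices of faces sharing an edge with it. Interior
#' faces of a closed manifold mesh have exactly three neighbours. A
#' non-manifold edge (shared by more than two faces) triggers a warning
#' and all pairings across it are recorded.
#'
#' @param mesh a `surface_mesh`.
#' @return list of integer vectors, one per face, class `element_adjacency`.
#' @export
build_adjacency <- function(mesh) {
  ek <- edge_keys(mesh)
  et <- ek$table
  ord <- order(ek$key)
  key <- ek$key[ord]
  face <- et$face[ord]
  runs <- rle(key)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  if (any(runs$lengths > 2L))
    warning(sprintf("%d non-manifold edge(s) (shared by >2 faces)",
                    sum(runs$lengths > 2L)), call. = FALSE)
  adj <- vector("list", n_faces(mesh))
  multi <- which(runs$lengths >= 2L)
  for (r in multi) {
    fs <- face[starts[r]:ends[r]]
    for (i in seq_along(fs)) {
      adj[[fs[i]]] <- c(adj[[fs[i]]], fs[-i])
    }
  }
  adj <- lapply(adj, function(x) sort(unique(x)))
  class(adj) <- "element_adjacency"
  adj
}

#' Vertex 1-ring neighbourhood as a sparse averaging operator
#'
#' Row i of the returned matrix holds weight 1/deg(i) on each 1-ring
#' neighbour of vertex i, so `W %*% V` gives per-vertex neighbour means
#' in one sparse product (used by synchronous Laplacian smoothing).
#'
#' @param mesh a `surface_mesh`.
#' @return a `dgCMatrix` of dimension n x n.
#' @export
vertex_ring_operator <- function(mesh) {
  ek <- edge_keys(mesh)
  et <- ek$table[!duplicated(ek$key), ]
  i <- c(et$lo, et$hi)
  j <- c(et$hi, et$lo)
  n <- n_vertices(mesh)
  a <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(a)
  deg[deg == 0] <- 1
  Matrix::Diagonal(x = 1 / deg) %*% a
}

# ---- normals / quality ------------------------------------------------------

#' Outward face normals (unit length)
#' @param mesh a `surface_mesh` with consistent winding.
#' @return m x 3 matrix of unit normals.
#' @export
face_normals <- function(mesh) {
  cr <- face_cross(mesh)
  len <- sqrt(rowSums(cr * cr))
  len[len == 0] <- 1
  cr / len
}

#' Area-weighted vertex normals (unit length)
#' @param mesh a `surface_mesh` with consistent winding.
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  cr <- face_cross(mesh)  # length = 2 * area, direction = face normal
  n <- n_vertices(mesh)
  out <- matrix(0, n, 3)
  f <- mesh$faces
  for (k in 1:3) {
    for (d in 1:3) {
      acc <- rowsum(cr[, d], f[, k], reorder = FALSE)
      out[as.integer(rownames(acc)), d] <- out[as.integer(rownames(acc)), d] + acc
    }
  }
  len <- sqrt(rowSums(out * out))
  len[len == 0] <- 1
  out / len
}

#' Triangle quality: 2 * inradius / circumradius
#'
#' Equals 1 for an equilateral triangle and tends to 0 for degenerate
#' slivers. Used in elastic-registration quality reports.
#'
#' @param mesh a `surface_mesh`.
#' @return numeric vector, one quality value in `[0, 1]` per face.
#' @export
triangle_quality <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  el <- function(i, j) sqrt(rowSums((v[f[, i], , drop = FALSE] -
                                       v[f[, j], , drop = FALSE])^2))
  a <- el(1, 2); b <- el(2, 3); c <- el(3, 1)
  s <- (a + b + c) / 2
  area2 <- pmax(s * (s - a) * (s - b) * (s - c), 0)
  area <- sqrt(area2)
  inr <- area / s
  circ <- a * b * c / pmax(4 * area, .Machine$double.xmin)
  q <- 2 * inr / circ
  q[area == 0] <- 0
  pmin(q, 1)
}

# ---- nearest neighbours -----------------------------------------------------

#' Exact nearest neighbours between point sets
#'
#' Exact (not approximate) search via a k-d tree; ties in distance are
#' broken by the lowest reference index so results are deterministic.
#'
#' @param query numeric matrix, q x 3.
#' @param reference numeric matrix, r x 3 (non-empty).
#' @return list with integer `index` (into `reference`) and numeric
#'   `distance` (mm), each of length q.
#' @export
nearest_vertices <- function(query, reference) {
  query <- as.matrix(query)
  reference <- as.matrix(reference)
  if (nrow(reference) == 0L)
    stop("invalid input: reference point set is empty", call. = FALSE)
  if (ncol(query) != 3L || ncol(reference) != 3L)
    stop("point sets must be n x 3 matrices", call. = FALSE)
  storage.mode(query) <- "double"
  storage.mode(reference) <- "double"
  cpp_nearest(query, reference)
}

#' Vertex centroid
#' @param mesh a `surface_mesh`.
#' @return length-3 numeric vector (mm).
#' @export
mesh_centroid <- function(mesh) colMeans(mesh$vertices)
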