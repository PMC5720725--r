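# Elastic mesh-to-mesh registration: morph the (aligned, scaled)
# baseline onto each target so the whole cohort shares the baseline's
# connectivity, rebuild the mean and re-register (two passes), and
# transfer enamel labels onto the registered meshes.
#
# The elastic scheme used here moves every baseline vertex a fixed
# fraction alpha toward its exact nearest target vertex each iteration,
# and regularises by Laplacian-smoothing the *displacement field* (not
# the positions) with a geometrically decaying weight, so late
# iterations fit fine detail and a perfectly fitted mesh is a fixed
# point of the update.

#' Shape vector: flattened registered representation of one specimen
#'
#' @param mesh a `surface_mesh` on the cohort's shared connectivity.
#' @param material optional per-node material values in `[0, 1]`; taken
#'   from `mesh$material` when present and not overridden.
#' @return object of class `shape_vector` with fields `values`
#'   (`[x1, y1, z1, (I1), ...]`), `M` (node count) and `has_material`.
#' @export
shape_vector <- function(mesh, material = NULL) {
  if (is.null(material)) material <- mesh$material
  m <- n_vertices(mesh)
  if (!is.null(material)) {
    if (length(material) != m)
      stop("material must have one value per node", call. = FALSE)
    if (any(material < 0 | material > 1))
      stop("invalid input: material values must lie in [0, 1]", call. = FALSE)
    values <- as.numeric(t(cbind(mesh$vertices, material)))
  } else {
    values <- as.numeric(t(mesh$vertices))
  }
  structure(list(values = values, M = m, has_material = !is.null(material)),
            class = "shape_vector")
}

shape_vector_from_values <- function(values, has_material) {
  k <- if (has_material) 4L else 3L
  if (length(values) %% k != 0L)
    stop("shape vector length inconsistent with material flag", call. = FALSE)
  structure(list(values = as.numeric(values), M = length(values) %/% k,
                 has_material = has_material),
            class = "shape_vector")
}

#' Rebuild a mesh from a shape vector
#' @param sv a `shape_vector`.
#' @param faces m x 3 face matrix of the cohort's shared connectivity.
#' @return a `surface_mesh` (with material labels when present).
#' @export
shape_to_mesh <- function(sv, faces) {
  k <- if (sv$has_material) 4L else 3L
  m <- matrix(sv$values, ncol = k, byrow = TRUE)
  surface_mesh(m[, 1:3, drop = FALSE], faces,
               material = if (sv$has_material) m[, 4] else NULL)
}

#' Registered cohort: specimens on shared connectivity
#'
#' @param faces shared face matrix (baseline connectivity).
#' @param vectors list of `shape_vector`, one per specimen.
#' @param ids character specimen ids.
#' @param groups character group labels.
#' @param reports optional per-specimen registration quality reports.
#' @return object of class `registered_cohort`.
#' @export
registered_cohort <- function(faces, vectors, ids = NULL, groups = NULL,
                              reports = NULL) {
  if (length(vectors) == 0L)
    stop("invalid input: empty cohort", call. = FALSE)
  m <- vectors[[1]]$M
  hm <- vectors[[1]]$has_material
  ok <- vapply(vectors, function(v) v$M == m && v$has_material == hm, TRUE)
  if (!all(ok))
    stop("all shape vectors must share node count and material flag",
         call. = FALSE)
  if (is.null(ids)) ids <- sprintf("s%03d", seq_along(vectors))
  structure(list(faces = faces, vectors = vectors, ids = ids,
                 groups = groups, M = m, has_material = hm,
                 reports = reports),
            class = "registered_cohort")
}

#' Cohort as an N x V matrix (one row per specimen)
#' @param cohort a `registered_cohort`.
#' @return numeric matrix.
#' @export
cohort_matrix <- function(cohort) {
  do.call(rbind, lapply(cohort$vectors, function(v) v$values))
}

# ---- Laplacian smoothing ----------------------------------------------------

#' Laplacian smoothing of a mesh
#'
#' Each vertex moves by `weight` times the offset from itself to the
#' mean of its 1-ring neighbours; the update is synchronous (Jacobi
#' style, order-independent) and repeated `passes` times.
#'
#' @param mesh a `surface_mesh`.
#' @param weight smoothing weight lambda in `[0, 1]`.
#' @param passes number of passes.
#' @return smoothed `surface_mesh` (connectivity unchanged).
#' @export
laplacian_smooth <- function(mesh, weight, passes = 1L) {
  w <- vertex_ring_operator(mesh)
  v <- mesh$vertices
  for (i in seq_len(passes))
    v <- (1 - weight) * v + weight * as.matrix(w %*% v)
  mesh$vertices <- v
  mesh
}

# ---- elastic registration ---------------------------------------------------

#' Elastic registration of a baseline mesh onto a target
#'
#' Iterative scheme: at iteration t each baseline vertex is pulled a
#' fraction `alpha` toward its exact nearest target vertex; the
#' displacement field is Laplacian-smoothed once with weight
#' `lambda0 * decay^(t-1)` before being applied, so early iterations
#' deform smoothly and late iterations fit fine detail. Stops when the
#' mean vertex displacement falls below `tol` or after `max_iter`
#' iterations. Connectivity is never changed.
#'
#' @param baseline `surface_mesh`, pre-aligned and pre-scaled to the target.
#' @param target `surface_mesh`.
#' @param alpha step fraction toward the nearest target vertex.
#' @param lambda0 initial Laplacian weight for the displacement field.
#' @param decay geometric decay ratio of the Laplacian weight.
#' @param tol convergence threshold on mean vertex displacement (mm).
#' @param max_iter iteration cap.
#' @return list with `mesh` (morphed baseline) and `report` (mean/max
#'   distance-to-target in mm, min triangle quality, iterations,
#'   convergence flag).
#' @export
elastic_register <- function(baseline, target, alpha = 0.5, lambda0 = 0.5,
                             decay = 0.9, tol = 1e-4, max_iter = 200L) {
  v <- baseline$vertices
  w <- vertex_ring_operator(baseline)
  n0 <- face_normals(baseline)
  lambda <- lambda0
  converged <- FALSE
  iterations <- 0L
  prev_dist <- Inf
  n_worse <- 0L
  dist_trace <- numeric()
  for (it in seq_len(max_iter)) {
    iterations <- it
    nn <- nearest_vertices(v, target$vertices)
    mean_dist <- mean(nn$distance)
    dist_trace <- c(dist_trace, mean_dist)
    if (mean_dist > prev_dist) {
      n_worse <- n_worse + 1L
      if (n_worse >= 10L)
        stop(paste0("elastic registration diverged (mean distance increased ",
                    "10 consecutive iterations); trace: ",
                    paste(signif(utils::tail(dist_trace, 12), 6), collapse = " ")),
             call. = FALSE)
    } else n_worse <- 0L
    prev_dist <- mean_dist
    u <- alpha * (target$vertices[nn$index, , drop = FALSE] - v)
    u <- (1 - lambda) * u + lambda * as.matrix(w %*% u)
    v <- v + u
    lambda <- lambda * decay
    if (mean(sqrt(rowSums(u * u))) < tol) {
      converged <- TRUE
      break
    }
  }
  out <- baseline
  out$vertices <- v
  flipped <- which(rowSums(face_normals(out) * n0) < 0)
  if (length(flipped) > 0L)
    warning(sprintf("elastic registration inverted %d face(s): %s",
                    length(flipped),
                    paste(utils::head(flipped, 10), collapse = ", ")),
            call. = FALSE)
  nn <- nearest_vertices(v, target$vertices)
  report <- list(mean_dist = mean(nn$distance), max_dist = max(nn$distance),
                 min_quality = min(triangle_quality(out)),
                 iterations = iterations, converged = converged)
  list(mesh = out, report = report)
}

#' Mean shape of a registered cohort
#'
#' Component-wise arithmetic mean of the cohort's shape vectors.
#'
#' @param cohort a `registered_cohort`.
#' @return a `shape_vector`.
#' @export
compute_mean_shape <- function(cohort) {
  shape_vector_from_values(colMeans(cohort_matrix(cohort)),
                           cohort$has_material)
}

#' Transfer enamel labels onto a registered mesh
#'
#' Each registered node is labelled enamel (I = 1) when its distance to
#' the nearest enamel-mesh vertex is at most `delta`, else dentin (0).
#' The default cutoff of one median target edge length keeps the
#' transferred boundary within one edge of the true CEJ: after elastic
#' registration the nodes lie essentially on the target surface, so true
#' enamel nodes sit within a fraction of an edge of an enamel vertex
#' while dentin nodes are at least one edge away.
#'
#' @param registered `surface_mesh` on baseline connectivity, in the
#'   target's frame.
#' @param enamel_mesh `surface_mesh` of the enamel surface, same frame.
#' @param delta distance cutoff (mm).
#' @return numeric per-node labels in `{0, 1}`.
#' @export
transfer_material <- function(registered, enamel_mesh,
                              delta = median_edge_length(registered)) {
  if (n_vertices(enamel_mesh) == 0L || nrow(enamel_mesh$vertices) == 0L) {
    warning("empty enamel mesh: all nodes labelled dentin", call. = FALSE)
    return(rep(0, n_vertices(registered)))
  }
  nn <- nearest_vertices(registered$vertices, enamel_mesh$vertices)
  as.numeric(nn$distance <= delta)
}

#' Extract the enamel submesh from a labelled whole-tooth mesh
#'
#' Keeps faces whose three vertices are all labelled enamel; unused
#' vertices are dropped.
#'
#' @param mesh a `surface_mesh` with material labels (or `material` given).
#' @param material optional per-vertex labels overriding `mesh$material`.
#' @return a `surface_mesh` of the enamel cap (open along the CEJ).
#' @export
extract_enamel_mesh <- function(mesh, material = NULL) {
  if (is.null(material)) material <- mesh$material
  if (is.null(material)) stop("mesh has no material labels", call. = FALSE)
  lab <- material >= 0.5
  keep <- lab[mesh$faces[, 1]] & lab[mesh$faces[, 2]] & lab[mesh$faces[, 3]]
  f <- mesh$faces[keep, , drop = FALSE]
  used <- sort(unique(as.integer(f)))
  remap <- integer(n_vertices(mesh))
  remap[used] <- seq_along(used)
  surface_mesh(mesh$vertices[used, , drop = FALSE],
               matrix(remap[f], ncol = 3L))
}

#' Two-pass cohort registration
#'
#' Pass 1 rigidly aligns and elastically registers the initial baseline
#' to every target; the mean shape of pass 1 becomes the baseline for
#' pass 2 (the mean geometry is closer to every specimen, improving
#' registration quality). Enamel labels are transferred after pass 2.
#'
#' @param training list of specimens; each element needs `mesh` (whole
#'   tooth `surface_mesh`) and either `enamel` (enamel `surface_mesh`) or
#'   material labels on the mesh (from which the enamel submesh is cut).
#'   Optional `id` and `group` fields are carried through.
#' @param initial_baseline `surface_mesh` used as the pass-1 baseline.
#' @param alpha,lambda0,decay,tol,max_iter passed to [elastic_register()].
#' @param delta material-transfer cutoff (mm); `NULL` for the per-target
#'   default of [transfer_material()].
#' @param icp_iter,global_init rigid pre-alignment settings per target;
#'   training meshes are normally already in the model frame, so the
#'   principal-axes global initialisation is off by default.
#' @return a `registered_cohort` with material, plus per-pass mean
#'   distance summaries in `attr(, "pass_summary")`.
#' @export
two_pass_register <- function(training, initial_baseline,
                              alpha = 0.5, lambda0 = 0.5, decay = 0.9,
                              tol = 1e-4, max_iter = 200L, delta = NULL,
                              icp_iter = 50L, global_init = FALSE) {
  if (length(training) < 2L)
    stop("invalid input: need at least 2 training specimens", call. = FALSE)
  register_pass <- function(baseline_mesh) {
    lapply(training, function(sp) {
      al <- align_chain(baseline_mesh, sp$mesh, max_iter = icp_iter,
                        global_init = global_init)
      res <- tryCatch(
        elastic_register(al$mesh, sp$mesh, alpha = alpha, lambda0 = lambda0,
                         decay = decay, tol = tol, max_iter = max_iter),
        error = function(e) stop(sprintf("registration failed for specimen '%s': %s",
                                         sp$id %||% "?", conditionMessage(e)),
                                 call. = FALSE))
      res
    })
  }
  base1 <- initial_baseline
  base1$material <- NULL
  pass1 <- register_pass(base1)
  mean_v <- Reduce(`+`, lapply(pass1, function(r) r$mesh$vertices)) /
    length(pass1)
  mean_mesh <- surface_mesh(mean_v, base1$faces)
  pass2 <- register_pass(mean_mesh)

  vectors <- vector("list", length(training))
  for (i in seq_along(training)) {
    sp <- training[[i]]
    enamel <- if (!is.null(sp$enamel)) sp$enamel
              else extract_enamel_mesh(sp$mesh)
    reg <- pass2[[i]]$mesh
    d <- if (is.null(delta)) median_edge_length(sp$mesh) else delta
    mat <- transfer_material(reg, enamel, delta = d)
    vectors[[i]] <- shape_vector(reg, material = mat)
  }
  ids <- vapply(training, function(sp) sp$id %||% NA_character_, "")
  if (anyNA(ids)) ids <- NULL
  groups <- vapply(training, function(sp) sp$group %||% NA_character_, "")
  if (anyNA(groups)) groups <- NULL
  cohort <- registered_cohort(base1$faces, vectors, ids = ids, groups = groups,
                              reports = lapply(pass2, function(r) r$report))
  attr(cohort, "pass_summary") <- list(
    pass1_mean_dist = mean(vapply(pass1, function(r) r$report$mean_dist, 0)),
    pass2_mean_dist = mean(vapply(pass2, function(r) r$report$mean_dist, 0)))
  cohort
}

`%||%` <- function(a, b) if (is.null(a)) b else a
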