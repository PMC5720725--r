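# Material binarisation, element-level smoothing of the enamel/dentin
# partition, and extraction of the cemento-enamel junction (CEJ) as a
# continuous boundary curve.
#
# Synthetic instances generated from the shape model carry probabilistic
# material values I in [0, 1]; the anatomical CEJ is smooth, continuous
# and free of isolated enamel or cementum islands, so the values are
# thresholded at the mid-range and the element partition smoothed until
# no element has two or more opposite-material neighbours.

#' Binarise probabilistic material values
#'
#' `Ih = 1` iff `I >= 0.5` (threshold at the mid-range value).
#'
#' @param I numeric per-node values in `[0, 1]`.
#' @return numeric per-node values in `{0, 1}`.
#' @export
binarize <- function(I) {
  if (any(I < 0 | I > 1, na.rm = TRUE) || anyNA(I))
    stop("invalid input: material values must lie in [0, 1]", call. = FALSE)
  as.numeric(I >= 0.5)
}

#' Element materials from node labels
#'
#' Majority vote of each triangle's three node labels (2-of-3; with
#' binary labels on triangles no tie is possible).
#'
#' @param mesh a `surface_mesh`.
#' @param Ih numeric per-node labels in `{0, 1}`.
#' @return numeric per-element labels in `{0, 1}`.
#' @export
elements_from_nodes <- function(mesh, Ih) {
  f <- mesh$faces
  votes <- Ih[f[, 1]] + Ih[f[, 2]] + Ih[f[, 3]]
  as.numeric(votes >= 2)
}

#' Smooth the element-level material partition
#'
#' Sweeps over the elements in index order: an element with two or more
#' edge-neighbours of the opposite material is flipped immediately
#' (sequential update), and sweeps repeat until one makes no flips or
#' `max_iter` is reached. The fixed order keeps the result
#' deterministic. A sequential schedule is used rather than a
#' synchronous one because along a straight staircase boundary on a
#' structured triangulation, synchronous flips put the entire boundary
#' band into a two-cycle that never terminates; the sequential sweep
#' provably stops only at a state where no element violates the rule.
#'
#' @param mesh a `surface_mesh`.
#' @param materials per-element labels in `{0, 1}`.
#' @param max_iter sweep cap.
#' @param adjacency optional precomputed [build_adjacency()] result.
#' @return smoothed per-element labels with attributes `iterations` and
#'   `converged`.
#' @export
smooth_materials <- function(mesh, materials, max_iter = 100L,
                             adjacency = NULL) {
  adj <- if (is.null(adjacency)) build_adjacency(mesh) else adjacency
  m <- as.numeric(materials)
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    changed <- FALSE
    for (i in seq_along(adj)) {
      if (sum(m[adj[[i]]] != m[i]) >= 2) {
        m[i] <- 1 - m[i]
        changed <- TRUE
      }
    }
    if (!changed) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning(sprintf("material smoothing did not converge in %d sweeps", max_iter),
            call. = FALSE)
  attr(m, "iterations") <- iterations
  attr(m, "converged") <- converged
  m
}

#' Node labels from element materials
#'
#' Majority vote over each node's incident elements; ties resolve to
#' enamel (1) so the crown cap stays closed.
#'
#' @param mesh a `surface_mesh`.
#' @param materials per-element labels in `{0, 1}`.
#' @return numeric per-node labels in `{0, 1}`.
#' @export
nodes_from_elements <- function(mesh, materials) {
  f <- mesh$faces
  n <- n_vertices(mesh)
  votes <- numeric(n)
  counts <- numeric(n)
  for (k in 1:3) {
    acc <- rowsum(as.numeric(materials), f[, k], reorder = FALSE)
    idx <- as.integer(rownames(acc))
    votes[idx] <- votes[idx] + acc
    cnt <- rowsum(rep(1, nrow(f)), f[, k], reorder = FALSE)
    counts[idx] <- counts[idx] + cnt
  }
  counts[counts == 0] <- 1
  as.numeric(votes / counts >= 0.5)
}

#' Extract the CEJ boundary curve(s)
#'
#' Boundary edges (shared by one enamel and one dentin element) are
#' chained into closed loops by edge-adjacency walking; loops are sorted
#' by length (mm) descending. A continuous, anatomically plausible CEJ
#' corresponds to exactly one loop. Branch points (a boundary vertex
#' with more than two boundary edges) abort the affected loop with a
#' warning.
#'
#' @param mesh a `surface_mesh`.
#' @param materials smoothed per-element labels in `{0, 1}`.
#' @return object of class `cej_curve`: list with `loops` (each an
#'   ordered closed vector of vertex indices), `lengths` (mm) and
#'   `n_loops`.
#' @export
extract_cej <- function(mesh, materials) {
  ek <- edge_keys(mesh)
  et <- ek$table
  ord <- order(ek$key)
  key <- ek$key[ord]
  runs <- rle(key)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  two <- which(runs$lengths == 2L)
  b_lo <- integer(); b_hi <- integer()
  for (r in two) {
    i1 <- ord[starts[r]]; i2 <- ord[ends[r]]
    if (materials[et$face[i1]] != materials[et$face[i2]]) {
      b_lo <- c(b_lo, et$lo[i1])
      b_hi <- c(b_hi, et$hi[i1])
    }
  }
  if (length(b_lo) == 0L) {
    warning("no material boundary: single-material mesh", call. = FALSE)
    return(structure(list(loops = list(), lengths = numeric(), n_loops = 0L),
                     class = "cej_curve"))
  }
  # vertex -> incident boundary edges
  nb <- length(b_lo)
  inc <- split(rep(seq_len(nb), 2L), c(b_lo, b_hi))
  used <- rep(FALSE, nb)
  loops <- list()
  for (e0 in seq_len(nb)) {
    if (used[e0]) next
    v_start <- b_lo[e0]
    loop <- c(v_start)
    used[e0] <- TRUE
    v_cur <- b_hi[e0]
    ok <- TRUE
    repeat {
      loop <- c(loop, v_cur)
      if (v_cur == v_start) break
      cand <- inc[[as.character(v_cur)]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0L) { ok <- FALSE; break }
      if (length(cand) > 1L) {
        warning(sprintf("branch point at vertex %d: loop aborted", v_cur),
                call. = FALSE)
        ok <- FALSE; break
      }
      e <- cand[1]
      used[e] <- TRUE
      v_cur <- if (b_lo[e] == v_cur) b_hi[e] else b_lo[e]
    }
    if (ok) loops[[length(loops) + 1L]] <- loop
  }
  lens <- vapply(loops, function(lp) {
    d <- mesh$vertices[lp[-1], , drop = FALSE] -
      mesh$vertices[lp[-length(lp)], , drop = FALSE]
    sum(sqrt(rowSums(d * d)))
  }, 0)
  o <- order(lens, decreasing = TRUE)
  structure(list(loops = loops[o], lengths = lens[o],
                 n_loops = length(loops)),
            class = "cej_curve")
}

#' @export
print.cej_curve <- function(x, ...) {
  cat(sprintf("<cej_curve: %d loop(s); lengths %s mm>\n", x$n_loops,
              paste(signif(x$lengths, 4), collapse = ", ")))
  invisible(x)
}

#' All vertex indices on the CEJ curve
#' @param cej a `cej_curve`.
#' @return sorted integer vector.
#' @export
cej_vertices <- function(cej) {
  sort(unique(unlist(cej$loops)))
}

#' Full material pipeline for a synthetic instance
#'
#' Binarise per-node values, vote elements, smooth the partition,
#' re-derive node labels and extract the CEJ.
#'
#' @param mesh a `surface_mesh`.
#' @param I per-node probabilistic material values (defaults to
#'   `mesh$material`).
#' @param max_iter smoothing sweep cap.
#' @return list with `node_material`, `element_material`, `cej`.
#' @export
material_pipeline <- function(mesh, I = mesh$material, max_iter = 100L) {
  ih <- binarize(I)
  elem <- elements_from_nodes(mesh, ih)
  elem <- smooth_materials(mesh, elem, max_iter = max_iter)
  nodes <- nodes_from_elements(mesh, elem)
  cej <- extract_cej(mesh, elem)
  list(node_material = nodes, element_material = elem, cej = cej)
}
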