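# Rigid pre-registration: per-axis bounding-box scaling of the baseline
# to each target, centroid (origin) alignment, an optional programmatic
# coarse transform standing in for interactive manual alignment, and
# point-to-point iterative closest point (ICP) refinement.

#' Rigid transform (proper rotation + translation)
#'
#' @param rotation 3 x 3 proper orthogonal matrix (det = +1).
#' @param translation length-3 numeric vector (mm).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)))
    stop("rotation must be 3 x 3", call. = FALSE)
  if (abs(det(rotation) - 1) > 1e-9 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation must be proper orthogonal", call. = FALSE)
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points or a mesh
#' @param transform a `rigid_transform`.
#' @param x an n x 3 point matrix or a `surface_mesh`.
#' @return transformed points or mesh.
#' @export
apply_transform <- function(transform, x) {
  if (inherits(x, "surface_mesh")) {
    x$vertices <- apply_transform(transform, x$vertices)
    return(x)
  }
  sweep(as.matrix(x) %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Compose rigid transforms: `compose_transforms(a, b)` applies `b` first
#' @param a,b `rigid_transform` objects.
#' @return the composite `rigid_transform` a \%*\% b.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  rt <- t(transform$rotation)
  rigid_transform(rt, -as.numeric(rt %*% transform$translation))
}

#' Serialise a rigid transform as a 4 x 4 homogeneous matrix
#' @param transform a `rigid_transform`.
#' @return 4 x 4 numeric matrix.
#' @export
as_homogeneous <- function(transform) {
  m <- diag(4)
  m[1:3, 1:3] <- transform$rotation
  m[1:3, 4] <- transform$translation
  m
}

#' Per-axis bounding-box scaling of the baseline to a target
#'
#' Maximum and minimum extents of both meshes are measured along x, y
#' and z; the baseline is scaled per axis, about its own centroid, so
#' its extents equal the target's.
#'
#' @param baseline,target `surface_mesh` objects.
#' @return list with `mesh` (scaled baseline) and `scale` (length-3
#'   positive factors sx, sy, sz).
#' @export
bbox_scale <- function(baseline, target) {
  eb <- apply(baseline$vertices, 2, range)
  et <- apply(target$vertices, 2, range)
  ext_b <- eb[2, ] - eb[1, ]
  ext_t <- et[2, ] - et[1, ]
  if (any(ext_b == 0))
    stop("invalid input: baseline has zero extent on an axis", call. = FALSE)
  s <- ext_t / ext_b
  ctr <- mesh_centroid(baseline)
  baseline$vertices <- sweep(sweep(baseline$vertices, 2, ctr, "-"),
                             2, s, "*")
  baseline$vertices <- sweep(baseline$vertices, 2, ctr, "+")
  list(mesh = baseline, scale = s)
}

#' Origin (centroid) alignment
#'
#' @param source,target `surface_mesh` objects.
#' @return translation-only `rigid_transform` moving the source centroid
#'   onto the target centroid.
#' @export
origin_align <- function(source, target) {
  rigid_transform(diag(3), mesh_centroid(target) - mesh_centroid(source))
}

#' Coarse transform from Euler angles and an offset
#'
#' Z-Y-X intrinsic convention: `R = Rz(a1) Ry(a2) Rx(a3)`. Stands in for
#' the interactive manual-alignment step of the original workflow.
#'
#' @param angles length-3 numeric, rotations about z, y, x (radians).
#' @param offset length-3 numeric translation (mm).
#' @return a `rigid_transform`.
#' @export
coarse_transform <- function(angles = c(0, 0, 0), offset = c(0, 0, 0)) {
  if (!all(is.finite(c(angles, offset))))
    stop("invalid input: non-finite angles/offset", call. = FALSE)
  cz <- cos(angles[1]); sz <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cx <- cos(angles[3]); sx <- sin(angles[3])
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  rigid_transform(rz %*% ry %*% rx, offset)
}

# closed-form rigid fit (Kabsch / SVD of the cross-covariance,
# reflection-corrected) minimising sum |R p + t - q|^2
kabsch <- function(p, q) {
  pc <- colMeans(p); qc <- colMeans(q)
  h <- crossprod(sweep(p, 2, pc, "-"), sweep(q, 2, qc, "-"))
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  r <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(r, qc - as.numeric(r %*% pc))
}

#' Point-to-point iterative closest point
#'
#' Per iteration, every source vertex is matched to its exact nearest
#' target vertex and the optimal rigid transform is solved in closed
#' form (SVD of the cross-covariance, reflection-corrected). The RMS
#' correspondence distance is monotone non-increasing by construction.
#'
#' @param source,target `surface_mesh` objects, roughly pre-aligned.
#' @param max_iter maximum iterations.
#' @param tol stop when the RMS improvement over one iteration falls
#'   below this (mm).
#' @param z_starts optional numeric vector of azimuthal restart angles
#'   (radians). Teeth are nearly rotationally symmetric about their long
#'   (z) axis, so plain point-to-point ICP locks into lattice minima
#'   within a few degrees of azimuth; when supplied, a full ICP run is
#'   started from each pre-rotation about the source centroid and the
#'   run with the lowest final RMS wins. `NULL` (default) runs the
#'   single plain start.
#' @return list with `transform` (cumulative `rigid_transform`), `rms`
#'   (final RMS correspondence distance, mm) and `trace` (per-iteration
#'   RMS values of the winning run; monotone non-increasing).
#' @export
icp <- function(source, target, max_iter = 100L, tol = 1e-6,
                z_starts = NULL) {
  if (any(!is.finite(source$vertices)) || any(!is.finite(target$vertices)))
    stop("invalid input: non-finite vertex coordinates", call. = FALSE)
  pts <- source$vertices
  run_from <- function(init) {
    cum <- init
    trace <- numeric()
    prev <- Inf
    for (it in seq_len(max_iter)) {
      cur <- apply_transform(cum, pts)
      nn <- nearest_vertices(cur, target$vertices)
      rms <- sqrt(mean(nn$distance^2))
      trace <- c(trace, rms)
      if (prev - rms < tol) break
      prev <- rms
      step <- kabsch(cur, target$vertices[nn$index, , drop = FALSE])
      cum <- compose_transforms(step, cum)
    }
    list(transform = cum, rms = trace[length(trace)], trace = trace)
  }
  best <- run_from(rigid_transform())
  if (!is.null(z_starts)) {
    ctr <- mesh_centroid(source)
    for (phi in z_starts) {
      if (phi == 0) next
      rot <- coarse_transform(c(phi, 0, 0))$rotation
      pre <- rigid_transform(rot, ctr - as.numeric(rot %*% ctr))
      cand <- run_from(pre)
      if (cand$rms < best$rms) best <- cand
    }
  }
  best
}

#' Full rigid pre-alignment chain
#'
#' Aligns and scales the baseline to a target in four steps: the
#' optional coarse transform; a global initialisation from principal
#' axes (the baseline's principal frame is rotated onto the target's,
#' trying all proper sign combinations and both pairings of the two
#' nearly degenerate cross-sectional axes, with per-axis scale estimated
#' rotation-invariantly from extents along matched principal axes);
#' point-to-point ICP from each candidate (plus optional azimuthal
#' jitter, see `z_starts`); and a final polish that alternates the
#' closed-form rigid fit with a per-axis scale re-estimate from the
#' current correspondences. Teeth are nearly rotationally symmetric
#' about their long axis, which gives plain ICP an exact-recovery basin
#' of only a few degrees; the principal-frame candidates land inside it.
#'
#' @param baseline,target `surface_mesh` objects.
#' @param coarse optional `rigid_transform` applied to the baseline first.
#' @param max_iter ICP iteration cap per start.
#' @param tol stop when the RMS improvement falls below this (mm).
#' @param z_starts azimuthal jitter angles (radians) added around each
#'   principal-frame candidate; `NULL` for none.
#' @param global_init use the principal-axes initialisation; set to
#'   `FALSE` when baseline and target are already roughly aligned (the
#'   identity start plus bounding-box scaling is then used alone).
#' @return list with `mesh` (the aligned, scaled baseline), `scale`
#'   (per-axis factors applied in the baseline frame about its
#'   centroid), `transform` (rigid part, a `rigid_transform`) and `rms`
#'   (final RMS distance to the target's nearest vertices).
#' @export
align_chain <- function(baseline, target, coarse = NULL,
                        max_iter = 60L, tol = 1e-12,
                        z_starts = c(-6, -3, 3, 6) * pi / 180,
                        global_init = TRUE) {
  base <- baseline
  if (!is.null(coarse)) base <- apply_transform(coarse, base)
  ctr <- mesh_centroid(base)
  p0 <- sweep(base$vertices, 2, ctr, "-")
  t_ctr <- mesh_centroid(target)
  q0 <- sweep(target$vertices, 2, t_ctr, "-")

  principal <- function(v) {
    e <- eigen(crossprod(v) / nrow(v), symmetric = TRUE)
    list(axes = e$vectors,
         extents = apply(v %*% e$vectors, 2, function(x) diff(range(x))))
  }

  # candidate (rotation, scale) initialisations
  cands <- list()
  if (global_init) {
    pb <- principal(p0)
    pt <- principal(q0)
    # model-axis index best aligned with each baseline principal axis
    axis_of <- apply(abs(pb$axes), 2, which.max)
    pairings <- list(1:3, c(1, 3, 2))  # cross axes may swap under scaling
    for (pair in pairings) {
      et <- pt$extents[pair]
      s <- numeric(3)
      s[axis_of] <- et / pb$extents
      if (any(!is.finite(s)) || any(s <= 0)) next
      ebs <- principal(sweep(p0, 2, s, "*"))$axes
      for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
        sg <- c(s1, s2, 1)
        r0 <- pt$axes[, pair] %*% diag(sg) %*% t(ebs)
        if (det(r0) < 0) r0 <- pt$axes[, pair] %*% diag(sg * c(1, 1, -1)) %*% t(ebs)
        cands[[length(cands) + 1L]] <- list(r = r0, s = s)
        for (phi in z_starts %||% numeric()) {
          # azimuthal jitter about the target's long axis
          axis <- pt$axes[, pair][, 1]
          K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                        -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
          rj <- diag(3) + sin(phi) * K + (1 - cos(phi)) * K %*% K
          cands[[length(cands) + 1L]] <- list(r = rj %*% r0, s = s)
        }
      }
    }
  }
  cands[[length(cands) + 1L]] <-
    list(r = diag(3), s = bbox_scale(base, target)$scale)

  run_from <- function(r, s) {
    u <- t_ctr - colMeans(sweep(p0, 2, s, "*") %*% t(r))
    prev <- Inf
    rms <- Inf
    for (it in seq_len(max_iter)) {
      cur <- sweep(sweep(p0, 2, s, "*") %*% t(r), 2, u, "+")
      nn <- nearest_vertices(cur, target$vertices)
      rms <- sqrt(mean(nn$distance^2))
      if (prev - rms < tol) break
      prev <- rms
      q <- target$vertices[nn$index, , drop = FALSE]
      for (k in 1:2) {
        kb <- kabsch(sweep(p0, 2, s, "*"), q)
        r <- kb$rotation
        u <- kb$translation
        y <- sweep(q, 2, u, "-") %*% r
        s <- pmax(colSums(p0 * y) / colSums(p0 * p0), 1e-12)
      }
    }
    list(rms = rms, r = r, s = s, u = u)
  }

  best <- NULL
  for (cand in cands) {
    res <- run_from(cand$r, cand$s)
    if (is.null(best) || res$rms < best$rms) best <- res
    if (best$rms < tol) break
  }
  mesh <- base
  mesh$vertices <- sweep(sweep(p0, 2, best$s, "*") %*% t(best$r),
                         2, best$u, "+")
  list(mesh = mesh, scale = best$s,
       transform = rigid_transform(best$r, best$u), rms = best$rms)
}
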