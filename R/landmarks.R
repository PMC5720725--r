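# Automated anatomical landmarking and gross measurement.
#
# All criteria are evaluated in the model frame (+x mesial, +y labial,
# +z incisal) with partition planes through the whole-mesh centroid.
# Crown landmarks are restricted to enamel-labelled nodes, CEJ landmarks
# to nodes on the extracted CEJ curve; ties break to the lowest vertex
# index so results are deterministic across platforms.

LANDMARK_NAMES <- c("RA", "CEJtLa", "CEJtLi", "CEJpM", "CEJpD",
                    "CmM", "CmD", "CmLa", "CmLi", "CmIE")

#' Detect the ten anatomical landmarks
#'
#' Criteria: `CmIE` = enamel node with max z (incisal edge); `RA` = node
#' with min z (root apex); `CmM`/`CmD` = enamel nodes with max/min x;
#' `CmLa`/`CmLi` = enamel nodes with max/min y; `CEJtLa`/`CEJtLi` = CEJ
#' node with min z in the labial (y > centroid) / lingual half;
#' `CEJpM`/`CEJpD` = CEJ node with max z in the mesial (x > centroid) /
#' distal half.
#'
#' @param mesh a `surface_mesh` in the model frame.
#' @param node_material per-node binary labels (1 = enamel).
#' @param cej a `cej_curve` (single loop expected).
#' @return object of class `landmark_set`: named list with `points`
#'   (10 x 3 matrix) and `vertex` (named source vertex indices).
#' @export
detect_landmarks <- function(mesh, node_material, cej) {
  v <- mesh$vertices
  ctr <- mesh_centroid(mesh)
  enamel <- which(node_material >= 0.5)
  if (length(enamel) == 0L)
    stop("landmark failure: no enamel nodes", call. = FALSE)
  cv <- cej_vertices(cej)
  if (length(cv) == 0L)
    stop("landmark failure: empty CEJ curve", call. = FALSE)

  pick <- function(cand, coord, maximise, name) {
    if (length(cand) == 0L)
      stop(sprintf("landmark failure: empty candidate set for %s", name),
           call. = FALSE)
    vals <- v[cand, coord]
    best <- if (maximise) max(vals) else min(vals)
    cand[which(vals == best)][1]  # lowest vertex index on ties
  }

  idx <- c(
    RA     = pick(seq_len(nrow(v)), 3, FALSE, "RA"),
    CEJtLa = pick(cv[v[cv, 2] > ctr[2]], 3, FALSE, "CEJtLa"),
    CEJtLi = pick(cv[v[cv, 2] < ctr[2]], 3, FALSE, "CEJtLi"),
    CEJpM  = pick(cv[v[cv, 1] > ctr[1]], 3, TRUE, "CEJpM"),
    CEJpD  = pick(cv[v[cv, 1] < ctr[1]], 3, TRUE, "CEJpD"),
    CmM    = pick(enamel, 1, TRUE, "CmM"),
    CmD    = pick(enamel, 1, FALSE, "CmD"),
    CmLa   = pick(enamel, 2, TRUE, "CmLa"),
    CmLi   = pick(enamel, 2, FALSE, "CmLi"),
    CmIE   = pick(enamel, 3, TRUE, "CmIE")
  )
  pts <- v[idx, , drop = FALSE]
  rownames(pts) <- names(idx)
  structure(list(points = pts, vertex = idx), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set>\n")
  print(round(x$points, 4))
  invisible(x)
}

#' Gross measurements from landmarks
#'
#' Euclidean 3D inter-landmark distances: `LDCc` (CEJtLa-CEJtLi), `LDC`
#' (CmLa-CmLi), `MDCc` (CEJpM-CEJpD), `MDC` (CmM-CmD), `LORla`
#' (RA-CEJtLa), `LOCla` (CEJtLa-CmIE); plus enclosed volume (mm^3) and
#' surface area (mm^2). An open mesh yields `vol = NA` with a warning.
#'
#' @param landmarks a `landmark_set`.
#' @param mesh the measured `surface_mesh` (closed for volume).
#' @return named numeric vector (class `measurement_record`).
#' @export
measure <- function(landmarks, mesh) {
  p <- landmarks$points
  d <- function(a, b) sqrt(sum((p[a, ] - p[b, ])^2))
  vol <- tryCatch(enclosed_volume(mesh), error = function(e) {
    warning("open mesh: volume omitted", call. = FALSE)
    NA_real_
  })
  out <- c(LDCc = d("CEJtLa", "CEJtLi"), LDC = d("CmLa", "CmLi"),
           MDCc = d("CEJpM", "CEJpD"), MDC = d("CmM", "CmD"),
           LORla = d("RA", "CEJtLa"), LOCla = d("CEJtLa", "CmIE"),
           vol = vol, area = surface_area(mesh))
  class(out) <- c("measurement_record", class(out))
  out
}

MEASUREMENT_NAMES <- c("LDCc", "LDC", "MDCc", "MDC", "LORla", "LOCla",
                       "vol", "area")

#' Measurement sweep across sigma levels of one PC
#'
#' For each level: generate the instance, binarise and smooth materials,
#' extract the CEJ, landmark and measure. This is the table feeding the
#' PC-versus-measurement regressions.
#'
#' @param model a `shape_model` fitted with material.
#' @param faces shared connectivity of the model's cohort.
#' @param pc PC index.
#' @param levels sigma levels (default -3..+3).
#' @return data.frame with columns `pc`, `level`, the eight measurements
#'   and `note` (landmark failures are annotated, measurements NA).
#' @export
measure_sweep <- function(model, faces, pc, levels = -3:3) {
  rows <- lapply(levels, function(lv) {
    sv <- sigma_sweep(model, pc, levels = lv)[[1]]
    mesh <- shape_to_mesh(sv, faces)
    rec <- tryCatch({
      mp <- material_pipeline(mesh)
      lm <- detect_landmarks(mesh, mp$node_material, mp$cej)
      list(vals = as.numeric(measure(lm, mesh)), note = "")
    }, error = function(e) list(vals = rep(NA_real_, 8L),
                                note = conditionMessage(e)))
    df <- as.data.frame(as.list(rec$vals))
    names(df) <- MEASUREMENT_NAMES
    cbind(data.frame(pc = pc, level = lv), df, data.frame(note = rec$note))
  })
  do.call(rbind, rows)
}
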