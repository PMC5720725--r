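# Correlation-method PCA over shape vectors (geometry + material),
# synthetic instance generation, projection, variance accounting, sigma
# sweeps and the reconstruction-error test.
#
# Because coordinates (mm) and material labels (unitless) mix units,
# every variable is standardised before decomposition (the correlation
# method). Instances are generated as x = xbar + s * (Phi d): the
# per-variable scale s re-enters at generation, which is the
# correlation-method reading of the usual mean-plus-weighted-modes
# instance equation. User-facing weights are expressed in per-PC
# standard deviations (sigma units); raw score units are available via
# the units flag.

#' PC weight vector
#' @param values numeric coefficients, one per leading PC.
#' @param units `"sigma"` (multiples of each PC's score sd, the
#'   user-facing convention) or `"raw"` (score units).
#' @return object of class `pc_weights`.
#' @export
pc_weights <- function(values, units = c("sigma", "raw")) {
  units <- match.arg(units)
  if (any(!is.finite(values)))
    stop("invalid input: non-finite weights", call. = FALSE)
  structure(list(values = as.numeric(values), units = units),
            class = "pc_weights")
}

raw_weights <- function(model, weights, c = length(weights$values)) {
  if (c > model$n_pcs)
    stop(sprintf("invalid input: c = %d exceeds available PCs (%d)",
                 c, model$n_pcs), call. = FALSE)
  w <- numeric(model$n_pcs)
  k <- min(c, length(weights$values))
  w[seq_len(k)] <- weights$values[seq_len(k)]
  if (c < model$n_pcs) w[(c + 1L):model$n_pcs] <- 0
  if (weights$units == "sigma") w <- w * sqrt(model$eigenvalues)
  w
}

#' Fit a correlation-method shape model
#'
#' Each variable is centred and divided by its standard deviation
#' (1/(N-1) normalisation); variables with sd below `epsilon` are marked
#' constant and excluded from the basis (most material components are
#' identical across specimens deep in the root or crown). PCs are
#' obtained from the thin SVD of the standardised N x V matrix -- the
#' V x V matrix is never formed. Eigenvector signs are fixed by making
#' each PC's largest-magnitude loading positive, so sweeps are
#' reproducible across platforms.
#'
#' @param cohort a `registered_cohort` (N >= 2).
#' @param use_material include material components when present.
#' @param epsilon constancy threshold on the per-variable sd (native units).
#' @return object of class `shape_model`.
#' @export
fit_model <- function(cohort, use_material = TRUE, epsilon = 1e-8) {
  x <- cohort_matrix(cohort)
  has_material <- cohort$has_material
  if (has_material && !use_material) {
    keep <- rep(c(TRUE, TRUE, TRUE, FALSE), cohort$M)
    x <- x[, keep, drop = FALSE]
    has_material <- FALSE
  }
  n <- nrow(x)
  if (n < 2L) stop("invalid input: need N >= 2 specimens", call. = FALSE)
  mu <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  constant <- s < epsilon
  if (all(constant))
    stop("invalid input: all variables constant", call. = FALSE)
  active <- which(!constant)
  z <- sweep(sweep(x[, active, drop = FALSE], 2, mu[active], "-"),
             2, s[active], "/")
  sv <- svd(z, nu = 0)
  eig <- sv$d^2 / (n - 1)
  keep <- which(sv$d > max(sv$d) * 1e-9 & eig > .Machine$double.eps)
  phi <- sv$v[, keep, drop = FALSE]
  eig <- eig[keep]
  # deterministic sign: largest-magnitude loading positive
  if (ncol(phi) > 0L) {
    for (j in seq_len(ncol(phi))) {
      i <- which.max(abs(phi[, j]))
      if (phi[i, j] < 0) phi[, j] <- -phi[, j]
    }
  }
  structure(list(mean = mu, scale = s, constant_mask = constant,
                 active = active, eigenvectors = phi, eigenvalues = eig,
                 n_pcs = length(eig), n_samples = n,
                 var_frac = if (length(eig)) eig / sum(eig) else numeric(),
                 has_material = has_material,
                 M = if (has_material) length(mu) %/% 4L else length(mu) %/% 3L),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("<shape_model: %d nodes, %d specimens, %d PCs%s>\n",
              x$M, x$n_samples, x$n_pcs,
              if (x$has_material) ", geometry+material" else ", geometry"))
  invisible(x)
}

#' Generate a synthetic shape instance
#'
#' Computes `x = xbar + s * sum_j phi_j d_j` over the first `c` PCs,
#' with sigma-unit weights converted via `d_j = w_j * sqrt(lambda_j)`.
#' Constant variables are emitted at their constant values; material
#' components are clamped to `[0, 1]`.
#'
#' @param model a `shape_model`.
#' @param weights a `pc_weights` (all-zero weights give the mean shape).
#' @param c number of PCs to use (defaults to all available).
#' @return a `shape_vector`.
#' @export
generate_instance <- function(model, weights, c = model$n_pcs) {
  d <- raw_weights(model, weights, c)
  x <- model$mean
  if (model$n_pcs > 0L)
    x[model$active] <- x[model$active] +
      model$scale[model$active] * as.numeric(model$eigenvectors %*% d)
  if (model$has_material) {
    mi <- seq(4L, length(x), by = 4L)
    x[mi] <- pmin(pmax(x[mi], 0), 1)
  }
  shape_vector_from_values(x, model$has_material)
}

#' Project a shape onto the model's PC basis
#'
#' Returns the raw-unit weighting coefficients
#' `d = Phi^T ((x - xbar) / s)` over the active variables.
#'
#' @param model a `shape_model`.
#' @param shape a `shape_vector` (or bare numeric vector) of matching length.
#' @return a `pc_weights` in raw units.
#' @export
project <- function(model, shape) {
  x <- if (inherits(shape, "shape_vector")) shape$values else as.numeric(shape)
  if (length(x) != length(model$mean))
    stop("invalid input: shape length does not match model", call. = FALSE)
  z <- (x[model$active] - model$mean[model$active]) / model$scale[model$active]
  pc_weights(as.numeric(crossprod(model$eigenvectors, z)), units = "raw")
}

#' Convert raw-unit weights to sigma units
#' @param model a `shape_model`.
#' @param weights a `pc_weights`.
#' @return a `pc_weights` in sigma units.
#' @export
as_sigma_weights <- function(model, weights) {
  if (weights$units == "sigma") return(weights)
  pc_weights(weights$values / sqrt(model$eigenvalues[seq_along(weights$values)]),
             units = "sigma")
}

#' Per-PC variance fractions
#' @param model a `shape_model`.
#' @return data.frame with columns `pc`, `eigenvalue`, `fraction`,
#'   `cumulative`.
#' @export
variance_report <- function(model) {
  data.frame(pc = seq_len(model$n_pcs), eigenvalue = model$eigenvalues,
             fraction = model$var_frac, cumulative = cumsum(model$var_frac))
}

#' Smallest number of PCs reaching a cumulative variance target
#' @param model a `shape_model`.
#' @param cumulative_target fraction in (0, 1].
#' @return integer c.
#' @export
choose_c <- function(model, cumulative_target) {
  if (cumulative_target <= 0 || cumulative_target > 1)
    stop("invalid input: cumulative target must be in (0, 1]", call. = FALSE)
  cum <- cumsum(model$var_frac)
  idx <- which(cum >= cumulative_target - 1e-12)
  if (length(idx) == 0L) model$n_pcs else idx[1]
}

#' Sigma sweep of one PC
#'
#' Generates one instance per level with `d_pc = level * sqrt(lambda_pc)`
#' and all other weights zero.
#'
#' @param model a `shape_model`.
#' @param pc PC index.
#' @param levels numeric sweep levels in sigma units (default -3..+3).
#' @return named list of `shape_vector`s, one per level.
#' @export
sigma_sweep <- function(model, pc, levels = -3:3) {
  if (pc > model$n_pcs)
    stop("invalid input: pc exceeds available PCs", call. = FALSE)
  out <- lapply(levels, function(lv) {
    w <- numeric(pc)
    w[pc] <- lv
    generate_instance(model, pc_weights(w, "sigma"), c = pc)
  })
  names(out) <- as.character(levels)
  out
}

#' Reconstruction-error test
#'
#' Each training specimen is reconstructed from its first k projected
#' weighting coefficients, for each k in `k_range`. The surface error is
#' the mean over reconstructed nodes of the Euclidean distance to the
#' nearest vertex of that specimen's registered target geometry; the
#' standardised-space error is the RMS residual in the standardised
#' variable space (monotone non-increasing in k exactly).
#'
#' @param model a `shape_model` fitted on `cohort`.
#' @param cohort the `registered_cohort` used to fit the model.
#' @param k_range integer vector of PC counts (default 0..all).
#' @param space `"surface"` (mm) or `"standardised"`.
#' @return numeric matrix, specimens x k values, dimnames = (ids, k).
#' @export
reconstruction_error_test <- function(model, cohort,
                                      k_range = 0:model$n_pcs,
                                      space = c("surface", "standardised")) {
  space <- match.arg(space)
  x <- cohort_matrix(cohort)
  if (cohort$has_material && !model$has_material)
    x <- x[, rep(c(TRUE, TRUE, TRUE, FALSE), cohort$M), drop = FALSE]
  errs <- matrix(NA_real_, nrow(x), length(k_range),
                 dimnames = list(cohort$ids, as.character(k_range)))
  for (i in seq_len(nrow(x))) {
    w <- project(model, x[i, ])
    target_geom <- shape_to_mesh(cohort$vectors[[i]], cohort$faces)$vertices
    z_i <- (x[i, model$active] - model$mean[model$active]) /
      model$scale[model$active]
    for (j in seq_along(k_range)) {
      k <- k_range[j]
      if (space == "standardised") {
        zk <- if (k == 0L) rep(0, length(z_i))
              else as.numeric(model$eigenvectors[, seq_len(k), drop = FALSE] %*%
                                w$values[seq_len(k)])
        errs[i, j] <- sqrt(mean((z_i - zk)^2))
      } else {
        inst <- generate_instance(model, w, c = k)
        vm <- shape_to_mesh(inst, cohort$faces)$vertices
        nn <- nearest_vertices(vm, target_geom)
        errs[i, j] <- mean(nn$distance)
      }
    }
  }
  errs
}

#' Save / load a shape model (JSON)
#'
#' @param model a `shape_model`.
#' @param path file path.
#' @return `path` invisibly, or the restored `shape_model`.
#' @export
save_model <- function(model, path) {
  obj <- unclass(model)
  obj$eigenvectors <- as.numeric(obj$eigenvectors)
  obj$eigenvector_rows <- length(model$active)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$eigenvectors <- matrix(obj$eigenvectors, nrow = obj$eigenvector_rows)
  obj$eigenvector_rows <- NULL
  obj$constant_mask <- as.logical(obj$constant_mask)
  structure(obj, class = "shape_model")
}
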