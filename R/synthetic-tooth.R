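# Parametric generator of canine-like tooth meshes with enamel/dentin
# surface labels, and of study-like populations with known, recoverable
# modes of variation.
#
# The tooth is a surface of revolution with azimuth-dependent elliptical
# radius: a convex elliptical crown cap (incisal apex at max z), a root
# tapering to a single apex (min z) displaced mesially by the curvature
# parameter, and a cemento-enamel junction (CEJ) whose height varies
# sinusoidally with azimuth -- peaks on the mesial/distal (+/-x) aspects,
# troughs on the labial/lingual (+/-y) aspects. Every gross measurement
# therefore has a closed-form target, which the tests exploit.

# axial position (fraction of crown length, from cervix) of the crown's
# maximum diameter; fixed so connectivity is identical across specimens
CROWN_BULGE_U <- 0.35

#' Parameters of a synthetic canine-like tooth
#'
#' Defaults approximate a permanent mandibular canine (mm): crown 11,
#' root 16, mesiodistal crown diameter 7, labiolingual 7.5, cervix
#' diameters 5.5 / 7, ~1 mm mesial apex displacement and a 1.5 mm CEJ
#' peak-to-trough amplitude.
#'
#' @param crown_length crown length, cervix plane to incisal edge (mm).
#' @param root_length root length, cervix plane to apex (mm).
#' @param md_diameter_crown,ll_diameter_crown maximum mesiodistal /
#'   labiolingual crown diameters (mm).
#' @param md_diameter_cervix,ll_diameter_cervix diameters at the cervix
#'   plane (mm); must not exceed the crown diameters.
#' @param root_curvature mesiodistal (+x) displacement of the root apex (mm).
#' @param apex_taper dimensionless taper exponent (> 0) of the root profile.
#' @param cej_amplitude CEJ peak-to-trough height (mm), must be smaller
#'   than `crown_length`.
#' @param mesh_resolution integer vector `c(n_theta, n_axial)`: azimuthal
#'   and axial sample counts. The default yields ~3k vertices.
#' @return a list of class `tooth_params`.
#' @export
tooth_params <- function(crown_length = 11, root_length = 16,
                         md_diameter_crown = 7, ll_diameter_crown = 7.5,
                         md_diameter_cervix = 5.5, ll_diameter_cervix = 7,
                         root_curvature = 1, apex_taper = 0.8,
                         cej_amplitude = 1.5,
                         mesh_resolution = c(48L, 64L)) {
  p <- list(crown_length = crown_length, root_length = root_length,
            md_diameter_crown = md_diameter_crown,
            ll_diameter_crown = ll_diameter_crown,
            md_diameter_cervix = md_diameter_cervix,
            ll_diameter_cervix = ll_diameter_cervix,
            root_curvature = root_curvature, apex_taper = apex_taper,
            cej_amplitude = cej_amplitude,
            mesh_resolution = as.integer(mesh_resolution))
  lens <- c("crown_length", "root_length", "md_diameter_crown",
            "ll_diameter_crown", "md_diameter_cervix", "ll_diameter_cervix")
  if (any(unlist(p[lens]) <= 0))
    stop("invalid input: all lengths must be > 0", call. = FALSE)
  if (p$apex_taper <= 0)
    stop("invalid input: apex_taper must be > 0", call. = FALSE)
  if (p$cej_amplitude < 0 || p$cej_amplitude >= p$crown_length)
    stop("invalid input: cej_amplitude must be in [0, crown_length)", call. = FALSE)
  class(p) <- "tooth_params"
  p
}

# crown radial profile: ratio rho = cervix/crown semi-axis at u = 0,
# maximum 1 at u = um, elliptical tip reaching 0 at u = 1; C1 at um
crown_profile <- function(u, rho, um = CROWN_BULGE_U) {
  out <- numeric(length(u))
  lo <- u <= um
  out[lo] <- rho + (1 - rho) * sin(pi * u[lo] / (2 * um))
  out[!lo] <- sqrt(pmax(1 - ((u[!lo] - um) / (1 - um))^2, 0))
  out
}

# CEJ height above the cervix plane as a function of azimuth:
# peaks (+amp/2) mesial/distal, troughs (-amp/2) labial/lingual
cej_height <- function(theta, amplitude) (amplitude / 2) * cos(2 * theta)

#' Generate one synthetic tooth
#'
#' @param params a `tooth_params` object.
#' @return list with `mesh` (closed `surface_mesh` whose `material` field
#'   holds the binary enamel label) and `material` (the same per-vertex
#'   0/1 vector).
#' @export
generate_tooth <- function(params = tooth_params()) {
  stopifnot(inherits(params, "tooth_params"))
  nt <- params$mesh_resolution[1]
  na <- params$mesh_resolution[2]
  if (nt < 8L)
    stop("invalid input: need at least 8 azimuthal samples to resolve the CEJ",
         call. = FALSE)
  Lc <- params$crown_length; Lr <- params$root_length
  a_cr <- params$md_diameter_crown / 2; b_cr <- params$ll_diameter_crown / 2
  a_cv <- params$md_diameter_cervix / 2; b_cv <- params$ll_diameter_cervix / 2
  theta <- 2 * pi * (seq_len(nt) - 1L) / nt

  # fixed crown/root split of the axial budget (approximate anatomical
  # proportion): the ring-to-parameter map must not depend on the
  # specimen's lengths, so vertices correspond across a population by
  # construction
  nc <- max(4L, round(na * 0.4))
  nr <- max(4L, na - nc)
  u_grid <- sort(unique(c(CROWN_BULGE_U, seq(0, 1, length.out = nc + 1L))))
  u_grid <- u_grid[u_grid < 1]              # u = 1 is the incisal pole
  s_grid <- seq(0, 1, length.out = nr + 1L)
  s_grid <- s_grid[s_grid > 0 & s_grid < 1] # s = 0 dup of u = 0; s = 1 apex

  rings <- list()
  ring_z <- numeric()
  # crown rings, top to bottom
  for (u in rev(u_grid)) {
    ga <- crown_profile(u, a_cv / a_cr)
    gb <- crown_profile(u, b_cv / b_cr)
    rings[[length(rings) + 1L]] <-
      cbind(a_cr * ga * cos(theta), b_cr * gb * sin(theta),
            rep(u * Lc, nt))
    ring_z <- c(ring_z, u * Lc)
  }
  # root rings, continuing downward; apex sheared mesially
  for (s in s_grid) {
    sc <- (1 - s)^params$apex_taper
    rings[[length(rings) + 1L]] <-
      cbind(a_cv * sc * cos(theta) + params$root_curvature * s^2,
            b_cv * sc * sin(theta),
            rep(-s * Lr, nt))
    ring_z <- c(ring_z, -s * Lr)
  }

  n_ring <- length(rings)
  verts <- do.call(rbind, rings)
  top_pole <- c(0, 0, Lc)
  apex_pole <- c(params$root_curvature, 0, -Lr)
  verts <- rbind(verts, top_pole, apex_pole)
  i_top <- n_ring * nt + 1L
  i_apex <- n_ring * nt + 2L

  ring_idx <- function(r) ((r - 1L) * nt + 1L):(r * nt)
  faces <- vector("list", n_ring + 1L)
  nxt <- c(seq_len(nt)[-1], 1L)
  # top fan
  r1 <- ring_idx(1L)
  faces[[1]] <- cbind(i_top, r1, r1[nxt])
  # side quads
  for (r in seq_len(n_ring - 1L)) {
    up <- ring_idx(r); lo <- ring_idx(r + 1L)
    faces[[r + 1L]] <- rbind(cbind(up, lo, lo[nxt]),
                             cbind(up, lo[nxt], up[nxt]))
  }
  # apex fan (reversed so the normal points down/out)
  rl <- ring_idx(n_ring)
  faces[[n_ring + 1L]] <- cbind(i_apex, rl[nxt], rl)
  faces <- do.call(rbind, faces)

  # material: enamel wherever z exceeds the azimuth-dependent CEJ height
  theta_all <- rep(theta, n_ring)
  z_all <- rep(ring_z, each = nt)
  mat <- as.numeric(z_all > cej_height(theta_all, params$cej_amplitude))
  mat <- c(mat, 1, 0)  # incisal pole enamel, apex dentin

  mesh <- surface_mesh(verts, faces, material = mat)
  list(mesh = mesh, material = mat)
}

#' Analytic landmark positions of a noise-free generated tooth
#'
#' Closed-form positions of the ten anatomical landmarks implied by the
#' generator, used as ground truth in recovery tests.
#'
#' @param params a `tooth_params` object.
#' @return named list of length-3 numeric vectors (mm).
#' @export
tooth_true_landmarks <- function(params) {
  Lc <- params$crown_length; Lr <- params$root_length
  a_cr <- params$md_diameter_crown / 2; b_cr <- params$ll_diameter_crown / 2
  a_cv <- params$md_diameter_cervix / 2; b_cv <- params$ll_diameter_cervix / 2
  A <- params$cej_amplitude
  z_b <- CROWN_BULGE_U * Lc
  # CEJ troughs sit in the root at z = -A/2; peaks in the crown at z = +A/2
  y_t <- b_cv * (1 - (A / 2) / Lr)^params$apex_taper
  x_p <- a_cr * crown_profile(A / (2 * Lc), a_cv / a_cr)
  list(
    RA     = c(params$root_curvature, 0, -Lr),
    CEJtLa = c(0, y_t, -A / 2),
    CEJtLi = c(0, -y_t, -A / 2),
    CEJpM  = c(x_p, 0, A / 2),
    CEJpD  = c(-x_p, 0, A / 2),
    CmM    = c(a_cr, 0, z_b),
    CmD    = c(-a_cr, 0, z_b),
    CmLa   = c(0, b_cr, z_b),
    CmLi   = c(0, -b_cr, z_b),
    CmIE   = c(0, 0, Lc)
  )
}

#' Analytic gross measurements of a noise-free generated tooth
#'
#' @param params a `tooth_params` object.
#' @return named numeric vector with elements LDCc, LDC, MDCc, MDC,
#'   LORla, LOCla (mm).
#' @export
tooth_true_measurements <- function(params) {
  lm <- tooth_true_landmarks(params)
  d <- function(a, b) sqrt(sum((lm[[a]] - lm[[b]])^2))
  c(LDCc = d("CEJtLa", "CEJtLi"), LDC = d("CmLa", "CmLi"),
    MDCc = d("CEJpM", "CEJpD"), MDC = d("CmM", "CmD"),
    LORla = d("RA", "CEJtLa"), LOCla = d("CEJtLa", "CmIE"))
}

#' Specification of a synthetic study population
#'
#' Parameter values are drawn log-normally around each group's mean with
#' the stated coefficient of variation, keeping lengths positive.
#' Two optional population-level latent modes produce correlated
#' variation: `scale_cv` draws a common log-normal factor applied to all
#' mm-valued parameters (overall tooth size) and `crown_root_cv` draws a
#' factor applied to `crown_length` and inversely to `root_length`
#' (crown:root length ratio). Surface noise is added independently per
#' vertex along the outward normal.
#'
#' @param n integer vector, specimens per group.
#' @param groups named list of mean `tooth_params`, one per group
#'   (names are the group labels). Defaults to a single group "A".
#' @param cv per-parameter coefficient of variation: single number or a
#'   named vector over the mm-valued parameters.
#' @param scale_cv CV of the overall-scale latent mode.
#' @param crown_root_cv CV of the crown:root ratio latent mode.
#' @param noise amplitude (sd, mm) of surface noise along vertex normals.
#' @param seed integer RNG seed; the population is deterministic given it.
#' @param orthogonalize_modes treat the two latent modes as a designed
#'   experiment: the realised log-factors are whitened in-sample (exact
#'   sample sd, zero sample correlation, across the whole population)
#'   before the group structure is applied. At n ~ 30 the sample
#'   covariance of two iid factor draws fluctuates enough to rotate
#'   near-degenerate principal axes; orthogonalised factors isolate
#'   mode-recovery properties from that design noise.
#' @return a list of class `population_spec`.
#' @export
population_spec <- function(n, groups = NULL, cv = 0, scale_cv = 0,
                            crown_root_cv = 0, noise = 0, seed = 1L,
                            orthogonalize_modes = FALSE) {
  if (is.null(groups)) groups <- list(A = tooth_params())
  if (length(n) == 1L) n <- rep(n, length(groups))
  if (length(n) != length(groups))
    stop("invalid input: one sample size per group required", call. = FALSE)
  if (any(n < 1L)) stop("invalid input: n must be >= 1 per group", call. = FALSE)
  if (noise < 0) stop("invalid input: noise amplitude must be >= 0", call. = FALSE)
  structure(list(n = as.integer(n), groups = groups, cv = cv,
                 scale_cv = scale_cv, crown_root_cv = crown_root_cv,
                 noise = noise, seed = as.integer(seed),
                 orthogonalize_modes = isTRUE(orthogonalize_modes)),
            class = "population_spec")
}

# parameters that carry mm units and participate in CV / scale variation
MM_PARAMS <- c("crown_length", "root_length", "md_diameter_crown",
               "ll_diameter_crown", "md_diameter_cervix",
               "ll_diameter_cervix", "root_curvature", "cej_amplitude")

lognormal_factor <- function(cv, n = 1L) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))  # unit mean
}

#' Generate a synthetic study population
#'
#' @param spec a `population_spec`.
#' @return list of specimens, each a list with `id`, `group`, `mesh`
#'   (closed `surface_mesh` with material labels), `params` (the true
#'   per-specimen `tooth_params`), and `modes` (latent mode factors
#'   `scale`, `crown_root`).
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  cv <- spec$cv
  n_total <- sum(spec$n)
  # latent mode log-factors drawn up front (optionally orthogonalised)
  sd1 <- if (spec$scale_cv > 0) sqrt(log(1 + spec$scale_cv^2)) else 0
  sd2 <- if (spec$crown_root_cv > 0) sqrt(log(1 + spec$crown_root_cv^2)) else 0
  l1 <- stats::rnorm(n_total, 0, max(sd1, .Machine$double.eps))
  l2 <- stats::rnorm(n_total, 0, max(sd2, .Machine$double.eps))
  if (spec$orthogonalize_modes && n_total >= 3L) {
    l1 <- l1 - mean(l1)
    l2 <- l2 - mean(l2)
    l2 <- l2 - l1 * sum(l1 * l2) / sum(l1 * l1)  # zero sample correlation
    l1 <- l1 / stats::sd(l1) * sd1               # exact sample sd
    l2 <- l2 / stats::sd(l2) * sd2
  }
  m_scales <- if (sd1 > 0) exp(l1 - sd1^2 / 2) else rep(1, n_total)
  m_ratios <- if (sd2 > 0) exp(l2 - sd2^2 / 2) else rep(1, n_total)
  out <- list()
  k <- 0L
  for (g in seq_along(spec$groups)) {
    gname <- names(spec$groups)[g]
    base <- spec$groups[[g]]
    for (i in seq_len(spec$n[g])) {
      k <- k + 1L
      p <- base
      m_scale <- m_scales[k]
      m_ratio <- m_ratios[k]
      for (nm in MM_PARAMS) {
        cvi <- if (length(cv) == 1L && is.null(names(cv))) cv
               else if (nm %in% names(cv)) cv[[nm]] else 0
        if (p[[nm]] > 0) p[[nm]] <- p[[nm]] * lognormal_factor(cvi) * m_scale
      }
      p$crown_length <- p$crown_length * m_ratio
      p$root_length <- p$root_length / m_ratio
      tooth <- generate_tooth(p)
      mesh <- tooth$mesh
      if (spec$noise > 0) {
        nrm <- vertex_normals(mesh)
        mesh$vertices <- mesh$vertices +
          nrm * stats::rnorm(n_vertices(mesh), 0, spec$noise)
      }
      out[[k]] <- list(id = sprintf("%s%02d", gname, i), group = gname,
                       mesh = mesh, params = p,
                       modes = c(scale = m_scale, crown_root = m_ratio))
    }
  }
  out
}
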