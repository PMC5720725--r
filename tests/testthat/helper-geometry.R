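# Shared geometric fixtures and independent oracles, built in code.

# unit cube [0,1]^3: 8 vertices, 12 triangles, outward winding
make_unit_cube <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  f <- rbind(c(1, 3, 2), c(1, 4, 3),   # bottom (-z)
             c(5, 6, 7), c(5, 7, 8),   # top (+z)
             c(1, 2, 6), c(1, 6, 5),   # front (-y)
             c(2, 3, 7), c(2, 7, 6),   # right (+x)
             c(3, 4, 8), c(3, 8, 7),   # back (+y)
             c(4, 1, 5), c(4, 5, 8))   # left (-x)
  surface_mesh(v, f)
}

# icosphere by recursive subdivision of an icosahedron
make_icosphere <- function(subdiv = 2, radius = 1) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- matrix(c(1, 12, 6, 1, 6, 2, 1, 2, 8, 1, 8, 11, 1, 11, 12,
                2, 6, 10, 6, 12, 5, 12, 11, 3, 11, 8, 7, 8, 2, 9,
                4, 10, 5, 4, 5, 3, 4, 3, 7, 4, 7, 9, 4, 9, 10,
                5, 10, 6, 3, 5, 12, 7, 3, 11, 9, 7, 8, 10, 9, 2),
              ncol = 3, byrow = TRUE)
  for (i in seq_len(subdiv)) {
    cache <- new.env()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      p <- v[a, ] + v[b, ]
      v <<- rbind(v, p / sqrt(sum(p^2)))
      cache[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 4 * nrow(f), 3)
    for (r in seq_len(nrow(f))) {
      a <- f[r, 1]; b <- f[r, 2]; c <- f[r, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf[(4 * r - 3):(4 * r), ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  surface_mesh(v * radius, f)
}

# sphere with material split by hemisphere (z >= 0 enamel)
make_two_hemisphere_sphere <- function(subdiv = 3, radius = 1) {
  m <- make_icosphere(subdiv, radius)
  m$material <- as.numeric(m$vertices[, 3] >= 0)
  m
}

# O(nm) exhaustive nearest-neighbour oracle (ties -> lowest index)
brute_nn <- function(query, ref) {
  idx <- integer(nrow(query))
  d <- numeric(nrow(query))
  for (i in seq_len(nrow(query))) {
    dd <- sqrt(colSums((t(ref) - query[i, ])^2))
    j <- which(dd == min(dd))[1]
    idx[i] <- j
    d[i] <- dd[j]
  }
  list(index = idx, distance = d)
}

# edge-dictionary face-adjacency oracle
adjacency_oracle <- function(mesh) {
  dict <- new.env()
  for (r in seq_len(nrow(mesh$faces))) {
    f <- mesh$faces[r, ]
    for (e in list(c(f[1], f[2]), c(f[2], f[3]), c(f[3], f[1]))) {
      key <- paste(min(e), max(e))
      dict[[key]] <- c(dict[[key]], r)
    }
  }
  adj <- vector("list", nrow(mesh$faces))
  for (key in ls(dict)) {
    fs <- dict[[key]]
    if (length(fs) >= 2) for (i in seq_along(fs))
      adj[[fs[i]]] <- c(adj[[fs[i]]], fs[-i])
  }
  lapply(adj, function(x) sort(unique(x)))
}

# quaternion oracle for Z-Y-X intrinsic Euler rotation
quat_mul <- function(a, b) {
  c(a[1] * b[1] - sum(a[2:4] * b[2:4]),
    a[1] * b[2:4] + b[1] * a[2:4] +
      c(a[3] * b[4] - a[4] * b[3],
        a[4] * b[2] - a[2] * b[4],
        a[2] * b[3] - a[3] * b[2]))
}
quat_from_axis <- function(axis, ang) c(cos(ang / 2), sin(ang / 2) * axis)
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
euler_zyx_quat <- function(angles) {
  q <- quat_mul(quat_from_axis(c(0, 0, 1), angles[1]),
                quat_mul(quat_from_axis(c(0, 1, 0), angles[2]),
                         quat_from_axis(c(1, 0, 0), angles[3])))
  quat_to_matrix(q)
}

# rotation matrix about an arbitrary axis (Rodrigues)
axis_angle_matrix <- function(axis, ang) {
  axis <- axis / sqrt(sum(axis^2))
  k <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(ang) * k + (1 - cos(ang)) * k %*% k
}

# construction-correspondence cohort: same mesh_resolution implies the
# generator emits identical connectivity, so shape vectors can be
# stacked without elastic registration
construction_cohort <- function(pop) {
  vecs <- lapply(pop, function(sp) shape_vector(sp$mesh))
  registered_cohort(pop[[1]]$mesh$faces, vecs,
                    ids = vapply(pop, `[[`, "", "id"),
                    groups = vapply(pop, `[[`, "", "group"))
}

# small tooth parameters for fast tests (~750 vertices)
small_tooth_params <- function(...) {
  tooth_params(..., mesh_resolution = c(24L, 32L))
}

# analytic CEJ-side truth at arbitrary positions
true_material_at <- function(v, cej_amplitude) {
  as.numeric(v[, 3] > (cej_amplitude / 2) * cos(2 * atan2(v[, 2], v[, 1])))
}

# UV (latitude/longitude) sphere whose middle ring lies exactly on the
# equator, so an element partition by centroid hemisphere has the
# equatorial edge ring as its boundary
make_uv_sphere <- function(n_theta = 48, n_lat = 23, radius = 1) {
  stopifnot(n_lat %% 2 == 1)
  lats <- seq(pi / 2, -pi / 2, length.out = n_lat + 2)[-c(1, n_lat + 2)]
  theta <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  rings <- lapply(lats, function(la)
    cbind(radius * cos(la) * cos(theta), radius * cos(la) * sin(theta),
          rep(radius * sin(la), n_theta)))
  v <- do.call(rbind, rings)
  v <- rbind(v, c(0, 0, radius), c(0, 0, -radius))
  i_top <- n_lat * n_theta + 1L
  i_bot <- n_lat * n_theta + 2L
  ring_idx <- function(r) ((r - 1L) * n_theta + 1L):(r * n_theta)
  nxt <- c(seq_len(n_theta)[-1], 1L)
  faces <- list(cbind(i_top, ring_idx(1), ring_idx(1)[nxt]))
  for (r in seq_len(n_lat - 1L)) {
    up <- ring_idx(r); lo <- ring_idx(r + 1L)
    faces[[length(faces) + 1L]] <- rbind(cbind(up, lo, lo[nxt]),
                                         cbind(up, lo[nxt], up[nxt]))
  }
  rl <- ring_idx(n_lat)
  faces[[length(faces) + 1L]] <- cbind(i_bot, rl[nxt], rl)
  surface_mesh(v, do.call(rbind, faces))
}
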