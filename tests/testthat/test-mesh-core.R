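# Mesh container, I/O and geometric primitives.

test_that("mesh file I/O round-trips across formats and cleans on load", {
  cube <- make_unit_cube()

  # ASCII OFF written by hand (independent of write_mesh)
  off <- tempfile(fileext = ".off")
  writeLines(c("OFF", "8 12 0",
               apply(cube$vertices, 1, paste, collapse = " "),
               apply(cube$faces - 1L, 1, function(r) paste(c(3, r), collapse = " "))),
             off)
  m <- load_mesh(off)
  expect_equal(n_vertices(m), 8L)
  expect_equal(n_faces(m), 12L)
  expect_equal(m$vertices, cube$vertices)

  # ASCII STL vertex soup: 36 vertices merge back to 8
  stl <- tempfile(fileext = ".stl")
  lines <- c("solid cube")
  for (r in seq_len(12)) {
    lines <- c(lines, "facet normal 0 0 0", "outer loop",
               apply(cube$vertices[cube$faces[r, ], ], 1,
                     function(p) paste("vertex", paste(p, collapse = " "))),
               "endloop", "endfacet")
  }
  writeLines(c(lines, "endsolid cube"), stl)
  ms <- load_mesh(stl)
  expect_equal(n_vertices(ms), 8L)
  expect_equal(n_faces(ms), 12L)
  expect_equal(enclosed_volume(ms), 1, tolerance = 1e-12)

  # PLY round trip, ASCII and binary, with material labels
  cube$material <- rep(c(0, 1), each = 4)
  for (bin in c(FALSE, TRUE)) {
    ply <- tempfile(fileext = ".ply")
    write_mesh(cube, ply, binary = bin)
    mp <- load_mesh(ply)
    expect_equal(mp$vertices, cube$vertices, tolerance = 1e-12)
    expect_equal(mp$faces, cube$faces)
    expect_equal(mp$material, cube$material)
  }
})

test_that("unparseable and empty meshes raise format errors", {
  trunc <- tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 8"), trunc)
  expect_error(load_mesh(trunc), "format error.*byte offset")
  expect_error(load_mesh(tempfile(fileext = ".ply")), "not found")
  bad_off <- tempfile(fileext = ".off")
  writeLines(c("NOT_OFF", "1 0 0"), bad_off)
  expect_error(load_mesh(bad_off), "format error")
})

test_that("surface area and volume match analytic values", {
  cube <- make_unit_cube()
  expect_equal(surface_area(cube), 6)
  expect_equal(enclosed_volume(cube), 1)

  tri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                      rbind(c(1, 2, 3)))
  expect_equal(surface_area(tri), 0.5)

  sph <- make_icosphere(4, radius = 2)
  expect_true(is_closed(sph))
  expect_equal(surface_area(sph), 4 * pi * 4, tolerance = 0.01)
  expect_equal(enclosed_volume(sph), (4 / 3) * pi * 8, tolerance = 0.01)

  open_cube <- cube
  open_cube$faces <- open_cube$faces[-1, ]
  expect_error(enclosed_volume(open_cube), "not closed.*3 boundary edges")
})

test_that("area/volume obey rigid invariance and similarity scaling", {
  sph <- make_icosphere(2, radius = 1.3)
  a0 <- surface_area(sph)
  v0 <- enclosed_volume(sph)
  set.seed(1)
  for (i in 1:3) {
    tf <- rigid_transform(axis_angle_matrix(rnorm(3), runif(1, 0, pi)),
                          rnorm(3, 0, 10))
    moved <- apply_transform(tf, sph)
    expect_equal(surface_area(moved), a0, tolerance = 1e-9)
    expect_equal(enclosed_volume(moved), v0, tolerance = 1e-9)
  }
  for (s in c(0.5, 2, 3)) {
    scaled <- sph
    scaled$vertices <- scaled$vertices * s
    expect_equal(surface_area(scaled), a0 * s^2, tolerance = 1e-12)
    expect_equal(enclosed_volume(scaled), v0 * s^3, tolerance = 1e-12)
  }
})

test_that("nearest_vertices is exact with deterministic tie-breaking", {
  set.seed(7)
  pts <- matrix(rnorm(30), 10, 3)
  self <- nearest_vertices(pts, pts)
  expect_equal(self$index, 1:10)
  expect_equal(self$distance, rep(0, 10))

  # brute-force oracle on >= 20 random instances
  for (rep in 1:20) {
    q <- matrix(rnorm(3 * sample(5:60, 1)), ncol = 3)
    r <- matrix(rnorm(3 * sample(3:50, 1)), ncol = 3)
    got <- nearest_vertices(q, r)
    want <- brute_nn(q, r)
    expect_equal(got$index, want$index)
    expect_equal(got$distance, want$distance, tolerance = 1e-12)
  }

  one <- matrix(c(5, 5, 5), 1, 3)
  all_one <- nearest_vertices(matrix(rnorm(30), 10, 3), one)
  expect_equal(all_one$index, rep(1L, 10))

  # exact tie: two references equidistant -> lowest index wins
  refs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(1, 0, 0))
  tie <- nearest_vertices(matrix(0, 1, 3), refs)
  expect_equal(tie$index, 1L)

  expect_error(nearest_vertices(matrix(0, 1, 3), matrix(0, 0, 3)),
               "empty")
})

test_that("element adjacency is symmetric and matches the edge-map oracle", {
  two <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
                      rbind(c(1, 2, 3), c(2, 4, 3)))
  adj <- build_adjacency(two)
  expect_equal(adj[[1]], 2L)
  expect_equal(adj[[2]], 1L)

  cube_adj <- build_adjacency(make_unit_cube())
  expect_true(all(lengths(cube_adj) == 3L))

  sph <- make_icosphere(2)
  adj <- build_adjacency(sph)
  oracle <- adjacency_oracle(sph)
  expect_equal(unclass(adj), oracle, ignore_attr = TRUE)
  # symmetry
  for (i in seq_along(adj))
    for (j in adj[[i]]) expect_true(i %in% adj[[j]])

  # non-manifold edge: three faces sharing one edge -> warning, all pairs
  nm <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                           c(0, -1, 0), c(0, 0, 1)),
                     rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5)))
  expect_warning(adj_nm <- build_adjacency(nm), "non-manifold")
  expect_equal(adj_nm[[1]], c(2L, 3L))
})

test_that("vertex ring operator averages 1-ring neighbours", {
  sph <- make_icosphere(1)
  w <- vertex_ring_operator(sph)
  expect_equal(unname(Matrix::rowSums(w)), rep(1, n_vertices(sph)))
  # row of vertex 1 puts equal weight on each neighbour
  nb <- which(w[1, ] > 0)
  expect_equal(unname(w[1, nb]), rep(1 / length(nb), length(nb)))
})
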