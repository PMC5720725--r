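# Material binarisation, partition smoothing, CEJ extraction.

test_that("binarize applies the mid-range threshold rule", {
  expect_equal(binarize(0.5), 1)
  expect_equal(binarize(0.49), 0)
  expect_equal(binarize(rep(0, 5)), rep(0, 5))
  x <- c(0, 0.2, 0.5, 0.9, 1)
  expect_equal(binarize(binarize(x)), binarize(x))  # idempotent
  expect_error(binarize(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("node/element label conversions use majority votes", {
  tri2 <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
                       rbind(c(1, 2, 3), c(2, 4, 3)))
  expect_equal(elements_from_nodes(tri2, c(1, 1, 1, 0)), c(1, 1))
  expect_equal(elements_from_nodes(tri2, c(1, 0, 0, 0)), c(0, 0))

  # node with all incident elements enamel -> 1; 50/50 tie -> enamel
  hexv <- rbind(c(0, 0, 0),
                t(sapply(0:5, function(k) c(cos(k * pi / 3), sin(k * pi / 3), 0))))
  hex <- surface_mesh(hexv, cbind(1, 2:7, c(3:7, 2)))
  expect_equal(nodes_from_elements(hex, rep(1, 6))[1], 1)
  expect_equal(nodes_from_elements(hex, c(1, 1, 1, 0, 0, 0))[1], 1)

  # hemisphere round trip: identity away from the boundary ring
  sph <- make_two_hemisphere_sphere(3)
  elem <- elements_from_nodes(sph, sph$material)
  back <- nodes_from_elements(sph, elem)
  away <- abs(sph$vertices[, 3]) > 0.15
  expect_equal(back[away], sph$material[away])

  # noise-free tooth: element labels match the analytic side off-boundary
  tooth <- generate_tooth(small_tooth_params())
  elem_t <- elements_from_nodes(tooth$mesh, tooth$material)
  fc <- (tooth$mesh$vertices[tooth$mesh$faces[, 1], ] +
         tooth$mesh$vertices[tooth$mesh$faces[, 2], ] +
         tooth$mesh$vertices[tooth$mesh$faces[, 3], ]) / 3
  truth <- true_material_at(fc, small_tooth_params()$cej_amplitude)
  off <- abs(fc[, 3] - (1.5 / 2) * cos(2 * atan2(fc[, 2], fc[, 1]))) > 1
  expect_equal(elem_t[off], truth[off])
})

test_that("smooth_materials reaches a zero-violation fixed point", {
  sph <- make_icosphere(2)
  adj <- build_adjacency(sph)

  # isolated enamel element in a dentin sea -> flipped in one sweep
  lone <- rep(0, n_faces(sph))
  lone[37] <- 1
  sm <- smooth_materials(sph, lone, adjacency = adj)
  expect_equal(as.numeric(sm), rep(0, n_faces(sph)))

  # uniform field unchanged, converges in one sweep
  uni <- smooth_materials(sph, rep(1, n_faces(sph)), adjacency = adj)
  expect_equal(attr(uni, "iterations"), 1L)
  expect_true(attr(uni, "converged"))

  # wide band on the sphere: interior band survives, fixed point holds
  fc <- (sph$vertices[sph$faces[, 1], ] + sph$vertices[sph$faces[, 2], ] +
         sph$vertices[sph$faces[, 3], ]) / 3
  band <- as.numeric(abs(fc[, 3]) < 0.4)
  smb <- smooth_materials(sph, band, adjacency = adj)
  interior <- abs(fc[, 3]) < 0.2
  expect_equal(as.numeric(smb)[interior], band[interior])
  # no element violates the rule at the fixed point
  viol <- vapply(seq_along(adj), function(i)
    sum(as.numeric(smb)[adj[[i]]] != as.numeric(smb)[i]) >= 2, TRUE)
  expect_false(any(viol))
  # idempotence
  again <- smooth_materials(sph, as.numeric(smb), adjacency = adj)
  expect_equal(as.numeric(again), as.numeric(smb))
  expect_equal(attr(again, "iterations"), 1L)
})

test_that("smoothing never increases the number of boundary loops", {
  sph <- make_two_hemisphere_sphere(2)
  adj <- build_adjacency(sph)
  set.seed(17)
  for (rep in 1:20) {
    noisy <- sph$material
    flip <- sample(length(noisy), 25)
    noisy[flip] <- 1 - noisy[flip]
    elem <- elements_from_nodes(sph, noisy)
    before <- suppressWarnings(extract_cej(sph, elem)$n_loops)
    sm <- smooth_materials(sph, elem, adjacency = adj)
    after <- suppressWarnings(extract_cej(sph, as.numeric(sm))$n_loops)
    expect_lte(after, before)
  }
})

test_that("extract_cej chains boundary edges into closed loops", {
  # element partition by centroid hemisphere on a UV sphere: the
  # boundary is exactly the equatorial edge ring
  sph <- make_uv_sphere(48, 23, radius = 2)
  fc <- (sph$vertices[sph$faces[, 1], ] + sph$vertices[sph$faces[, 2], ] +
         sph$vertices[sph$faces[, 3], ]) / 3
  elem <- as.numeric(fc[, 3] > 0)
  cej <- extract_cej(sph, elem)
  expect_equal(cej$n_loops, 1L)
  expect_equal(cej$lengths[1], 2 * pi * 2, tolerance = 0.05)
  lp <- cej$loops[[1]]
  expect_equal(lp[1], lp[length(lp)])  # closed

  expect_warning(none <- extract_cej(sph, rep(0, n_faces(sph))),
                 "single-material")
  expect_equal(none$n_loops, 0L)

  tooth <- generate_tooth(small_tooth_params())
  mp <- material_pipeline(tooth$mesh)
  expect_equal(mp$cej$n_loops, 1L)
  expect_true(attr(mp$element_material, "converged"))
})
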