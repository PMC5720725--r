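# Elastic registration, shape vectors, cohorts, material transfer.

test_that("laplacian_smooth shrinks curved meshes and fixes flats", {
  sph <- make_icosphere(2)
  expect_identical(laplacian_smooth(sph, 0)$vertices, sph$vertices)

  # volume strictly decreases with every pass on a sphere
  vols <- numeric(10)
  cur <- sph
  for (i in 1:10) {
    cur <- laplacian_smooth(cur, 0.5, passes = 1)
    vols[i] <- enclosed_volume(cur)
  }
  expect_true(all(diff(c(enclosed_volume(sph), vols)) < 0))

  # vertex already at its 1-ring centroid stays put: regular hexagon fan
  hexv <- rbind(c(0, 0, 0),
                t(sapply(0:5, function(k) c(cos(k * pi / 3), sin(k * pi / 3), 0))))
  hexf <- cbind(1, 2:7, c(3:7, 2))
  hex <- surface_mesh(hexv, hexf)
  sm <- laplacian_smooth(hex, 0.7)
  expect_equal(sm$vertices[1, ], c(0, 0, 0), tolerance = 1e-15)
})

test_that("shape vectors and cohorts enforce their invariants", {
  tooth <- generate_tooth(small_tooth_params())
  sv <- shape_vector(tooth$mesh)
  expect_equal(length(sv$values), 4L * sv$M)
  expect_true(sv$has_material)
  back <- shape_to_mesh(sv, tooth$mesh$faces)
  expect_equal(back$vertices, tooth$mesh$vertices)
  expect_equal(back$material, tooth$material)

  geom <- tooth$mesh
  geom$material <- NULL
  svg <- shape_vector(geom)
  expect_equal(length(svg$values), 3L * svg$M)

  expect_error(registered_cohort(tooth$mesh$faces, list(sv, svg)),
               "share node count")
  expect_error(shape_vector(tooth$mesh, material = rep(2, n_vertices(tooth$mesh))),
               "\\[0, 1\\]")
})

test_that("elastic registration fits targets without changing connectivity", {
  # identity: converges in one iteration with zero displacement
  sph <- make_icosphere(3)
  res0 <- elastic_register(sph, sph)
  expect_equal(res0$report$iterations, 1L)
  expect_identical(res0$mesh$vertices, sph$vertices)

  # concentric spheres: all vertices end on the larger radius
  big <- sph
  big$vertices <- big$vertices * 1.2
  res <- elastic_register(sph, big)
  r <- sqrt(rowSums(res$mesh$vertices^2))
  expect_true(all(abs(r - 1.2) < 0.01))
  expect_identical(res$mesh$faces, sph$faces)

  # tooth-to-tooth: same params, different noise
  spec <- population_spec(n = 2, cv = 0, noise = 0.05, seed = 8,
                          groups = list(A = small_tooth_params()))
  pop <- generate_population(spec)
  a <- pop[[1]]$mesh; a$material <- NULL
  res2 <- suppressWarnings(elastic_register(a, pop[[2]]$mesh))
  expect_lt(res2$report$mean_dist, 0.05)
  expect_equal(n_vertices(res2$mesh), n_vertices(a))
  expect_identical(res2$mesh$faces, a$faces)

  # idempotence: re-registering a converged result barely moves
  res3 <- suppressWarnings(elastic_register(res2$mesh, pop[[2]]$mesh))
  disp <- sqrt(rowSums((res3$mesh$vertices - res2$mesh$vertices)^2))
  expect_lt(mean(disp), 1e-3)
})

test_that("compute_mean_shape averages component-wise", {
  tooth <- generate_tooth(small_tooth_params())
  sv <- shape_vector(tooth$mesh)
  co1 <- registered_cohort(tooth$mesh$faces, list(sv))
  expect_equal(compute_mean_shape(co1)$values, sv$values)

  sv2 <- sv
  sv2$values <- sv$values + 1
  co2 <- registered_cohort(tooth$mesh$faces, list(sv, sv2))
  expect_equal(compute_mean_shape(co2)$values, sv$values + 0.5)

  set.seed(3)
  vecs <- lapply(1:5, function(i)
    shape_vector_from_values(rnorm(12), has_material = FALSE))
  co5 <- registered_cohort(matrix(c(1L, 2L, 3L), 1), vecs)
  acc <- numeric(12)
  for (v in vecs) acc <- acc + v$values   # naive summation oracle
  expect_equal(compute_mean_shape(co5)$values, acc / 5, tolerance = 1e-12)
})

test_that("material transfer labels enamel within the cutoff", {
  tooth <- generate_tooth(small_tooth_params())
  m <- tooth$mesh
  expect_equal(transfer_material(m, m), rep(1, n_vertices(m)))

  far <- m
  far$vertices <- far$vertices + 1000
  expect_equal(transfer_material(m, far), rep(0, n_vertices(m)))

  empty <- surface_mesh(matrix(1, 1, 3), matrix(integer(), 0, 3))
  empty$vertices <- empty$vertices[0, , drop = FALSE]
  expect_warning(out <- transfer_material(m, empty), "empty enamel")
  expect_equal(out, rep(0, n_vertices(m)))
})

test_that("two-pass registration produces a coherent labelled cohort", {
  spec <- population_spec(n = 4, cv = 0.05, scale_cv = 0.08, noise = 0.05,
                          seed = 5, groups = list(A = small_tooth_params()))
  pop <- generate_population(spec)
  base <- generate_tooth(small_tooth_params())$mesh
  base$material <- NULL
  co <- suppressWarnings(two_pass_register(pop, base, tol = 0, max_iter = 40))

  expect_s3_class(co, "registered_cohort")
  expect_length(co$vectors, 4L)
  expect_true(all(vapply(co$vectors, function(v) v$M == co$M, TRUE)))
  expect_true(co$has_material)
  expect_identical(co$faces, base$faces)

  ps <- attr(co, "pass_summary")
  expect_lte(ps$pass2_mean_dist, ps$pass1_mean_dist)
  expect_lt(ps$pass2_mean_dist, 0.05)

  # transferred labels agree with the analytic CEJ side
  for (i in 1:2) {
    mesh <- shape_to_mesh(co$vectors[[i]], co$faces)
    truth <- true_material_at(mesh$vertices, pop[[i]]$params$cej_amplitude)
    agree <- mean((mesh$material >= 0.5) == (truth == 1))
    expect_gt(agree, 0.98)
  }

  # identical copies of the baseline: pass-2 distance ~ 0
  copies <- list(list(id = "c1", mesh = { b <- base; b$material <- rep(1, n_vertices(b)); b }),
                 list(id = "c2", mesh = { b <- base; b$material <- rep(1, n_vertices(b)); b }))
  co0 <- two_pass_register(copies, base, tol = 0, max_iter = 30)
  expect_lt(attr(co0, "pass_summary")$pass2_mean_dist, 1e-8)

  expect_error(two_pass_register(pop[1], base), "at least 2")
})
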