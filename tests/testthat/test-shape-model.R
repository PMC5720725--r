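# Correlation-method PCA: fitting, generation, projection, sweeps,
# reconstruction error.

# tiny helper: cohort of bare numeric vectors (no material)
vector_cohort <- function(x) {
  vecs <- lapply(seq_len(nrow(x)), function(i)
    shape_vector_from_values(x[i, ], has_material = FALSE))
  registered_cohort(matrix(c(1L, 2L, 3L), 1), vecs)
}

test_that("fit_model matches a dense correlation-matrix oracle", {
  set.seed(10)
  x <- matrix(rnorm(60), 10, 6)
  model <- fit_model(vector_cohort(x))
  oracle <- eigen(stats::cor(x), symmetric = TRUE)
  keep <- oracle$values > 1e-9
  expect_equal(model$eigenvalues, oracle$values[keep], tolerance = 1e-9)
  # eigenvectors match up to sign
  for (j in seq_len(model$n_pcs)) {
    dot <- abs(sum(model$eigenvectors[, j] * oracle$vectors[, j]))
    expect_equal(dot, 1, tolerance = 1e-9)
  }
  expect_equal(sum(model$var_frac), 1, tolerance = 1e-9)
  # orthonormal basis, descending eigenvalues
  expect_equal(crossprod(model$eigenvectors), diag(model$n_pcs),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(diff(model$eigenvalues) <= 0))
})

test_that("degenerate cohorts are handled per contract", {
  x <- matrix(rep(c(1, 2, 3, 4, 5, 6), each = 4), 4, 6)
  expect_error(fit_model(vector_cohort(x)), "all variables constant")

  x2 <- x
  x2[, 1] <- x2[, 1] + rnorm(4)
  m2 <- fit_model(vector_cohort(x2))
  expect_true(all(which(m2$constant_mask) == 2:6))

  set.seed(1)
  x3 <- matrix(rnorm(18), 3, 6)
  expect_lte(fit_model(vector_cohort(x3))$n_pcs, 2L)

  expect_error(fit_model(vector_cohort(matrix(rnorm(6), 1, 6))), "N >= 2")
})

test_that("generate/project round trips are exact", {
  set.seed(4)
  x <- matrix(rnorm(8 * 12, sd = 2), 8, 12)
  co <- vector_cohort(x)
  model <- fit_model(co)

  # zero weights give the mean exactly
  mean_inst <- generate_instance(model, pc_weights(numeric(model$n_pcs)))
  expect_equal(mean_inst$values, colMeans(x), tolerance = 1e-12)
  expect_equal(project(model, mean_inst)$values, numeric(model$n_pcs),
               tolerance = 1e-9)

  # training specimens reproduce from their own projections
  for (i in c(1, 5)) {
    w <- project(model, x[i, ])
    rec <- generate_instance(model, w)
    expect_equal(rec$values, x[i, ], tolerance = 1e-9)
  }

  # sigma-weight round trip and linearity
  w <- pc_weights(c(1.5, -0.5), units = "sigma")
  plus <- generate_instance(model, w, c = 2)
  minus <- generate_instance(model, pc_weights(c(-1.5, 0.5), "sigma"), c = 2)
  expect_equal((plus$values + minus$values) / 2, mean_inst$values,
               tolerance = 1e-12)
  round2 <- project(model, plus)
  expect_equal(as_sigma_weights(model, round2)$values[1:2], w$values,
               tolerance = 1e-9)

  # score variances equal eigenvalues (1/(N-1))
  sc <- t(apply(x, 1, function(r) project(model, r)$values))
  expect_equal(apply(sc, 2, var), model$eigenvalues, tolerance = 1e-9)
  expect_equal(colMeans(sc), numeric(model$n_pcs), tolerance = 1e-9)

  expect_error(generate_instance(model, w, c = model$n_pcs + 1L),
               "exceeds available")
  expect_error(project(model, x[1, 1:5]), "length")
})

test_that("variance accounting and choose_c follow the cumulative rule", {
  set.seed(6)
  x <- matrix(rnorm(60), 10, 6)
  model <- fit_model(vector_cohort(x))
  vr <- variance_report(model)
  expect_equal(sum(vr$fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(vr$cumulative) >= -1e-12))
  expect_equal(choose_c(model, 1), model$n_pcs)
  expect_equal(choose_c(model, vr$fraction[1] / 2), 1L)

  # hand-computed case: fractions (0.4, 0.3, 0.2, 0.1), target 0.75 -> 3
  fake <- structure(list(var_frac = c(0.4, 0.3, 0.2, 0.1), n_pcs = 4L),
                    class = "shape_model")
  expect_equal(choose_c(fake, 0.75), 3L)
  expect_error(choose_c(fake, 0), "\\(0, 1\\]")

  # one dominant generative mode -> PC1 fraction > 0.5
  spec <- population_spec(n = 15, scale_cv = 0.1, cv = 0.01, noise = 0.02,
                          seed = 2, groups = list(A = small_tooth_params()))
  co <- construction_cohort(generate_population(spec))
  ms <- fit_model(co)
  expect_gt(ms$var_frac[1], 0.5)
})

test_that("sigma sweeps are symmetric and level 0 is the mean", {
  set.seed(8)
  x <- matrix(rnorm(7 * 9), 7, 9)
  model <- fit_model(vector_cohort(x))
  sw <- sigma_sweep(model, 1)
  expect_length(sw, 7L)
  expect_equal(sw[["0"]]$values, colMeans(x), tolerance = 1e-12)
  expect_equal(sw[["2"]]$values + sw[["-2"]]$values, 2 * colMeans(x),
               tolerance = 1e-12)
  expect_error(sigma_sweep(model, model$n_pcs + 1L), "exceeds")
})

test_that("reconstruction error decays with k and vanishes at full rank", {
  spec <- population_spec(n = 8, cv = 0.05, scale_cv = 0.08, noise = 0.02,
                          seed = 7, groups = list(A = small_tooth_params()))
  co <- construction_cohort(generate_population(spec))
  model <- fit_model(co)

  ez <- reconstruction_error_test(model, co, space = "standardised")
  for (i in seq_len(nrow(ez)))
    expect_true(all(diff(ez[i, ]) <= 1e-9))

  es <- reconstruction_error_test(model, co, k_range = c(0, model$n_pcs))
  expect_true(all(es[, 1] > 0))
  expect_true(all(es[, 2] <= 1e-6))
})

test_that("duplicating a specimen keeps scores centred", {
  set.seed(12)
  x <- matrix(rnorm(5 * 9), 5, 9)
  xd <- rbind(x, x[3, ])
  md <- fit_model(vector_cohort(xd))
  sc <- t(apply(xd, 1, function(r) project(md, r)$values))
  expect_equal(colMeans(sc), numeric(md$n_pcs), tolerance = 1e-9)
})

test_that("models serialise to JSON and back", {
  set.seed(13)
  x <- matrix(rnorm(6 * 9), 6, 9)
  model <- fit_model(vector_cohort(x))
  path <- tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)
  expect_equal(back$eigenvalues, model$eigenvalues)
  expect_equal(back$eigenvectors, model$eigenvectors)
  expect_equal(back$mean, model$mean)
  w <- project(back, x[2, ])
  expect_equal(generate_instance(back, w)$values, x[2, ], tolerance = 1e-9)
})
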