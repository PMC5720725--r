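# Agreement, regression and group-comparison statistics.

test_that("bland_altman reproduces hand-computed bias and limits", {
  ident <- bland_altman(1:5, 1:5)
  expect_equal(ident$bias, 0)
  expect_equal(c(ident$lower, ident$upper), c(0, 0))

  shifted <- bland_altman(1:5, 1:5 + 1)
  expect_equal(shifted$bias, -1)
  expect_equal(c(shifted$lower, shifted$upper), c(-1, -1))

  # hand arithmetic: diffs (-0.1, 0.1, -0.2, 0.2), sd = sqrt(0.1/3)
  ba <- bland_altman(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd, sqrt(0.1 / 3), tolerance = 1e-12)
  expect_equal(ba$upper, 1.96 * sqrt(0.1 / 3), tolerance = 1e-12)
  expect_equal(round(ba$sd, 4), 0.1826)
  expect_equal(round(ba$upper, 3), 0.358)

  # antisymmetry
  set.seed(3)
  a <- rnorm(10); b <- rnorm(10)
  ab <- bland_altman(a, b); ba2 <- bland_altman(b, a)
  expect_equal(ab$bias, -ba2$bias)
  expect_equal(ab$upper, -ba2$lower)

  expect_error(bland_altman(1:3, 1:4), "equal length")
  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("fit_line matches closed-form OLS and lm", {
  x <- 1:7
  perfect <- fit_line(x, 2 * x + 1)
  expect_equal(perfect$slope, 2)
  expect_equal(perfect$intercept, 1)
  expect_equal(perfect$r_squared, 1)

  # hand-computed: x=(1,2,3), y=(1,2,4) -> slope 3/2, R^2 = 27/28
  h <- fit_line(c(1, 2, 3), c(1, 2, 4))
  expect_equal(h$slope, 1.5)
  expect_equal(h$r_squared, 27 / 28, tolerance = 1e-12)

  set.seed(9)
  xr <- rnorm(15); yr <- 0.7 * xr + rnorm(15)
  got <- fit_line(xr, yr)
  lm_fit <- summary(lm(yr ~ xr))
  expect_equal(got$slope, unname(coef(lm_fit)[2, 1]), tolerance = 1e-12)
  expect_equal(got$t, unname(coef(lm_fit)[2, 3]), tolerance = 1e-12)
  expect_equal(got$p, unname(coef(lm_fit)[2, 4]), tolerance = 1e-12)
  expect_equal(got$r_squared, lm_fit$r.squared, tolerance = 1e-12)
  expect_equal(got$r_squared, cor(xr, yr)^2, tolerance = 1e-12)

  expect_error(fit_line(rep(1, 5), rnorm(5)), "constant predictor")
  flat <- fit_line(1:5, rep(2, 5))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
})

test_that("pc_measurement_regressions shapes the R-squared table", {
  sw <- data.frame(pc = 1, level = -3:3,
                   LDCc = 2 * (-3:3) + 5, LDC = rep(4, 7),
                   MDCc = NA_real_, MDC = 1:7, LORla = (-3:3)^1 * 0.1 + 2,
                   LOCla = rnorm(7), vol = 3 * (-3:3) + 100,
                   area = rep(1, 7), note = "")
  reg <- pc_measurement_regressions(sw, alpha = 0.01)
  expect_equal(nrow(reg), 8L)
  r_ldcc <- reg[reg$measurement == "LDCc", ]
  expect_equal(r_ldcc$r_squared, 1)
  expect_true(r_ldcc$significant)
  r_ldc <- reg[reg$measurement == "LDC", ]
  expect_equal(r_ldc$r_squared, 0)
  expect_false(r_ldc$significant)
  expect_true(is.na(reg[reg$measurement == "MDCc", "r_squared"]))
})

test_that("compare_groups matches aov/TukeyHSD and classical identities", {
  set.seed(21)
  y <- rnorm(24)
  g <- rep(c("A", "B", "C"), times = c(9, 10, 5))
  got <- compare_groups(y, g, alpha = 0.99)  # force post-hoc
  ref <- summary(aov(y ~ factor(g)))[[1]]
  expect_equal(got$F, ref["factor(g)", "F value"], tolerance = 1e-9)
  expect_equal(got$p, ref["factor(g)", "Pr(>F)"], tolerance = 1e-9)
  tk <- TukeyHSD(aov(y ~ factor(g)))$`factor(g)`
  expect_equal(got$pairwise$p_adj, unname(tk[, "p adj"]), tolerance = 1e-6)
  expect_equal(got$pairwise$difference, unname(tk[, "diff"]),
               tolerance = 1e-9)

  # k = 2: F equals the squared pooled-variance t statistic
  y2 <- rnorm(14); g2 <- rep(c("A", "B"), 7)
  f2 <- compare_groups(y2, g2)$F
  t2 <- t.test(y2 ~ g2, var.equal = TRUE)$statistic
  expect_equal(f2, unname(t2)^2, tolerance = 1e-9)

  # constructed discordant group: exactly the two pairs flagged
  yd <- c(rnorm(8, 0, 0.1), rnorm(8, 0, 0.1), rnorm(8, 10, 0.1))
  gd <- rep(c("A", "B", "C"), each = 8)
  res <- compare_groups(yd, gd)
  expect_lt(res$p, 1e-6)
  flagged <- res$pairwise$pair[res$pairwise$significant]
  expect_setequal(flagged, c("C-A", "C-B"))

  # invariances: label permutation, constant shift
  perm <- sample(length(yd))
  expect_equal(compare_groups(yd[perm], gd[perm])$F, res$F, tolerance = 1e-9)
  expect_equal(compare_groups(yd + 5, gd)$F, res$F, tolerance = 1e-9)

  expect_error(compare_groups(1:5, c("A", "A", "A", "A", "B")), "n >= 2")
  expect_error(compare_groups(1:4, rep("A", 4)), ">= 2 groups")
})

test_that("boxplot summaries follow the stated conventions", {
  set.seed(30)
  x <- c(rnorm(20), 8)  # one clear outlier
  bs <- toothSSM:::boxplot_summary(x)
  q <- unname(quantile(x, c(0.25, 0.5, 0.75)))
  iqr <- q[3] - q[1]
  expect_equal(bs$q1, q[1])
  expect_equal(bs$median, q[2])
  expect_equal(bs$outliers, 8)
  expect_equal(bs$whisker_high, max(x[x <= q[3] + 1.5 * iqr]))
  expect_equal(bs$notch_low, q[2] - 1.57 * iqr / sqrt(length(x)))
})
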