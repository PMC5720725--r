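# Validation and inference statistics: Bland-Altman agreement, linear
# regression of measurements on PC weights, and one-way ANOVA with
# Tukey HSD post-hoc comparison of PC scores between groups.
#
# The F statistic, Tukey intervals and boxplot summaries are computed
# from first principles (sums of squares, the studentised range
# distribution, quartiles) rather than delegated to modelling helpers,
# so every reported number is a testable quantity; the test suite
# cross-checks them against R's lm/aov/TukeyHSD.

#' Bland-Altman agreement analysis
#'
#' Differences are `a - b`; the bias is their mean and the 95% limits of
#' agreement are `bias +/- 1.96 * sd` with the (n-1)-denominator sd
#' (the factor is 1.96, not 2.0).
#'
#' @param series_a,series_b paired numeric measurements, equal length >= 2.
#' @return list with `bias`, `sd`, `lower`, `upper` and a per-pair
#'   data.frame `pairs` (columns `mean`, `difference`).
#' @export
bland_altman <- function(series_a, series_b) {
  if (length(series_a) != length(series_b))
    stop("invalid input: series must have equal length", call. = FALSE)
  if (length(series_a) < 2L)
    stop("invalid input: need at least 2 pairs", call. = FALSE)
  d <- series_a - series_b
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, sd = s,
       lower = bias - 1.96 * s, upper = bias + 1.96 * s,
       pairs = data.frame(mean = (series_a + series_b) / 2, difference = d))
}

#' Ordinary least squares fit with slope t-test
#'
#' @param x predictor values (not constant), length >= 3.
#' @param y response values.
#' @return list with `slope`, `intercept`, `r_squared`, `t`, `p`
#'   (two-sided, H0: slope = 0, df = n - 2) and `n`.
#' @export
fit_line <- function(x, y) {
  n <- length(x)
  if (n < 3L) stop("invalid input: need n >= 3", call. = FALSE)
  if (length(y) != n) stop("invalid input: x and y lengths differ", call. = FALSE)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("invalid input: constant predictor", call. = FALSE)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  sigma2 <- ss_res / (n - 2)
  se <- sqrt(sigma2 / sxx)
  t <- if (se == 0) { if (slope == 0) 0 else Inf * sign(slope) } else slope / se
  p <- 2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
  list(slope = slope, intercept = intercept, r_squared = r2,
       t = t, p = p, n = n)
}

#' Regressions of measurements on PC sweep level
#'
#' One [fit_line()] per (PC, measurement) with the sigma level as the
#' predictor, shaped like the usual R-squared matrix with significance
#' flags at `alpha`. Sweep rows with landmark failures propagate NA
#' cells.
#'
#' @param sweeps data.frame rbind of [measure_sweep()] tables over the
#'   PCs of interest.
#' @param alpha significance level for the slope t-test.
#' @return data.frame with columns `pc`, `measurement`, `r_squared`,
#'   `p`, `significant`.
#' @export
pc_measurement_regressions <- function(sweeps, alpha = 0.01) {
  out <- list()
  for (pc in sort(unique(sweeps$pc))) {
    sub <- sweeps[sweeps$pc == pc, ]
    for (m in MEASUREMENT_NAMES) {
      ok <- is.finite(sub[[m]])
      if (sum(ok) < 3L) {
        row <- data.frame(pc = pc, measurement = m, r_squared = NA_real_,
                          p = NA_real_, significant = NA)
      } else {
        ft <- fit_line(sub$level[ok], sub[[m]][ok])
        row <- data.frame(pc = pc, measurement = m, r_squared = ft$r_squared,
                          p = ft$p, significant = ft$p < alpha)
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

# boxplot summary following the standard conventions: quartiles,
# whiskers at the data extremes after excluding 1.5*IQR outliers,
# notches at median +/- 1.57*IQR/sqrt(n)
boxplot_summary <- function(x) {
  q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75)))
  iqr <- q[3] - q[1]
  out_lo <- x < q[1] - 1.5 * iqr
  out_hi <- x > q[3] + 1.5 * iqr
  inl <- x[!(out_lo | out_hi)]
  list(q1 = q[1], median = q[2], q3 = q[3],
       whisker_low = min(inl), whisker_high = max(inl),
       outliers = sort(x[out_lo | out_hi]),
       notch_low = q[2] - 1.57 * iqr / sqrt(length(x)),
       notch_high = q[2] + 1.57 * iqr / sqrt(length(x)))
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Fixed-effects one-way ANOVA of the scores across groups. When
#' `p < alpha`, pairwise Tukey HSD comparisons are run at the same
#' `alpha` (adjusted p from the studentised range distribution).
#' Boxplot-ready summaries per group are always included.
#'
#' @param weights numeric scores, one per specimen (a single PC's scores).
#' @param groups group labels, same length; >= 2 groups, each n >= 2.
#' @param alpha significance level (default 0.05).
#' @return list with `F`, `p`, `df`, `group_means`, `pairwise`
#'   (data.frame: pair, difference, adjusted p, significant) or NULL
#'   when the omnibus test is not significant, and `boxplots`.
#' @export
compare_groups <- function(weights, groups, alpha = 0.05) {
  groups <- as.character(groups)
  gl <- split(weights, groups)
  if (length(gl) < 2L)
    stop("invalid input: need >= 2 groups", call. = FALSE)
  ns <- vapply(gl, length, 0L)
  if (any(ns < 2L))
    stop("invalid input: every group needs n >= 2", call. = FALSE)
  n <- length(weights)
  k <- length(gl)
  grand <- mean(weights)
  means <- vapply(gl, mean, 0)
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum(vapply(gl, function(x) sum((x - mean(x))^2), 0))
  df1 <- k - 1L
  df2 <- n - k
  ms_b <- ss_between / df1
  ms_w <- ss_within / df2
  f <- if (ms_w == 0) { if (ms_b == 0) 0 else Inf } else ms_b / ms_w
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)

  pairwise <- NULL
  if (is.finite(p) && p < alpha) {
    pairs <- utils::combn(names(gl), 2L)
    rows <- lapply(seq_len(ncol(pairs)), function(c2) {
      i <- pairs[1, c2]; j <- pairs[2, c2]
      diff <- means[j] - means[i]
      se <- sqrt(ms_w / 2 * (1 / ns[i] + 1 / ns[j]))
      padj <- if (se == 0) { if (diff != 0) 0 else 1 } else
        stats::ptukey(abs(diff) / se, nmeans = k, df = df2,
                      lower.tail = FALSE)
      data.frame(pair = paste(j, i, sep = "-"), difference = unname(diff),
                 p_adj = unname(padj), significant = unname(padj < alpha))
    })
    pairwise <- do.call(rbind, rows)
  }
  list(F = f, p = p, df = c(df1, df2), group_means = means,
       pairwise = pairwise, boxplots = lapply(gl, boxplot_summary))
}

#' Group comparison across all PCs of a model
#'
#' @param scores matrix of PC scores, specimens x PCs (e.g. projections
#'   of a training cohort).
#' @param groups group labels per specimen.
#' @param alpha significance level.
#' @return list of [compare_groups()] results, one per PC.
#' @export
compare_groups_all <- function(scores, groups, alpha = 0.05) {
  out <- lapply(seq_len(ncol(scores)), function(j)
    compare_groups(scores[, j], groups, alpha = alpha))
  names(out) <- paste0("PC", seq_len(ncol(scores)))
  out
}

#' Training-set PC scores of a cohort
#'
#' @param model a `shape_model`.
#' @param cohort the `registered_cohort` it was fitted on.
#' @param units `"raw"` or `"sigma"`.
#' @return numeric matrix, specimens x PCs.
#' @export
cohort_scores <- function(model, cohort, units = c("raw", "sigma")) {
  units <- match.arg(units)
  x <- cohort_matrix(cohort)
  if (cohort$has_material && !model$has_material)
    x <- x[, rep(c(TRUE, TRUE, TRUE, FALSE), cohort$M), drop = FALSE]
  sc <- t(apply(x, 1, function(r) project(model, r)$values))
  if (units == "sigma")
    sc <- sweep(sc, 2, sqrt(model$eigenvalues), "/")
  rownames(sc) <- cohort$ids
  colnames(sc) <- paste0("PC", seq_len(ncol(sc)))
  sc
}
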