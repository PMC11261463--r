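#' Bonferroni correction
#'
#' @param p_raw raw p-value(s) in [0, 1].
#' @param m family size (>= 1).
#' @return `min(1, m * p_raw)`, elementwise.
#' @export
bonferroni <- function(p_raw, m) {
  if (any(m < 1)) stop("family size m must be >= 1")
  if (any(p_raw < 0 | p_raw > 1)) stop("p_raw must lie in [0, 1]")
  pmin(1, m * p_raw)
}

#' Pooled-variance two-sample t-test from summary statistics
#'
#' Student's independent-samples t with pooled variance and
#' `df = n_a + n_b - 2`, computed from group means, SDs and sizes.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summaries (n >= 2 each).
#' @return list: `t`, `df`, `p` (two-tailed).
#' @export
t_test_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2 || n_b < 2) stop("both groups need n >= 2")
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
  if (sp2 == 0) {
    if (mean_a == mean_b) stop("zero variance and equal means: t undefined")
    return(list(t = sign(mean_a - mean_b) * Inf, df = n_a + n_b - 2, p = 0))
  }
  t <- (mean_a - mean_b) / sqrt(sp2 * (1 / n_a + 1 / n_b))
  df <- n_a + n_b - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' One-way ANOVA from group summary statistics
#'
#' F = MSB / MSW with the between-group sum of squares from group means
#' around the size-weighted grand mean and the within-group sum of squares
#' `sum((n_i - 1) * s_i^2)`. Equals a raw-data one-way ANOVA whenever the
#' summaries are exact.
#'
#' @param means,sds,ns per-group mean, SD and size (>= 2 groups).
#' @return list: `F`, `df_between`, `df_within`, `p`.
#' @export
anova_oneway_from_summary <- function(means, sds, ns) {
  k <- length(means)
  if (k < 2 || length(sds) != k || length(ns) != k)
    stop("need >= 2 groups with matching means, sds, ns")
  N <- sum(ns)
  gm <- sum(ns * means) / N
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((ns - 1) * sds^2)
  if (ssw == 0 && ssb == 0) stop("no variance anywhere: F undefined")
  if (ssw == 0) stop("zero within-group variance: F undefined")
  Fst <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = Fst, df_between = k - 1, df_within = N - k,
       p = stats::pf(Fst, k - 1, N - k, lower.tail = FALSE))
}

#' Pearson chi-square test of independence
#'
#' Classic `sum((O - E)^2 / E)` with expected counts from the row/column
#' margins, `df = (r - 1)(c - 1)`, no continuity correction.
#'
#' @param table r-by-c matrix of counts with positive margins.
#' @return list: `chisq`, `df`, `p`.
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column margin: expected counts undefined")
  # small-expected-count approximation warnings are the caller's concern
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Covariate-adjusted partial correlation
#'
#' Residualizes `x` and `y` on the covariates (plus intercept) by least
#' squares and correlates the residuals; the p-value uses the t transform
#' with `df = n - 2 - k` for `k` covariates. With no covariates this is
#' the plain Pearson correlation.
#'
#' @param x,y numeric vectors (e.g. an FC edge value and a clinical score).
#' @param covariates numeric matrix/data.frame of nuisance variables, or
#'   NULL; must be full rank with `n > k + 2`.
#' @param x_name,y_name labels carried into the result.
#' @return list of class `partial_corr`: `r_partial`, `df`, `p_raw`, plus
#'   names and covariate count.
#' @export
partial_correlation <- function(x, y, covariates = NULL,
                                x_name = "x", y_name = "y") {
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ")
  if (is.null(covariates)) {
    Z <- matrix(1, n, 1)
    k <- 0L
  } else {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariates row count differs from n")
    k <- ncol(covariates)
    Z <- cbind(1, covariates)
  }
  if (n <= k + 2) stop("need n > k + 2 observations")
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) stop("covariate matrix is rank deficient")
  rx <- stats::lm.fit(Z, x)$residuals
  ry <- stats::lm.fit(Z, y)$residuals
  # numerically-zero residual variance: x or y lies in the covariate span
  tol_x <- 1e-10 * max(stats::sd(x), 1)
  tol_y <- 1e-10 * max(stats::sd(y), 1)
  if (stats::sd(rx) <= tol_x || stats::sd(ry) <= tol_y)
    stop("x or y is constant after residualization")
  r <- stats::cor(rx, ry)
  r <- min(1, max(-1, r))
  df <- n - 2L - k
  p <- if (abs(r) == 1) 0 else {
    t <- abs(r) * sqrt(df / (1 - r^2))
    2 * stats::pt(-t, df)
  }
  structure(list(x_name = x_name, y_name = y_name, n_covariates = k,
                 r_partial = r, df = df, p_raw = p),
            class = "partial_corr")
}

#' @export
print.partial_corr <- function(x, ...) {
  cat(sprintf("partial correlation %s ~ %s | %d covariate(s): r = %.4f (df = %d, p = %.4g)\n",
              x$x_name, x$y_name, x$n_covariates, x$r_partial, x$df, x$p_raw))
  invisible(x)
}

#' Seed-based FC group comparison
#'
#' For each seed node, extracts every seed-target FC value per subject and
#' compares the two groups with a pooled-variance two-sample t-test;
#' Bonferroni correction uses the number of tests performed (duplicate
#' unordered seed pairs are tested once) unless `family_size` is given.
#'
#' @param cohort a `cpm_cohort` containing both groups.
#' @param seeds 0-based seed node indices (typically CPM hub nodes).
#' @param groups two group labels (default the patient subtypes; the first
#'   is the reference whose lower mean gives negative t).
#' @param family_size Bonferroni family size, or `"auto"` (default: number
#'   of tests in this call).
#' @return data.frame of class `seed_fc_comparison`, one row per
#'   seed-target test, sorted by `p_raw`: seed, target, per-group mean/SD,
#'   `t`, `df`, `p_raw`, `p_bonf`, `m`.
#' @export
seed_fc_compare <- function(cohort, seeds,
                            groups = c("melancholic", "non_melancholic"),
                            family_size = "auto") {
  if (length(groups) != 2) stop("exactly two group labels are required")
  sub <- cohort$subjects
  ga <- sub$group == groups[1]
  gb <- sub$group == groups[2]
  if (sum(ga) < 2 || sum(gb) < 2)
    stop("both groups need at least 2 subjects")
  n <- cohort$n_nodes
  if (any(seeds < 0 | seeds >= n)) stop("seed node out of atlas range")
  X <- fc_edge_matrix(cohort)

  pairs <- do.call(rbind, lapply(seeds, function(s) {
    tg <- setdiff(0:(n - 1), s)
    cbind(pmin(s, tg), pmax(s, tg))
  }))
  pairs <- unique(pairs)
  flat <- edge_flat_index(pairs[, 1], pairs[, 2], n) + 1L

  va <- X[ga, flat, drop = FALSE]
  vb <- X[gb, flat, drop = FALSE]
  ma <- colMeans(va); mb <- colMeans(vb)
  sa <- apply(va, 2, stats::sd); sb <- apply(vb, 2, stats::sd)
  na <- sum(ga); nb <- sum(gb)
  sp2 <- ((na - 1) * sa^2 + (nb - 1) * sb^2) / (na + nb - 2)
  tstat <- ifelse(sp2 > 0, (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb)), 0)
  df <- na + nb - 2
  p_raw <- ifelse(sp2 > 0, 2 * stats::pt(-abs(tstat), df), 1)
  m <- if (identical(family_size, "auto")) nrow(pairs) else as.integer(family_size)

  # seed is the queried node; target the other endpoint
  seed_col <- ifelse(pairs[, 1] %in% seeds, pairs[, 1], pairs[, 2])
  target_col <- ifelse(seed_col == pairs[, 1], pairs[, 2], pairs[, 1])
  out <- data.frame(seed = seed_col, target = target_col,
                    mean_a = ma, sd_a = sa, mean_b = mb, sd_b = sb,
                    t = tstat, df = df, p_raw = p_raw,
                    p_bonf = bonferroni(p_raw, m), m = m)
  out <- out[order(out$p_raw, out$seed, out$target), ]
  rownames(out) <- NULL
  attr(out, "groups") <- groups
  class(out) <- c("seed_fc_comparison", "data.frame")
  out
}
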