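#' CPM configuration
#'
#' Settings for connectome-based predictive modeling: edge-selection
#' threshold, which correlation tail defines the predictive network,
#' cross-validation scheme, and the permutation-test size.
#'
#' @param p_threshold edge-selection significance level (default 1e-4, the
#'   stringent threshold typical for whole-connectome selection).
#' @param tail `"positive"` (default; network strength is the sum over
#'   positively selected edges), `"negative"`, or `"both"` (positive minus
#'   negative strength as the single predictor).
#' @param cv `"loocv"` (default) or `"kfold"`.
#' @param k folds for `cv = "kfold"` (default 10).
#' @param n_permutations permutation-test iterations (default 5000).
#' @param behavior name of the target behavioral score column (default
#'   `"teps_abstract_consummatory"`).
#' @param seed RNG seed for permutations and k-fold assignment.
#' @return object of class `cpm_config`.
#' @export
cpm_config <- function(p_threshold = 1e-4,
                       tail = c("positive", "negative", "both"),
                       cv = c("loocv", "kfold"),
                       k = 10,
                       n_permutations = 5000,
                       behavior = "teps_abstract_consummatory",
                       seed = 1) {
  tail <- match.arg(tail)
  cv <- match.arg(cv)
  if (!(p_threshold > 0 && p_threshold < 1))
    stop("p_threshold must lie in (0, 1)")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  structure(list(p_threshold = p_threshold, tail = tail, cv = cv,
                 k = as.integer(k),
                 n_permutations = as.integer(n_permutations),
                 behavior = behavior, seed = as.integer(seed)),
            class = "cpm_config")
}

#' Binary edge mask
#'
#' A selected edge set over the canonical flat edge order (see
#' [edge_pairs()]). `as.matrix()` renders it as a symmetric 0/1 node-by-
#' node matrix with zero diagonal.
#'
#' @param edges logical vector over flat edge positions.
#' @param n_nodes node count.
#' @param tail label (`"positive"`, `"negative"`, or other).
#' @return object of class `edge_mask`.
#' @export
edge_mask <- function(edges, n_nodes, tail = "positive") {
  stopifnot(is.logical(edges))
  n_nodes <- as.integer(n_nodes)
  if (!is.na(n_nodes) && length(edges) != n_edges(n_nodes))
    stop("edge vector length does not match n_nodes")
  structure(list(edges = edges, n_nodes = n_nodes, tail = tail),
            class = "edge_mask")
}

#' @export
as.matrix.edge_mask <- function(x, ...) {
  if (is.na(x$n_nodes))
    stop("mask has no node mapping (edge features without node count)")
  m <- devectorize_edges(as.numeric(x$edges), x$n_nodes)
  diag(m) <- 0
  m
}

#' @export
print.edge_mask <- function(x, ...) {
  cat(sprintf("%s edge mask: %d of %d edges over %d nodes\n",
              x$tail, sum(x$edges), length(x$edges), x$n_nodes))
  invisible(x)
}

#' List the (i, j) node pairs of an edge mask
#' @param mask an `edge_mask`.
#' @return integer matrix with 0-based columns `i`, `j`.
#' @export
mask_pairs <- function(mask) {
  if (is.na(mask$n_nodes))
    stop("mask has no node mapping (edge features without node count)")
  edge_pairs(mask$n_nodes)[mask$edges, , drop = FALSE]
}

#' Per-edge correlation with a behavioral score
#'
#' Pearson correlation of every edge column against the behavior vector,
#' with two-tailed p-values from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' Constant edges get `r = 0`, `p = 1`.
#'
#' @param edge_values subjects-by-edges numeric matrix.
#' @param behavior per-subject score (nonconstant; >= 4 subjects).
#' @return list with numeric vectors `r` and `p` (one entry per edge) and
#'   `n` subjects.
#' @export
edge_behavior_correlation <- function(edge_values, behavior) {
  X <- as.matrix(edge_values)
  n <- nrow(X)
  if (n < 4) stop("at least 4 subjects are required")
  if (length(behavior) != n)
    stop("behavior length does not match subject count")
  if (stats::var(behavior) == 0)
    stop("behavior is constant; edge selection is undefined")
  r <- suppressWarnings(as.numeric(stats::cor(X, behavior)))
  r[!is.finite(r)] <- 0
  r <- pmin(1, pmax(-1, r))
  p <- r_to_p(r, n)
  list(r = r, p = p, n = n)
}

# two-tailed p for a Pearson r on n observations (df = n - 2)
r_to_p <- function(r, n) {
  p <- rep(1, length(r))
  ok <- abs(r) < 1 & r != 0
  t <- abs(r[ok]) * sqrt((n - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * stats::pt(-t, n - 2)
  p[abs(r) == 1] <- 0
  p
}

#' Select predictive edges by sign and significance
#'
#' @param r,p per-edge correlation and p-value (from
#'   [edge_behavior_correlation()]).
#' @param p_threshold selection level, or a [cpm_config()].
#' @param n_nodes node count for the masks (inferred from the edge count
#'   when omitted).
#' @return list of disjoint `positive` and `negative` [edge_mask()]s:
#'   positive = `{r > 0 & p < p_threshold}`, negative likewise for `r < 0`.
#' @export
select_edges <- function(r, p, p_threshold = 1e-4, n_nodes = NULL) {
  if (inherits(p_threshold, "cpm_config")) p_threshold <- p_threshold$p_threshold
  if (is.null(n_nodes)) n_nodes <- infer_n_nodes(length(r))
  list(positive = edge_mask(r > 0 & p < p_threshold, n_nodes, "positive"),
       negative = edge_mask(r < 0 & p < p_threshold, n_nodes, "negative"))
}

infer_n_nodes <- function(E) {
  n <- (1 + sqrt(1 + 8 * E)) / 2
  if (n != round(n))
    stop(sprintf("%d is not a valid unordered-edge count", E))
  as.integer(n)
}

#' Network strength of one subject under an edge mask
#'
#' Sum of the subject's FC values over the masked edges, each unordered
#' pair counted once. The single predictor of the CPM linear model.
#'
#' @param fc FC matrix (or flat edge vector).
#' @param mask an [edge_mask()] (or symmetric 0/1 matrix with zero
#'   diagonal).
#' @return scalar strength; 0 for an empty mask.
#' @export
network_strength <- function(fc, mask) {
  if (is.matrix(mask)) {
    if (any(mask != t(mask)) || any(diag(mask) != 0) ||
        !all(mask %in% c(0, 1)))
      stop("matrix mask must be symmetric 0/1 with zero diagonal")
    mask <- edge_mask(vectorize_edges(ifelse(mask > 0, 1, 0) + diag(nrow(mask)),
                                      check = FALSE) > 0,
                      nrow(mask))
  }
  v <- if (is.matrix(fc)) {
    if (nrow(fc) != mask$n_nodes) stop("fc and mask dimensions disagree")
    vectorize_edges(fc, check = FALSE)
  } else {
    if (length(fc) != length(mask$edges)) stop("fc and mask dimensions disagree")
    fc
  }
  sum(v[mask$edges])
}

# resolve (edge matrix, behavior vector, n_nodes, ids) from cohort/matrix input
resolve_cpm_input <- function(x, config, behavior, n_nodes) {
  if (inherits(x, "cpm_cohort")) {
    X <- fc_edge_matrix(x)
    if (is.null(behavior)) {
      if (!config$behavior %in% names(x$subjects))
        stop("behavior score '", config$behavior, "' missing from cohort")
      behavior <- x$subjects[[config$behavior]]
    }
    n_nodes <- x$n_nodes
    ids <- x$subjects$id
  } else {
    X <- as.matrix(x)
    if (is.null(behavior)) stop("behavior vector required for matrix input")
    if (is.null(n_nodes)) n_nodes <- infer_n_nodes(ncol(X))
    n_nodes <- as.integer(n_nodes)  # NA allowed: plain edge features
    ids <- rownames(X)
    if (is.null(ids)) ids <- sprintf("S%03d", seq_len(nrow(X)))
  }
  if (any(!is.finite(behavior))) stop("behavior contains missing values")
  list(X = X, y = as.numeric(behavior), n_nodes = n_nodes, ids = ids)
}

#' Run connectome-based predictive modeling
#'
#' Cross-validated prediction of a behavioral score from FC edges. For
#' each held-out subject (LOOCV, the default), edges are selected on the
#' training subjects only ([edge_behavior_correlation()] +
#' [select_edges()]), each training subject is scored by network strength
#' under the training mask, a univariate least-squares line
#' `behavior ~ strength` is fitted on the training subjects, and the
#' held-out subject is predicted from its own strength. Folds whose mask
#' is empty (or whose strengths are degenerate) predict the training-mean
#' behavior and are flagged. The result is invariant to subject ordering.
#'
#' @param x a `cpm_cohort` (typically [cohort_patients()]) or a
#'   subjects-by-edges matrix.
#' @param config a [cpm_config()].
#' @param behavior score vector (required for matrix input; taken from
#'   `config$behavior` column for cohorts).
#' @param n_nodes node count (inferred when possible).
#' @return object of class `cpm_result`: `predictions` (named, one per
#'   subject), `observed`, `r_obs` (Pearson correlation of observed vs
#'   predicted), `mse` (mean squared prediction error), `fold_masks`
#'   (folds-by-edges logical matrix for the configured tail's positive
#'   component; positive and negative kept separately in `fold_masks_pos`
#'   / `fold_masks_neg`), `consensus_mask` (edge-wise intersection across
#'   folds), `empty_folds`, `n_nodes`, `config`.
#' @export
run_cpm <- function(x, config = cpm_config(), behavior = NULL,
                    n_nodes = NULL) {
  inp <- resolve_cpm_input(x, config, behavior, n_nodes)
  X <- inp$X; y <- inp$y
  n <- nrow(X)
  if (n < 6) stop("at least 6 subjects are required for CPM")
  if (stats::var(y) == 0) stop("behavior is constant")

  if (config$cv == "loocv") {
    core <- cpm_loocv_core(X, y, config$p_threshold, config$tail)
  } else {
    core <- cpm_kfold_core(X, y, config$p_threshold, config$tail,
                           config$k, config$seed)
  }
  pred <- core$pred
  names(pred) <- inp$ids
  primary <- if (config$tail == "negative") core$Mneg else core$Mpos
  consensus <- colSums(primary) == nrow(primary)
  r_obs <- if (stats::sd(pred) > 0) stats::cor(y, pred) else NA_real_
  structure(
    list(predictions = pred, observed = stats::setNames(y, inp$ids),
         r_obs = r_obs, mse = mean((y - pred)^2),
         fold_masks = primary,
         fold_masks_pos = core$Mpos, fold_masks_neg = core$Mneg,
         consensus_mask = edge_mask(consensus, inp$n_nodes,
                                    tail = config$tail),
         empty_folds = core$empty,
         n_nodes = inp$n_nodes, config = config),
    class = "cpm_result")
}

#' @export
print.cpm_result <- function(x, ...) {
  cat(sprintf("CPM (%s tail, %s): r_obs = %.4f, MSE = %.4f over %d subjects; consensus network: %d edges\n",
              x$config$tail, x$config$cv, x$r_obs, x$mse,
              length(x$predictions), sum(x$consensus_mask$edges)))
  if (!is.null(x$p_perm))
    cat(sprintf("permutation p = %.4f (%d iterations)\n", x$p_perm,
                length(x$null_distribution)))
  invisible(x)
}

# LOOCV engine. Leave-one-out training correlations come from downdated
# sufficient statistics (totals minus the held-out row), so no per-fold
# copy of X is made. Edge selection at the two-tailed level p_threshold is
# applied as |r| > r_crit (the exact monotone equivalent of the t-transform
# p-value), avoiding a p-matrix. The X-only statistics are precomputed once
# in cpm_loocv_prepare() and reused across permutations of y.
cpm_loocv_prepare <- function(X) {
  n <- nrow(X); m <- n - 1
  Sx <- colSums(X); Sxx <- colSums(X * X)
  sx <- matrix(Sx, n, ncol(X), byrow = TRUE) - X    # training sums per fold
  den_x <- m * (matrix(Sxx, n, ncol(X), byrow = TRUE) - X * X) - sx * sx
  den_x[den_x < 0] <- 0
  list(X = X, n = n, m = m, sx = sx, den_x = den_x)
}

cpm_loocv_core <- function(X, y, p_threshold, tail, pre = NULL) {
  if (is.null(pre)) pre <- cpm_loocv_prepare(X)
  n <- pre$n; m <- pre$m
  df <- m - 2
  t_crit <- stats::qt(1 - p_threshold / 2, df)
  rc2 <- t_crit^2 / (df + t_crit^2)

  Sxy <- as.numeric(crossprod(X, y))
  sy <- sum(y) - y                              # length n, per fold
  syy <- sum(y * y) - y * y
  sxy <- matrix(Sxy, n, ncol(X), byrow = TRUE) - X * y
  num <- m * sxy - pre$sx * sy                  # sign(num) = sign(r)
  den2 <- pre$den_x * (m * syy - sy * sy)
  sel <- num * num > rc2 * den2 & den2 > 0      # |r| > r_crit
  Mpos <- sel & num > 0                         # n x E, row i = fold i mask
  Mneg <- sel & num < 0

  empty <- logical(n)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    sgn <- switch(tail,
      positive = which(Mpos[i, ]),
      negative = which(Mneg[i, ]),
      both = NULL)
    if (tail == "both") {
      s <- rowSums(X[, Mpos[i, ], drop = FALSE]) -
        rowSums(X[, Mneg[i, ], drop = FALSE])
      empty[i] <- !any(Mpos[i, ] | Mneg[i, ])
    } else {
      s <- rowSums(X[, sgn, drop = FALSE])
      empty[i] <- length(sgn) == 0
    }
    ytr <- y[-i]; str <- s[-i]
    vs <- stats::var(str)
    if (empty[i] || vs == 0) {
      pred[i] <- mean(ytr)
    } else {
      b <- stats::cov(str, ytr) / vs
      a <- mean(ytr) - b * mean(str)
      pred[i] <- a + b * s[i]
    }
  }
  list(pred = pred, Mpos = Mpos, Mneg = Mneg, empty = empty)
}

cpm_kfold_core <- function(X, y, p_threshold, tail, k, seed) {
  n <- nrow(X)
  if (k < 2 || k > n) stop("k must lie in [2, n]")
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  E <- ncol(X)
  Mpos <- matrix(FALSE, k, E); Mneg <- matrix(FALSE, k, E)
  empty <- logical(k)
  pred <- numeric(n)
  for (f in seq_len(k)) {
    te <- fold == f
    ebc <- edge_behavior_correlation(X[!te, , drop = FALSE], y[!te])
    Mpos[f, ] <- ebc$r > 0 & ebc$p < p_threshold
    Mneg[f, ] <- ebc$r < 0 & ebc$p < p_threshold
    mv <- switch(tail, positive = Mpos[f, ], negative = Mneg[f, ],
                 both = Mpos[f, ] | Mneg[f, ])
    empty[f] <- !any(mv)
    sgn <- switch(tail, positive = Mpos[f, ] * 1, negative = Mneg[f, ] * 1,
                  both = Mpos[f, ] - Mneg[f, ])
    s <- as.numeric(X %*% sgn)
    str <- s[!te]; ytr <- y[!te]
    vs <- stats::var(str)
    if (empty[f] || vs == 0) {
      pred[te] <- mean(ytr)
    } else {
      b <- stats::cov(str, ytr) / vs
      a <- mean(ytr) - b * mean(str)
      pred[te] <- a + b * s[te]
    }
  }
  list(pred = pred, Mpos = Mpos, Mneg = Mneg, empty = empty)
}

#' Permutation test of CPM predictive performance
#'
#' Each iteration shuffles the behavior vector across subjects (FC held
#' fixed) and re-runs the full cross-validated CPM; the p-value uses the
#' add-one estimator `p = (1 + #{r_null >= r_obs}) / (1 + N)` with ties
#' counted as exceedances, so `p` is never zero. Iterations whose
#' predictions are degenerate (e.g. edge selection fails in every fold)
#' contribute `r_null = 0`; their count is reported. Permutations are
#' drawn from one seeded stream, so results are reproducible.
#'
#' @inheritParams run_cpm
#' @return the [run_cpm()] result augmented with `p_perm`,
#'   `null_distribution` (permuted r values) and `n_degenerate_null`.
#' @export
permutation_test <- function(x, config = cpm_config(), behavior = NULL,
                             n_nodes = NULL) {
  inp <- resolve_cpm_input(x, config, behavior, n_nodes)
  res <- run_cpm(x, config, behavior, n_nodes)
  if (is.na(res$r_obs))
    stop("observed CPM run is degenerate; permutation test undefined")
  X <- inp$X; y <- inp$y
  n <- length(y)
  N <- config$n_permutations
  set.seed(config$seed)
  perm_idx <- matrix(0L, n, N)
  for (b in seq_len(N)) perm_idx[, b] <- sample.int(n)
  null_r <- numeric(N)
  n_degen <- 0L
  pre <- if (config$cv == "loocv") cpm_loocv_prepare(X) else NULL
  for (b in seq_len(N)) {
    yp <- y[perm_idx[, b]]
    core <- if (config$cv == "loocv")
      cpm_loocv_core(X, yp, config$p_threshold, config$tail, pre = pre)
    else
      cpm_kfold_core(X, yp, config$p_threshold, config$tail,
                     config$k, config$seed + b)
    if (stats::sd(core$pred) > 0) {
      null_r[b] <- stats::cor(yp, core$pred)
    } else {
      null_r[b] <- 0
      n_degen <- n_degen + 1L
    }
  }
  res$p_perm <- perm_pvalue(res$r_obs, null_r)
  res$null_distribution <- null_r
  res$n_degenerate_null <- n_degen
  res
}

#' Add-one permutation p-value
#'
#' `p = (1 + #\{r_null >= r_obs\}) / (1 + N)`; ties count as exceedances,
#' so the estimate lies in `[1/(N+1), 1]` and is never zero.
#'
#' @param r_obs observed statistic.
#' @param null_r vector of permuted statistics.
#' @return the p-value estimate.
#' @export
perm_pvalue <- function(r_obs, null_r) {
  (1 + sum(null_r >= r_obs)) / (1 + length(null_r))
}

#' Consensus mask and node degrees
#'
#' Intersects per-fold edge masks into a consensus network and computes
#' each node's degree (incident consensus edges). Nodes with degree at or
#' above `hub_threshold` are flagged as hubs — the highest-degree nodes
#' used as seeds for follow-up analysis.
#'
#' @param fold_masks folds-by-edges logical matrix (e.g.
#'   `cpm_result$fold_masks`), a list of [edge_mask()]s, or a single
#'   `edge_mask`.
#' @param n_nodes node count (required for a plain matrix).
#' @param hub_threshold minimum degree to flag a hub (default 5).
#' @return list with `consensus` (an `edge_mask`) and `degrees`
#'   (data.frame: `node` 0-based, `degree`, `is_hub`; sorted by degree
#'   descending, ties by node index ascending).
#' @export
consensus_and_degree <- function(fold_masks, n_nodes = NULL,
                                 hub_threshold = 5) {
  if (inherits(fold_masks, "edge_mask")) fold_masks <- list(fold_masks)
  if (is.list(fold_masks)) {
    n_nodes <- fold_masks[[1]]$n_nodes
    fold_masks <- do.call(rbind, lapply(fold_masks, function(m) m$edges))
  }
  if (is.null(n_nodes)) n_nodes <- infer_n_nodes(ncol(fold_masks))
  if (nrow(fold_masks) < 1) stop("at least one fold mask is required")
  consensus <- colSums(fold_masks) == nrow(fold_masks)
  ep <- edge_pairs(n_nodes)[consensus, , drop = FALSE]
  deg <- tabulate(c(ep[, 1], ep[, 2]) + 1L, nbins = n_nodes)
  ord <- order(-deg, seq_len(n_nodes))
  degrees <- data.frame(node = (seq_len(n_nodes) - 1L)[ord],
                        degree = deg[ord],
                        is_hub = deg[ord] >= hub_threshold)
  rownames(degrees) <- NULL
  list(consensus = edge_mask(consensus, n_nodes, "consensus"),
       degrees = degrees)
}

#' Region-by-region edge counts of a mask
#'
#' Collapses a selected edge set onto atlas regions: cell (a, b) counts
#' mask edges with one endpoint in region a and the other in b. Matrices
#' are symmetric; summing each unordered region pair once (upper triangle
#' plus diagonal) recovers the mask's edge count.
#'
#' @param mask an [edge_mask()].
#' @param atlas atlas table covering all nodes (see [synthetic_atlas()]).
#' @return list of symmetric count matrices `lobe` and `gyrus`.
#' @export
summarize_mask_by_atlas <- function(mask, atlas) {
  assert_atlas(atlas, n_nodes = mask$n_nodes)
  ep <- mask_pairs(mask)
  count_by <- function(labels) {
    lev <- unique(labels)
    m <- matrix(0L, length(lev), length(lev), dimnames = list(lev, lev))
    if (nrow(ep)) {
      a <- labels[ep[, 1] + 1L]
      b <- labels[ep[, 2] + 1L]
      for (k in seq_along(a)) {
        m[a[k], b[k]] <- m[a[k], b[k]] + 1L
        if (a[k] != b[k]) m[b[k], a[k]] <- m[b[k], a[k]] + 1L
      }
    }
    m
  }
  list(lobe = count_by(atlas$lobe), gyrus = count_by(atlas$gyrus))
}
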