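# shared fixtures, all built in code

# compact cohort spec for fast tests: 30 nodes, 12/10/8 subjects,
# 12 planted edges on two degree-5 hubs, subtype edge (15, 25)
small_spec <- function(seed = 1, planted_positive_edges = NULL, ...) {
  planted <- planted_positive_edges
  if (is.null(planted)) {
    planted <- rbind(
      cbind(5L, c(1L, 8L, 10L, 12L, 20L)),
      cbind(15L, c(2L, 9L, 11L, 21L, 25L)),
      rbind(c(3L, 7L), c(18L, 26L))
    )
    colnames(planted) <- c("i", "j")
  }
  cohort_spec(n_nodes = 30,
              group_sizes = c(melancholic = 12, non_melancholic = 10,
                              control = 8),
              planted_positive_edges = planted,
              subtype_diff_edge = c(15L, 25L),
              edge_behavior_r = 0.6,
              sex_male_counts = c(melancholic = 5, non_melancholic = 4,
                                  control = 3),
              seed = seed, ...)
}

# random valid FC matrix
random_fc <- function(n, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(n * n, -0.8, 0.8), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

# brute-force LOOCV CPM: explicit per-fold recomputation with cor/lm,
# independent of the package's downdated-statistics engine
brute_force_loocv <- function(X, y, p_threshold, tail = "positive") {
  n <- nrow(X)
  vapply(seq_len(n), function(i) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    r <- suppressWarnings(as.numeric(cor(Xtr, ytr)))
    r[!is.finite(r)] <- 0
    p <- vapply(r, function(rr) {
      if (abs(rr) >= 1) return(0)
      if (rr == 0) return(1)
      tt <- abs(rr) * sqrt((n - 3) / (1 - rr^2))
      2 * pt(-tt, n - 3)
    }, numeric(1))
    keep <- switch(tail,
                   positive = r > 0 & p < p_threshold,
                   negative = r < 0 & p < p_threshold)
    if (!any(keep)) return(mean(ytr))
    s <- rowSums(X[, keep, drop = FALSE])
    if (var(s[-i]) == 0) return(mean(ytr))
    fit <- lm(ytr ~ s[-i])
    unname(coef(fit)[1] + coef(fit)[2] * s[i])
  }, numeric(1))
}

default_planted_flat <- function() {
  pe <- default_planted_edges()
  edge_flat_index(pe[, 1], pe[, 2], 246) + 1L
}
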