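test_that("edge-behavior correlation matches the t-distribution oracle", {
  set.seed(1)
  y <- rnorm(10)
  X <- cbind(y, matrix(rnorm(10 * 4), 10, 4))  # first edge duplicates behavior
  res <- edge_behavior_correlation(X, y)
  expect_equal(res$r[1], 1)
  expect_equal(res$p[1], 0)
  # independently coded t-CDF evaluation for a single worked edge
  r2 <- cor(X[, 2], y)
  t2 <- abs(r2) * sqrt((10 - 2) / (1 - r2^2))
  expect_equal(res$p[2], 2 * (1 - pt(t2, 8)), tolerance = 1e-10)
  expect_equal(res$r[2], r2, tolerance = 1e-12)

  Xc <- X; Xc[, 3] <- 5  # constant edge
  resc <- edge_behavior_correlation(Xc, y)
  expect_equal(resc$r[3], 0)
  expect_equal(resc$p[3], 1)
  expect_error(edge_behavior_correlation(X, rep(1, 10)), "constant")
})

test_that("selection p-values are type-I calibrated under the null", {
  set.seed(21)
  X <- matrix(rnorm(59 * 10000), 59, 10000)
  y <- rnorm(59)
  res <- edge_behavior_correlation(X, y)
  expect_lt(abs(mean(res$p < 0.05) - 0.05), 0.01)
})

test_that("edge selection splits by sign at the threshold", {
  set.seed(2)
  r <- runif(45, -1, 1)
  p <- runif(45)
  sel <- select_edges(r, p, p_threshold = 0.999999)
  expect_equal(sel$positive$edges, r > 0 & p < 0.999999)
  expect_false(any(sel$positive$edges & sel$negative$edges))
  sel0 <- select_edges(r, rep(1, 45), p_threshold = 1e-4)
  expect_equal(sum(sel0$positive$edges) + sum(sel0$negative$edges), 0L)
})

test_that("network strength is the masked upper-triangle sum", {
  m <- diag(1, 4)
  m[1, 2] <- m[2, 1] <- 0.2
  m[3, 4] <- m[4, 3] <- 0.3
  mk <- edge_mask(rep(FALSE, 6), 4)
  expect_equal(network_strength(m, mk), 0)
  mk$edges[c(1, 6)] <- TRUE  # edges (0,1) and (2,3)
  expect_equal(network_strength(m, mk), 0.5)

  set.seed(3)
  fc <- random_fc(8)
  sel <- runif(28) < 0.4
  mask <- edge_mask(sel, 8)
  # brute-force oracle over the upper triangle
  mm <- as.matrix(mask)
  acc <- 0
  for (i in 1:7) for (j in (i + 1):8) if (mm[i, j] == 1) acc <- acc + fc[i, j]
  expect_equal(network_strength(fc, mask), acc, tolerance = 1e-12)
  expect_equal(network_strength(fc, mm), acc, tolerance = 1e-12)
  expect_error(network_strength(random_fc(5), mask), "disagree")
})

test_that("LOOCV recovers a noiseless linear edge-behavior relation", {
  set.seed(9)
  X <- matrix(rnorm(20 * 45), 20, 45)
  y <- 3 + 2 * X[, 7]
  res <- run_cpm(X, cpm_config(p_threshold = 0.01), behavior = y,
                 n_nodes = 10)
  expect_gt(res$r_obs, 0.99)
  expect_lt(res$mse, 1e-20)
})

test_that("cross-validated predictions are centred under the null", {
  r <- vapply(1:100, function(s) {
    set.seed(300 + s)
    X <- matrix(rnorm(59 * 200), 59, 200)
    y <- rnorm(59)
    run_cpm(X, cpm_config(p_threshold = 0.05), behavior = y,
            n_nodes = NA)$r_obs
  }, numeric(1))
  expect_lt(abs(mean(r)), 0.1)
})

test_that("predictions are invariant to subject ordering", {
  set.seed(13)
  X <- matrix(rnorm(15 * 45), 15, 45,
              dimnames = list(sprintf("P%02d", 1:15), NULL))
  y <- rnorm(15)
  res <- run_cpm(X, cpm_config(p_threshold = 0.1), behavior = y, n_nodes = 10)
  perm <- sample(15)
  res2 <- run_cpm(X[perm, ], cpm_config(p_threshold = 0.1),
                  behavior = y[perm], n_nodes = 10)
  expect_equal(res2$predictions[names(res$predictions)], res$predictions,
               tolerance = 1e-12)
})

test_that("held-out behavior never leaks into its own prediction", {
  set.seed(14)
  X <- matrix(rnorm(12 * 28), 12, 28)
  y <- X[, 5] + rnorm(12, 0, 0.5)
  cfg <- cpm_config(p_threshold = 0.2)
  base <- run_cpm(X, cfg, behavior = y, n_nodes = 8)
  for (i in c(1, 6, 12)) {
    y2 <- y
    y2[i] <- y[i] + 1000
    mod <- run_cpm(X, cfg, behavior = y2, n_nodes = 8)
    expect_equal(unname(mod$predictions[i]), unname(base$predictions[i]),
                 tolerance = 1e-10)
  }
})

test_that("folds with empty masks fall back to the training mean", {
  set.seed(15)
  X <- matrix(rnorm(10 * 15), 10, 15)
  y <- rnorm(10)
  res <- run_cpm(X, cpm_config(p_threshold = 1e-12), behavior = y,
                 n_nodes = 6)
  expect_true(all(res$empty_folds))
  means <- vapply(1:10, function(i) mean(y[-i]), numeric(1))
  expect_equal(unname(res$predictions), means, tolerance = 1e-12)
})

test_that("k-fold cross-validation is seeded and reproducible", {
  set.seed(16)
  X <- matrix(rnorm(24 * 45), 24, 45)
  y <- X[, 3] + rnorm(24, 0, 0.3)
  cfg <- cpm_config(p_threshold = 0.05, cv = "kfold", k = 4, seed = 5)
  a <- run_cpm(X, cfg, behavior = y, n_nodes = 10)
  b <- run_cpm(X, cfg, behavior = y, n_nodes = 10)
  expect_identical(a$predictions, b$predictions)
  expect_equal(dim(a$fold_masks), c(4L, 45L))
  expect_gt(a$r_obs, 0.5)
})

test_that("permutation p-values use the add-one estimator with tie exceedance", {
  null_r <- seq(-0.99, 0, length.out = 199)
  expect_equal(perm_pvalue(0.5, null_r), 1 / 200)   # above all nulls
  expect_equal(perm_pvalue(-1, null_r), 1.0)        # below all nulls
  expect_equal(perm_pvalue(0, null_r), 2 / 200)     # tie counts
  set.seed(17)
  X <- matrix(rnorm(20 * 45), 20, 45)
  y <- X[, 2] + rnorm(20, 0, 0.2)
  res <- permutation_test(X, cpm_config(p_threshold = 0.05,
                                        n_permutations = 99, seed = 3),
                          behavior = y, n_nodes = 10)
  expect_gte(res$p_perm, 1 / 100)
  expect_lte(res$p_perm, 1)
  expect_length(res$null_distribution, 99)
  res2 <- permutation_test(X, cpm_config(p_threshold = 0.05,
                                         n_permutations = 99, seed = 3),
                           behavior = y, n_nodes = 10)
  expect_identical(res$null_distribution, res2$null_distribution)
})

test_that("consensus intersects folds and degrees obey conservation", {
  set.seed(18)
  fold_masks <- matrix(runif(5 * 45) < 0.5, 5, 45)
  cd <- consensus_and_degree(fold_masks, n_nodes = 10, hub_threshold = 5)
  expect_equal(cd$consensus$edges, colSums(fold_masks) == 5)
  # consensus is a subset of every fold mask
  for (f in 1:5) expect_true(all(fold_masks[f, cd$consensus$edges]))
  # degree = row sums of the mask matrix; sum = 2 |E|
  mm <- as.matrix(cd$consensus)
  deg <- cd$degrees$degree[order(cd$degrees$node)]
  expect_equal(deg, unname(rowSums(mm)))
  expect_equal(sum(deg), 2 * sum(cd$consensus$edges))
})

test_that("hub flagging respects the degree threshold boundary", {
  # one node with 7 incident edges, one with 4
  pairs <- rbind(cbind(0L, 1:7), cbind(9L, 10:13))
  sel <- rep(FALSE, n_edges(14))
  sel[edge_flat_index(pairs[, 1], pairs[, 2], 14) + 1L] <- TRUE
  cd <- consensus_and_degree(edge_mask(sel, 14), hub_threshold = 5)
  expect_true(cd$degrees$is_hub[cd$degrees$node == 0])
  expect_false(cd$degrees$is_hub[cd$degrees$node == 9])
  expect_equal(cd$degrees$degree[1], 7)
  expect_equal(cd$degrees$node[1], 0)  # sorted by degree desc
})

test_that("atlas summaries conserve the mask edge count", {
  at <- synthetic_atlas(20)
  empty <- edge_mask(rep(FALSE, n_edges(20)), 20)
  s0 <- summarize_mask_by_atlas(empty, at)
  expect_true(all(s0$lobe == 0) && all(s0$gyrus == 0))

  # single edge within one lobe
  same <- which(at$lobe == at$lobe[1])[1:2] - 1L
  sel <- rep(FALSE, n_edges(20))
  sel[edge_flat_index(same[1], same[2], 20) + 1L] <- TRUE
  s1 <- summarize_mask_by_atlas(edge_mask(sel, 20), at)
  expect_equal(s1$lobe[at$lobe[1], at$lobe[1]], 1L)
  expect_equal(sum(s1$lobe[upper.tri(s1$lobe, diag = TRUE)]), 1L)

  set.seed(19)
  sel <- runif(n_edges(20)) < 0.3
  sr <- summarize_mask_by_atlas(edge_mask(sel, 20), at)
  for (m in sr) {
    expect_equal(sum(m[upper.tri(m, diag = TRUE)]), sum(sel))
    expect_equal(m, t(m))
  }
})
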