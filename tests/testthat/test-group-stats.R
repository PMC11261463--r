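test_that("Bonferroni correction is monotone, capped and identity at m = 1", {
  expect_equal(bonferroni(0.01, 3), 0.03)
  expect_equal(bonferroni(0.5, 10), 1.0)
  expect_equal(bonferroni(0.2, 1), 0.2)
  p <- seq(0, 1, by = 0.1)
  expect_true(all(diff(bonferroni(p, 7)) >= 0))
  expect_true(all(bonferroni(p, 3) <= bonferroni(p, 5)))
  expect_true(all(bonferroni(p, 50) <= 1))
  expect_error(bonferroni(0.1, 0), "m")
  expect_error(bonferroni(1.2, 2), "p_raw")
})

test_that("pooled t from summaries matches the closed form and is antisymmetric", {
  r <- t_test_from_summary(1, 1, 10, 0, 1, 10)
  expect_equal(r$t, sqrt(5), tolerance = 1e-12)  # delta / (s_p sqrt(2/10))
  expect_equal(r$df, 18)
  r0 <- t_test_from_summary(5, 2, 8, 5, 3, 9)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  swap <- t_test_from_summary(0, 1, 10, 1, 1, 10)
  expect_equal(swap$t, -r$t)
  expect_equal(swap$p, r$p)
  # oracle: matches t.test on raw data whose summaries are exact
  set.seed(31)
  a <- rnorm(12); b <- rnorm(15, 1)
  ref <- t.test(a, b, var.equal = TRUE)
  got <- t_test_from_summary(mean(a), sd(a), 12, mean(b), sd(b), 15)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
})

test_that("summary-statistic ANOVA equals a raw-data one-way ANOVA", {
  set.seed(32)
  g <- list(rnorm(9, 0), rnorm(14, 0.8), rnorm(11, -0.3))
  res <- anova_oneway_from_summary(sapply(g, mean), sapply(g, sd),
                                   lengths(g))
  raw <- anova(aov(y ~ grp, data.frame(
    y = unlist(g), grp = factor(rep(1:3, lengths(g))))))
  expect_equal(res$F, raw$`F value`[1], tolerance = 1e-10)
  expect_equal(res$p, raw$`Pr(>F)`[1], tolerance = 1e-10)
  expect_equal(res$df_between, 2)
  expect_equal(res$df_within, 31)
  expect_equal(anova_oneway_from_summary(c(1, 1), c(1, 1), c(5, 5))$F, 0)
  expect_error(anova_oneway_from_summary(c(1, 2), c(0, 0), c(5, 5)),
               "within-group")
})

test_that("chi-square independence matches the direct O/E loop", {
  set.seed(33)
  tab <- matrix(rpois(6, 20) + 1, 2, 3)
  res <- chi_square_independence(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$chisq, sum((tab - E)^2 / E), tolerance = 1e-12)
  expect_equal(res$df, 2)
  # table equal to its expected counts
  exact <- outer(c(10, 20), c(3, 7)) / 10
  expect_equal(chi_square_independence(exact)$chisq, 0, tolerance = 1e-12)
  expect_error(chi_square_independence(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("partial correlation reduces, forces and matches the recursion oracle", {
  set.seed(34)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(partial_correlation(x, y)$r_partial, cor(x, y),
               tolerance = 1e-12)
  z <- rnorm(20)
  forced <- partial_correlation(x, x + z, matrix(z, ncol = 1))
  expect_equal(abs(forced$r_partial), 1, tolerance = 1e-10)

  # 12-point fixture, 2 covariates: second-order recursion formula
  set.seed(35)
  n <- 12
  z1 <- rnorm(n); z2 <- rnorm(n)
  xf <- 0.5 * z1 + rnorm(n); yf <- -0.3 * z2 + rnorm(n)
  pc1 <- function(rxy, rxz, ryz) (rxy - rxz * ryz) /
    sqrt((1 - rxz^2) * (1 - ryz^2))
  r_xy.1 <- pc1(cor(xf, yf), cor(xf, z1), cor(yf, z1))
  r_x2.1 <- pc1(cor(xf, z2), cor(xf, z1), cor(z2, z1))
  r_y2.1 <- pc1(cor(yf, z2), cor(yf, z1), cor(z2, z1))
  oracle <- pc1(r_xy.1, r_x2.1, r_y2.1)
  got <- partial_correlation(xf, yf, cbind(z1, z2))
  expect_equal(got$r_partial, oracle, tolerance = 1e-10)
  expect_equal(got$df, 8)

  expect_error(partial_correlation(xf, yf, cbind(z1, z1)), "rank")
  expect_error(partial_correlation(z1, yf, cbind(z1, z2)), "constant")
})

test_that("independent covariates leave a planted correlation unchanged", {
  set.seed(36)
  diffs <- vapply(1:200, function(i) {
    n <- 50
    lat <- rnorm(n)
    x <- lat + rnorm(n)
    y <- lat + rnorm(n)
    z <- cbind(rnorm(n), rnorm(n))
    partial_correlation(x, y, z)$r_partial - cor(x, y)
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.02)
})

test_that("seed-FC comparison tests each seed-target pair once, sorted by p", {
  co <- generate_cohort(small_spec(seed = 21))
  pat <- cohort_patients(co)
  sf <- seed_fc_compare(pat, seeds = c(5, 15))
  # 2 * (n-1) minus the duplicate seed-seed pair
  expect_equal(nrow(sf), 2 * 29 - 1)
  expect_equal(unique(sf$m), nrow(sf))
  expect_true(all(diff(sf$p_raw) >= 0))
  expect_equal(sf$p_bonf, pmin(1, sf$p_raw * sf$m))
  expect_equal(unique(sf$df), 20)
  # identical group data (equal sizes, FC copied): t = 0, p = 1 everywhere
  co2 <- co
  mel_ids <- co2$subjects$id[co2$subjects$group == "melancholic"][1:10]
  nm_ids <- co2$subjects$id[co2$subjects$group == "non_melancholic"][1:10]
  keep <- c(mel_ids, nm_ids)
  co2$subjects <- co2$subjects[co2$subjects$id %in% keep, ]
  co2$fc <- co2$fc[keep]
  for (k in 1:10) co2$fc[[nm_ids[k]]] <- co2$fc[[mel_ids[k]]]
  sf2 <- seed_fc_compare(co2, seeds = 5)
  expect_true(all(abs(sf2$t) < 1e-12))
  expect_true(all(sf2$p_raw > 1 - 1e-9))
  expect_error(seed_fc_compare(pat, seeds = 400), "range")
})
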