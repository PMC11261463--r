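test_that("generation is seed-deterministic and seed-sensitive", {
  a <- generate_cohort(small_spec(seed = 42))
  b <- generate_cohort(small_spec(seed = 42))
  expect_identical(a, b)
  c <- generate_cohort(small_spec(seed = 43))
  expect_false(identical(a$fc, c$fc))
  expect_identical(a$subjects$id, c$subjects$id)
})

test_that("default spec yields the three study groups with 246-node FC", {
  co <- generate_cohort(cohort_spec(seed = 1))
  tab <- table(co$subjects$group)
  expect_equal(as.vector(tab[c("melancholic", "non_melancholic", "control")]),
               c(31L, 28L, 32L))
  expect_equal(dim(co$fc[[1]]), c(246L, 246L))
  expect_silent(assert_fc(co$fc[[sample(91, 1)]], tol = 1e-8))
})

test_that("invalid specs are rejected with the offending field named", {
  expect_error(cohort_spec(group_sizes = c(melancholic = 1,
                                           non_melancholic = 5,
                                           control = 5)),
               "group_sizes")
  expect_error(cohort_spec(edge_behavior_r = 1), "edge_behavior_r")
  expect_error(cohort_spec(n_nodes = 100), "planted_positive_edges")
  expect_error(small_spec(subtype_diff_edge = c(4, 4)), "subtype_diff_edge")
  bad <- rbind(c(1L, 2L), c(2L, 1L))
  expect_error(small_spec(planted_positive_edges = bad), "duplicate")
})

test_that("planted edges realize the target edge-behavior correlation", {
  flat <- default_planted_flat()
  frac <- vapply(1:50, function(s) {
    co <- generate_cohort(cohort_spec(seed = s))
    pat <- cohort_patients(co)
    r <- cor(fc_edge_matrix(pat)[, flat],
             pat$subjects$teps_abstract_consummatory)
    mean(r >= 0.2 & r <= 0.75)
  }, numeric(1))
  expect_gte(mean(frac), 0.9)
})

test_that("with no subtype effect the patient groups match on planted edges", {
  flat <- default_planted_flat()
  d <- vapply(1:100, function(s) {
    co <- generate_cohort(cohort_spec(subtype_diff_d = 0, seed = s))
    X <- fc_edge_matrix(co)[, flat]
    g <- co$subjects$group
    mean(abs(colMeans(X[g == "melancholic", , drop = FALSE]) -
               colMeans(X[g == "non_melancholic", , drop = FALSE])))
  }, numeric(1))
  expect_lt(mean(d), 0.05)
})

test_that("null mode matches pure noise in the max edge-behavior correlation", {
  flat <- default_planted_flat()
  gen <- vapply(1:60, function(s) {
    co <- generate_cohort(cohort_spec(edge_behavior_r = 0, seed = 400 + s))
    pat <- cohort_patients(co)
    max(abs(cor(fc_edge_matrix(pat)[, flat],
                pat$subjects$teps_abstract_consummatory)))
  }, numeric(1))
  set.seed(77)
  noise <- vapply(1:60, function(s)
    max(abs(cor(matrix(rnorm(59 * 26), 59, 26), rnorm(59)))), numeric(1))
  expect_lt(abs(mean(gen) - mean(noise)), 0.04)
})

test_that("behavior scores stay within instrument bounds", {
  co <- generate_cohort(cohort_spec(seed = 3))
  expect_true(all(co$subjects$hamd >= 0 & co$subjects$hamd <= 52))
  expect_true(all(co$subjects$teps_total >= 18 &
                    co$subjects$teps_total <= 108))
  expect_true(all(is.finite(as.matrix(
    co$subjects[, grep("teps|hamd", names(co$subjects))]))))
})

test_that("time-series mode approximately realizes the target FC", {
  co <- generate_cohort(small_spec(seed = 5), mode = "timeseries")
  sid <- co$subjects$id[1]
  fc_hat <- fc_from_timeseries(co$ts[[sid]])
  err <- abs(vectorize_edges(fc_hat) - vectorize_edges(co$fc[[sid]]))
  # sampling error of r at 200 time points is ~1/sqrt(200)
  expect_lt(median(err), 0.1)
  expect_lt(max(err), 0.35)
})

test_that("cohort directory round-trips and malformed input is rejected", {
  co <- generate_cohort(small_spec(seed = 11))
  keep <- co$subjects$id[1:3]
  co$subjects <- co$subjects[co$subjects$id %in% keep, ]
  co$fc <- co$fc[keep]
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$subjects, co$subjects, tolerance = 1e-12)
  expect_equal(back$fc, co$fc, tolerance = 1e-12)
  expect_equal(back$atlas, co$atlas)
  expect_equal(back$spec$edge_behavior_r, co$spec$edge_behavior_r)

  # missing covariate column
  sub <- read.table(file.path(dir, "subjects.tsv"), sep = "\t", header = TRUE)
  sub$fd <- NULL
  write.table(sub, file.path(dir, "subjects.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_cohort(dir), "fd")

  # asymmetric FC matrix
  write_cohort(co, dir)
  m <- as.matrix(read.table(file.path(dir, sprintf("fc_%s.tsv", keep[1])),
                            sep = "\t"))
  m[1, 2] <- m[1, 2] + 0.5
  write.table(m, file.path(dir, sprintf("fc_%s.tsv", keep[1])),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  expect_error(read_cohort(dir), "symmetric")
})

test_that("synthetic atlas has the documented vocabularies", {
  at <- synthetic_atlas()
  expect_equal(nrow(at), 246L)
  expect_equal(length(unique(at$lobe)), 7L)
  expect_equal(length(unique(at$gyrus)), 24L)
  expect_equal(length(unique(at$network)), 7L)
  expect_equal(sum(at$lobe == "Subcortical"), 36L)
  expect_silent(cpmnet:::assert_atlas(at, 246))
})
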