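#' Default planted predictive edges
#'
#' The default planted positive network: 26 edges concentrated on two hub
#' nodes, mirroring a predictive network whose two highest-degree nodes
#' (inferior temporal and parahippocampal analogs, 9 and 7 incident edges)
#' carry most of the signal, with the remaining 10 edges scattered over
#' distinct low-degree nodes. Node indices are 0-based positions in
#' [synthetic_atlas()].
#'
#' @return integer matrix with columns `i`, `j` (0-based, `i < j`).
#' @export
default_planted_edges <- function() {
  hub1 <- 89L   # ITG right-hemisphere analog
  hub2 <- 109L  # PhG right-hemisphere analog
  p1 <- c(69L, 71L, 73L, 81L, 88L, 100L, 121L, 135L, 163L)
  p2 <- c(1L, 108L, 134L, 146L, 147L, 174L, 175L)
  extra <- rbind(
    c(2L, 30L), c(15L, 55L), c(40L, 128L), c(60L, 150L), c(75L, 190L),
    c(83L, 200L), c(105L, 137L), c(120L, 176L), c(156L, 220L), c(165L, 235L)
  )
  e <- rbind(cbind(rep(hub1, length(p1)), p1),
             cbind(rep(hub2, length(p2)), p2),
             extra)
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  colnames(e) <- c("i", "j")
  e
}

# Table of per-group behavioral score distributions (mean, SD) and the
# truncation bounds of each instrument. Groups: melancholic (mel),
# non-melancholic (nonmel) MDD, healthy controls (hc). TEPS: lower score =
# more severe anhedonia; HAMD: higher = more severe depression.
default_behavior_table <- function() {
  tab <- rbind(
    hamd                         = c(21.77, 3.79, 21.00, 3.14, 0.94, 0.95, 0, 52),
    teps_anticipatory            = c(26.30, 7.83, 33.71, 5.91, 35.13, 6.11, 10, 60),
    teps_abstract_anticipatory   = c(13.17, 4.71, 17.04, 3.85, 19.94, 2.70, 6, 36),
    teps_contextual_anticipatory = c(13.13, 3.90, 16.68, 3.64, 15.19, 4.31, 4, 24),
    teps_consummatory            = c(32.00, 7.34, 35.75, 7.12, 42.53, 6.63, 8, 48),
    teps_abstract_consummatory   = c(20.20, 5.12, 22.39, 5.28, 26.78, 4.23, 5, 36),
    teps_contextual_consummatory = c(11.80, 3.18, 13.36, 3.27, 15.75, 3.65, 4, 24),
    teps_total                   = c(58.30, 13.95, 69.46, 11.16, 77.66, 11.60, 18, 108)
  )
  colnames(tab) <- c("mel_mean", "mel_sd", "nonmel_mean", "nonmel_sd",
                     "hc_mean", "hc_sd", "lo", "hi")
  tab
}

default_covariate_table <- function() {
  tab <- rbind(
    age              = c(28.65, 5.30, 32.04, 8.18, 29.59, 5.00, 16, 70),
    education        = c(15.16, 3.195, 12.54, 3.00, 14.59, 2.82, 0, 25),
    illness_duration = c(6.75, 4.26, 5.96, 4.64, 0.00, 0.00, 0, 360),
    fd               = c(0.05, 0.03, 0.04, 0.02, 0.05, 0.02, 0.005, 0.5)
  )
  colnames(tab) <- c("mel_mean", "mel_sd", "nonmel_mean", "nonmel_sd",
                     "hc_mean", "hc_sd", "lo", "hi")
  tab
}

#' Specification of a synthetic cohort
#'
#' Defines the statistical structure of a simulated three-group study:
#' group sizes, behavioral score distributions, nuisance covariates, a
#' planted set of behavior-linked positive FC edges concentrated on two
#' hub nodes, and one edge carrying a standardized mean difference between
#' the two patient subtypes.
#'
#' Defaults emulate the study design the package targets: 31 melancholic
#' and 28 non-melancholic depressed patients plus 32 controls, a 246-node
#' parcellation, 26 planted edges whose values correlate with the abstract
#' consummatory pleasure score across patients, and a subtype-difference
#' edge between the parahippocampal-analog hub and a cingulate-analog node
#' (melancholic mean shifted downward).
#'
#' @param n_nodes number of atlas nodes (default 246).
#' @param group_sizes named counts for `melancholic`, `non_melancholic`,
#'   `control` (defaults 31/28/32).
#' @param behavior matrix of per-group means/SDs and bounds per score
#'   (rows = scores; see `cpmnet:::default_behavior_table`).
#' @param covariates matrix like `behavior` for age (years), education
#'   (years), illness_duration (months; fixed 0 for controls), fd
#'   (framewise displacement).
#' @param sex_male_counts males per group (defaults 10/10/15).
#' @param planted_positive_edges integer matrix (`i`, `j`; 0-based) of
#'   behavior-linked edges; default [default_planted_edges()].
#' @param behavior_target name of the score the planted edges track
#'   (default `"teps_abstract_consummatory"`).
#' @param edge_behavior_r target Pearson correlation between each planted
#'   edge and the target score across patients (default 0.5; |r| < 1).
#' @param subtype_diff_edge node pair (0-based) carrying the subtype
#'   contrast (default c(109, 174), the PhG-analog hub to a CG-analog).
#' @param subtype_diff_d standardized mean difference on that edge,
#'   melancholic minus non-melancholic (default -1.0: melancholic lower).
#' @param fc_mean mean of the background edge-value distribution
#'   (default 0.2, a typical resting-state FC level).
#' @param fc_between_sd SD of per-edge population means around `fc_mean`
#'   (default 0.1).
#' @param noise_sd residual subject-level FC noise scale (default 0.15).
#' @param n_timepoints time points for time-series-level generation
#'   (default 200 volumes).
#' @param seed RNG seed (default 1).
#' @return object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_nodes = 246,
                        group_sizes = c(melancholic = 31,
                                        non_melancholic = 28,
                                        control = 32),
                        behavior = default_behavior_table(),
                        covariates = default_covariate_table(),
                        sex_male_counts = c(melancholic = 10,
                                            non_melancholic = 10,
                                            control = 15),
                        planted_positive_edges = default_planted_edges(),
                        behavior_target = "teps_abstract_consummatory",
                        edge_behavior_r = 0.5,
                        subtype_diff_edge = c(109L, 174L),
                        subtype_diff_d = -1.0,
                        fc_mean = 0.2,
                        fc_between_sd = 0.1,
                        noise_sd = 0.15,
                        n_timepoints = 200,
                        seed = 1) {
  spec <- structure(
    list(n_nodes = as.integer(n_nodes),
         group_sizes = group_sizes,
         behavior = behavior,
         covariates = covariates,
         sex_male_counts = sex_male_counts,
         planted_positive_edges = planted_positive_edges,
         behavior_target = behavior_target,
         edge_behavior_r = edge_behavior_r,
         subtype_diff_edge = as.integer(subtype_diff_edge),
         subtype_diff_d = subtype_diff_d,
         fc_mean = fc_mean,
         fc_between_sd = fc_between_sd,
         noise_sd = noise_sd,
         n_timepoints = as.integer(n_timepoints),
         seed = as.integer(seed)),
    class = "cohort_spec")
  validate_cohort_spec(spec)
}

validate_cohort_spec <- function(spec) {
  gs <- spec$group_sizes
  need <- c("melancholic", "non_melancholic", "control")
  if (!all(need %in% names(gs)))
    stop("group_sizes: must name melancholic, non_melancholic and control")
  if (any(gs < 2)) stop("group_sizes: all group sizes must be >= 2")
  pe <- spec$planted_positive_edges
  if (!is.null(pe) && nrow(pe)) {
    if (any(pe[, 1] == pe[, 2]))
      stop("planted_positive_edges: endpoints must be distinct")
    key <- paste(pmin(pe[, 1], pe[, 2]), pmax(pe[, 1], pe[, 2]))
    if (anyDuplicated(key))
      stop("planted_positive_edges: duplicate edges")
    if (max(pe) >= spec$n_nodes || min(pe) < 0)
      stop("planted_positive_edges: node index out of range for n_nodes")
  }
  if (abs(spec$edge_behavior_r) >= 1)
    stop("edge_behavior_r: |r| must be < 1")
  if (any(spec$behavior[, c("mel_sd", "nonmel_sd", "hc_sd")] <= 0))
    stop("behavior: SDs must be > 0")
  if (!spec$behavior_target %in% rownames(spec$behavior))
    stop("behavior_target: not a row of the behavior table")
  sde <- spec$subtype_diff_edge
  if (length(sde) != 2 || sde[1] == sde[2] ||
      any(sde < 0) || any(sde >= spec$n_nodes))
    stop("subtype_diff_edge: must be two distinct in-range node indices")
  if (spec$noise_sd <= 0) stop("noise_sd: must be > 0")
  sm <- spec$sex_male_counts[names(gs)]
  if (any(is.na(sm)) || any(sm < 0) || any(sm > gs))
    stop("sex_male_counts: must lie in [0, group size] for every group")
  spec
}

# Truncated-Gaussian draws by resampling within [lo, hi].
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  for (it in 1:100) {
    out <- x < lo | x > hi
    if (!any(out)) break
    x[out] <- stats::rnorm(sum(out), mean, sd)
  }
  pmin(hi, pmax(lo, x))
}

#' Generate a synthetic cohort
#'
#' Simulates subjects, behavioral scores, covariates and per-subject FC
#' matrices under the edge-level model: each edge has a population mean
#' drawn once per cohort around `fc_mean`; a subject's edge value adds
#' `noise_sd`-scaled Gaussian noise. For patients, each planted edge mixes
#' in the standardized target behavior score so that its correlation with
#' the score across patients is approximately `edge_behavior_r`; the
#' subtype-difference edge additionally shifts the melancholic group by
#' `subtype_diff_d` noise-SD units. Control FC is behavior-independent.
#' All edge values are clipped to (-1, 1); matrices are symmetric with
#' unit diagonal but not forced positive definite (downstream analyses
#' consume edge values only).
#'
#' @param spec a [cohort_spec()].
#' @param mode `"fc"` (default) generates FC matrices directly at the edge
#'   level; `"timeseries"` additionally realizes each subject's matrix as
#'   `n_timepoints` node signals whose empirical Pearson correlation
#'   approximates the target matrix (nearest positive-definite target via
#'   eigenvalue clamping).
#' @return object of class `cpm_cohort`: list with `subjects` (data.frame:
#'   id, group, behavior scores, sex, covariates), `fc` (named list of FC
#'   matrices) or `ts` (named list of node-by-time matrices), `atlas`,
#'   `n_nodes` and the generating `spec`.
#' @examples
#' co <- generate_cohort(cohort_spec(n_nodes = 20, seed = 7))
#' table(co$subjects$group)
#' @export
generate_cohort <- function(spec = cohort_spec(), mode = c("fc", "timeseries")) {
  mode <- match.arg(mode)
  validate_cohort_spec(spec)
  set.seed(spec$seed)

  gs <- spec$group_sizes[c("melancholic", "non_melancholic", "control")]
  n_total <- sum(gs)
  group <- rep(names(gs), gs)
  id <- sprintf("S%03d", seq_len(n_total))

  # behavioral scores, truncated Gaussian per group
  grp_col <- c(melancholic = "mel", non_melancholic = "nonmel", control = "hc")
  bt <- spec$behavior
  beh <- sapply(rownames(bt), function(sc) {
    x <- numeric(n_total)
    for (g in names(gs)) {
      pick <- group == g
      pre <- grp_col[[g]]
      x[pick] <- rnorm_trunc(sum(pick), bt[sc, paste0(pre, "_mean")],
                             bt[sc, paste0(pre, "_sd")],
                             bt[sc, "lo"], bt[sc, "hi"])
    }
    x
  })
  ct <- spec$covariates
  cov <- sapply(rownames(ct), function(sc) {
    x <- numeric(n_total)
    for (g in names(gs)) {
      pick <- group == g
      pre <- grp_col[[g]]
      x[pick] <- rnorm_trunc(sum(pick), ct[sc, paste0(pre, "_mean")],
                             ct[sc, paste0(pre, "_sd")],
                             ct[sc, "lo"], ct[sc, "hi"])
    }
    x
  })
  sex <- unlist(lapply(names(gs), function(g) {
    n <- gs[[g]]; m <- spec$sex_male_counts[[g]]
    sample(rep(c("male", "female"), c(m, n - m)))
  }))

  subjects <- data.frame(id = id, group = group, sex = sex,
                         beh, cov, stringsAsFactors = FALSE)

  # edge-level FC
  n <- spec$n_nodes
  E <- n_edges(n)
  base <- stats::rnorm(E, spec$fc_mean, spec$fc_between_sd)
  patient <- group != "control"
  y <- subjects[[spec$behavior_target]]
  z <- numeric(n_total)
  z[patient] <- as.numeric(scale(y[patient]))

  planted_flat <- if (nrow(spec$planted_positive_edges))
    edge_flat_index(spec$planted_positive_edges[, 1],
                    spec$planted_positive_edges[, 2], n) + 1L
  else integer(0)
  sub_flat <- edge_flat_index(spec$subtype_diff_edge[1],
                              spec$subtype_diff_edge[2], n) + 1L
  rho <- spec$edge_behavior_r

  edge_mat <- matrix(stats::rnorm(n_total * E, 0, 1), n_total, E)
  # mix standardized behavior into planted edges for patients only
  if (length(planted_flat) && rho != 0) {
    edge_mat[patient, planted_flat] <-
      rho * z[patient] +
      sqrt(1 - rho^2) * edge_mat[patient, planted_flat]
  }
  edge_mat <- edge_mat * spec$noise_sd + matrix(base, n_total, E, byrow = TRUE)
  if (spec$subtype_diff_d != 0) {
    mel <- group == "melancholic"
    edge_mat[mel, sub_flat] <- edge_mat[mel, sub_flat] +
      spec$subtype_diff_d * spec$noise_sd
  }
  edge_mat[edge_mat > 0.999] <- 0.999
  edge_mat[edge_mat < -0.999] <- -0.999

  fc <- lapply(seq_len(n_total), function(s) devectorize_edges(edge_mat[s, ], n))
  names(fc) <- id

  cohort <- structure(
    list(subjects = subjects, fc = fc, ts = NULL,
         atlas = synthetic_atlas(n), n_nodes = n, spec = spec),
    class = "cpm_cohort")

  if (mode == "timeseries") {
    cohort$ts <- lapply(fc, function(m)
      realize_timeseries(m, spec$n_timepoints))
    names(cohort$ts) <- id
  }
  cohort
}

# Draw node-by-time signals whose sample correlation approximates `target`:
# clamp eigenvalues to make the target positive definite, then colour white
# noise with its Cholesky factor.
realize_timeseries <- function(target, n_timepoints) {
  eg <- eigen(target, symmetric = TRUE)
  lam <- pmax(eg$values, 1e-6)
  pd <- eg$vectors %*% (lam * t(eg$vectors))
  d <- sqrt(diag(pd))
  pd <- pd / tcrossprod(d)
  ch <- chol(pd)
  z <- matrix(stats::rnorm(n_timepoints * nrow(target)),
              n_timepoints, nrow(target))
  t(z %*% ch)
}

#' @export
print.cpm_cohort <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat(sprintf("synthetic cohort: %d subjects (%s), %d-node FC\n",
              nrow(x$subjects),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              x$n_nodes))
  invisible(x)
}

#' Subset the patient groups of a cohort
#'
#' @param cohort a `cpm_cohort`.
#' @param groups group labels to keep (default the two patient groups).
#' @return a `cpm_cohort` restricted to those subjects.
#' @export
cohort_patients <- function(cohort,
                            groups = c("melancholic", "non_melancholic")) {
  keep <- cohort$subjects$group %in% groups
  cohort$subjects <- cohort$subjects[keep, , drop = FALSE]
  rownames(cohort$subjects) <- NULL
  cohort$fc <- cohort$fc[cohort$subjects$id]
  if (!is.null(cohort$ts)) cohort$ts <- cohort$ts[cohort$subjects$id]
  cohort
}

#' Stack a cohort's FC matrices into a subjects-by-edges matrix
#'
#' Rows follow `cohort$subjects$id`; columns are the canonical flat edge
#' order of [edge_pairs()]. Time-series-only cohorts are converted with
#' [fc_from_timeseries()] first.
#'
#' @param cohort a `cpm_cohort`.
#' @return numeric matrix, subjects x edges, with subject ids as rownames.
#' @export
fc_edge_matrix <- function(cohort) {
  ids <- cohort$subjects$id
  get_fc <- function(sid) {
    if (!is.null(cohort$fc) && !is.null(cohort$fc[[sid]]))
      cohort$fc[[sid]]
    else if (!is.null(cohort$ts) && !is.null(cohort$ts[[sid]]))
      fc_from_timeseries(cohort$ts[[sid]])
    else stop("subject ", sid, " has neither fc nor time series")
  }
  out <- t(vapply(ids, function(sid) vectorize_edges(get_fc(sid), check = FALSE),
                  numeric(n_edges(cohort$n_nodes))))
  rownames(out) <- ids
  out
}
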