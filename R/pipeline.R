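#' Run the full analysis pipeline on a cohort
#'
#' Wires the stages together in dependency order: CPM on the patient
#' groups, hub identification from the consensus network, seed-based FC
#' subtype comparison using the hubs as seeds, covariate-adjusted partial
#' correlation of the top differing edge against the consummatory and
#' total pleasure scores, and RBF-SVM subtype classification on that
#' edge's FC value. Writes plain-text TSV/JSON outputs plus a
#' `manifest.json` capturing config and seeds, so a rerun with the same
#' manifest reproduces every number.
#'
#' @param cohort a `cpm_cohort` or a cohort directory (see
#'   [read_cohort()]).
#' @param out_dir output directory (created if needed); NULL skips file
#'   output.
#' @param config a [cpm_config()].
#' @param hub_threshold minimum consensus degree for a hub (default 5).
#' @param svm_seed seed for SVM fold shuffling (default `config$seed`).
#' @param svm_k SVM cross-validation folds (default 5).
#' @param classify_edge optional 0-based node pair overriding the
#'   seed-analysis top edge as the classification feature.
#' @param partial_scores clinical scores for the partial-correlation
#'   stage.
#' @param partial_covariates covariate columns to adjust for.
#' @return list with per-stage results: `cpm`, `hubs`, `seed_fc`,
#'   `partial`, `svm`, and `manifest`.
#' @export
run_pipeline <- function(cohort,
                         out_dir = NULL,
                         config = cpm_config(),
                         hub_threshold = 5,
                         svm_seed = config$seed,
                         svm_k = 5,
                         classify_edge = NULL,
                         partial_scores = c("teps_consummatory", "teps_total"),
                         partial_covariates = c("age", "education",
                                                "illness_duration", "fd")) {
  if (is.character(cohort)) {
    if (!dir.exists(cohort)) stop("cohort directory not found: ", cohort)
    cohort <- read_cohort(cohort)
  }
  if (!inherits(cohort, "cpm_cohort")) stop("cohort must be a cpm_cohort or directory")
  patients <- cohort_patients(cohort)

  message("stage cpm: ", config$n_permutations, " permutations, cv = ", config$cv)
  cpm <- permutation_test(patients, config)
  hubs <- consensus_and_degree(cpm$fold_masks, n_nodes = cpm$n_nodes,
                               hub_threshold = hub_threshold)
  seeds <- hubs$degrees$node[hubs$degrees$is_hub]
  if (!length(seeds)) {
    message("stage groupdiff: no hub reached degree ", hub_threshold,
            "; using the top-degree node as seed")
    seeds <- hubs$degrees$node[1]
  }

  message("stage groupdiff: seeds ", paste(seeds, collapse = ", "))
  seed_fc <- seed_fc_compare(patients, seeds)

  top_edge <- if (is.null(classify_edge))
    c(seed_fc$seed[1], seed_fc$target[1]) else as.integer(classify_edge)
  flat <- edge_flat_index(top_edge[1], top_edge[2], cohort$n_nodes) + 1L
  Xp <- fc_edge_matrix(patients)
  edge_vals <- Xp[, flat]

  message("stage partialcorr: edge ", top_edge[1], "-", top_edge[2])
  covm <- as.matrix(patients$subjects[, partial_covariates])
  partial <- lapply(partial_scores, function(sc)
    partial_correlation(edge_vals, patients$subjects[[sc]], covm,
                        x_name = sprintf("fc_%d_%d", top_edge[1], top_edge[2]),
                        y_name = sc))
  names(partial) <- partial_scores
  praw <- vapply(partial, function(p) p$p_raw, numeric(1))
  padj <- bonferroni(praw, length(praw))

  message("stage classify: RBF-SVM on edge ", top_edge[1], "-", top_edge[2])
  svm <- grid_search_cv(matrix(edge_vals, ncol = 1,
                               dimnames = list(patients$subjects$id, NULL)),
                        patients$subjects$group, k = svm_k, seed = svm_seed)

  manifest <- list(
    package_version = as.character(utils::packageVersion("cpmnet")),
    n_subjects = nrow(cohort$subjects),
    n_patients = nrow(patients$subjects),
    n_nodes = cohort$n_nodes,
    cpm_config = unclass(config),
    hub_threshold = hub_threshold,
    seeds = seeds,
    classify_edge = top_edge,
    svm = list(k = svm_k, seed = svm_seed),
    partial = list(scores = partial_scores, covariates = partial_covariates)
  )
  res <- list(cpm = cpm, hubs = hubs, seed_fc = seed_fc,
              partial = partial, partial_p_bonf = padj,
              svm = svm, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wt <- function(x, f) utils::write.table(x, file.path(out_dir, f),
                                          sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  cpm <- res$cpm
  wt(data.frame(id = names(cpm$predictions),
                observed = as.numeric(cpm$observed),
                predicted = as.numeric(cpm$predictions)),
     "predictions.tsv")
  ep <- mask_pairs(cpm$consensus_mask)
  wt(data.frame(node_i = ep[, 1], node_j = ep[, 2]), "edges_positive.tsv")
  wt(res$hubs$degrees, "degrees.tsv")
  wt(data.frame(null_r = cpm$null_distribution), "null_r.tsv")
  wt(as.data.frame(res$seed_fc), "seed_fc.tsv")
  wt(data.frame(score = names(res$partial),
                r_partial = vapply(res$partial, `[[`, numeric(1), "r_partial"),
                df = vapply(res$partial, `[[`, numeric(1), "df"),
                p_raw = vapply(res$partial, `[[`, numeric(1), "p_raw"),
                p_bonf = as.numeric(res$partial_p_bonf)),
     "partialcorr.tsv")
  svm <- res$svm
  wt(data.frame(id = names(svm$fold_assignments),
                fold = as.integer(svm$fold_assignments),
                predicted = svm$predictions),
     "folds.tsv")
  jsonlite::write_json(
    list(r_obs = cpm$r_obs, mse = cpm$mse, p_perm = cpm$p_perm,
         n_consensus_edges = sum(cpm$consensus_mask$edges),
         config = res$manifest$cpm_config),
    file.path(out_dir, "result.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(tp = svm$confusion$tp, fn = svm$confusion$fn,
         tn = svm$confusion$tn, fp = svm$confusion$fp,
         sensitivity = svm$sensitivity, specificity = svm$specificity,
         accuracy = svm$accuracy,
         se_accuracy = svm$se_accuracy,
         se_sensitivity = svm$se_sensitivity,
         se_specificity = svm$se_specificity,
         best_c = svm$best_c, best_g = svm$best_g, seed = svm$seed,
         se_definition = "sd of per-fold metric / sqrt(k)"),
    file.path(out_dir, "classification.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
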