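#!/usr/bin/env Rscript
# Stage 4: subtype classification from the discriminating edge.
#
# Classifies melancholic vs non-melancholic patients from the FC value of
# the subtype-difference edge with an RBF-kernel SVM: features scaled to
# [-1, 1] per training fold, c and g grid-searched over powers of two,
# stratified five-fold cross-validation, pooled confusion matrix with
# per-fold standard errors.
# Writes results/04_classification.json and 04_folds.tsv.

suppressPackageStartupMessages(library(cpmnet))
SEED <- 1
dir.create("results", showWarnings = FALSE)

spec <- cohort_spec(seed = SEED)
cohort <- generate_cohort(spec)
patients <- cohort_patients(cohort)

sde <- spec$subtype_diff_edge
flat <- edge_flat_index(sde[1], sde[2], cohort$n_nodes) + 1L
feat <- matrix(fc_edge_matrix(patients)[, flat], ncol = 1,
               dimnames = list(patients$subjects$id, "subtype_edge_fc"))

svm <- grid_search_cv(feat, patients$subjects$group, k = 5, seed = SEED)
print(svm)

write.table(data.frame(id = names(svm$fold_assignments),
                       fold = as.integer(svm$fold_assignments),
                       truth = patients$subjects$group,
                       predicted = svm$predictions),
            "results/04_folds.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(
  list(edge = sde, tp = svm$confusion$tp, fn = svm$confusion$fn,
       tn = svm$confusion$tn, fp = svm$confusion$fp,
       sensitivity_pct = 100 * svm$sensitivity,
       specificity_pct = 100 * svm$specificity,
       accuracy_pct = 100 * svm$accuracy,
       se_accuracy = svm$se_accuracy, se_sensitivity = svm$se_sensitivity,
       se_specificity = svm$se_specificity,
       best_c = svm$best_c, best_g = svm$best_g, seed = SEED),
  "results/04_classification.json", auto_unbox = TRUE, digits = NA)
message("classification results written to results/04_*")
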