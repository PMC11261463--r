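#!/usr/bin/env Rscript
# Stage 2: connectome-based prediction of anhedonia severity.
#
# Runs CPM with leave-one-out cross-validation on the 59 patients:
# edge selection at p < 1e-4 on each training fold, network-strength
# scoring, a univariate linear model, and a 1000-iteration permutation
# test. Identifies the consensus positive network and its hub nodes, and
# summarises the selected edges by atlas lobe.
# Writes results/02_*.

suppressPackageStartupMessages(library(cpmnet))
SEED <- 1
dir.create("results", showWarnings = FALSE)

cohort <- generate_cohort(cohort_spec(seed = SEED))
patients <- cohort_patients(cohort)

cfg <- cpm_config(n_permutations = 1000, seed = SEED)
res <- permutation_test(patients, cfg)
print(res)

write.table(data.frame(id = names(res$predictions),
                       observed = as.numeric(res$observed),
                       predicted = as.numeric(res$predictions)),
            "results/02_predictions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(null_r = res$null_distribution),
            "results/02_null_r.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

hubs <- consensus_and_degree(res$fold_masks, n_nodes = cohort$n_nodes)
ep <- mask_pairs(hubs$consensus)
write.table(data.frame(node_i = ep[, 1], node_j = ep[, 2]),
            "results/02_consensus_edges.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(head(hubs$degrees, 20), "results/02_top_degrees.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

lobes <- summarize_mask_by_atlas(hubs$consensus, cohort$atlas)$lobe
write.table(cbind(lobe = rownames(lobes), as.data.frame(lobes)),
            "results/02_edges_by_lobe.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

jsonlite::write_json(
  list(r_obs = res$r_obs, mse = res$mse, p_perm = res$p_perm,
       n_consensus_edges = sum(hubs$consensus$edges),
       hub_nodes = hubs$degrees$node[hubs$degrees$is_hub],
       seed = SEED),
  "results/02_cpm_result.json", auto_unbox = TRUE, digits = NA)

message(sprintf(
  "CPM: r_obs = %.4f, MSE = %.4f, permutation p = %.4f; %d consensus edges; hubs: %s",
  res$r_obs, res$mse, res$p_perm, sum(hubs$consensus$edges),
  paste(hubs$degrees$node[hubs$degrees$is_hub], collapse = ", ")))
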