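# cpmnet

Connectome-based predictive modeling (CPM) of anhedonia severity from
functional-connectivity matrices, with depression-subtype follow-up
analyses: hub identification, seed-based FC group comparison,
covariate-adjusted partial correlation, and RBF-SVM subtype
classification. Written for researchers in psychiatric neuroimaging and
network neuroscience who want a tested, reproducible R implementation of
this workflow — and a seeded synthetic cohort generator so the whole
pipeline can be exercised and validated without access to clinical data.

## The method

Each subject contributes a symmetric node-by-node FC matrix (246-node
parcellation; edge = Pearson correlation of two regional fMRI time
series) and a behavioral score *y* (TEPS abstract consummatory pleasure;
lower = more severe anhedonia). CPM proceeds per leave-one-out fold:

1. correlate every edge with *y* on the training subjects; keep the
   positive network {e : r<sub>e</sub> > 0, p<sub>e</sub> < 10⁻⁴} with
   p from t = r√((n−2)/(1−r²));
2. score each subject by **network strength**, the sum of FC values over
   the selected edges;
3. fit *y* ~ strength by least squares on the training subjects and
   predict the held-out subject.

Performance is r<sub>obs</sub> = cor(observed, predicted) and the mean
squared error; significance comes from re-running the whole procedure on
permuted behavior vectors, p = (1 + #{r<sub>null</sub> ≥
r<sub>obs</sub>})/(1 + N). Nodes with ≥ 5 consensus-network edges are
hubs and become seeds for a pooled-variance t comparison of
melancholic vs non-melancholic patients (Bonferroni-corrected), and the
top edge feeds a partial correlation (covariates: age, education,
illness duration, framewise displacement) and an RBF-SVM classifier
(LIBSVM via e1071; features min-max scaled to [−1, 1] per training fold;
c and g grid-searched over powers of two; stratified 5-fold CV).

See `vignettes/cpm-methods.Rmd` for the full model description,
parameter rationale, and the synthetic generator's calibration.

## Worked example

```r
library(cpmnet)

cohort   <- generate_cohort(cohort_spec(seed = 1))   # 31/28/32 subjects
patients <- cohort_patients(cohort)

res <- permutation_test(patients, cpm_config(n_permutations = 1000, seed = 1))
print(res)
#> CPM (positive tail, loocv): r_obs = 0.8967, MSE = 6.0948 over 59 subjects; consensus network: 12 edges
#> permutation p = 0.0010 (1000 iterations)
```

The synthetic cohort plants 26 behavior-linked positive edges (each
correlating with the target score at r ≈ 0.5 across the 59 patients) on
two hub nodes. The run above recovers a 12-edge consensus network — all
12 planted, none spurious — predicts the held-out scores at
r<sub>obs</sub> = 0.90 (MSE 6.09, in squared points of the TEPS abstract
consummatory scale), and the permutation p of 0.001 is the smallest
value 1000 iterations can resolve. Downstream, the subtype-difference
edge supports classification of melancholic vs non-melancholic patients:

```r
spec <- cohort_spec(seed = 1)
edge <- spec$subtype_diff_edge                     # hub–cingulate-analog edge
flat <- edge_flat_index(edge[1], edge[2], 246) + 1
svm  <- grid_search_cv(matrix(fc_edge_matrix(patients)[, flat], ncol = 1),
                       patients$subjects$group, k = 5, seed = 1)
print(svm)
#> RBF-SVM 5-fold CV: accuracy 81.36%, sensitivity 77.42%, specificity 85.71% (c = 0.125, g = 8)
#> pooled confusion: tp=24 fn=7 tn=24 fp=4; SEs acc 0.034 / sens 0.064 / spec 0.064
```

The `analysis/` directory holds the same workflow as four numbered
narrative scripts (simulate → CPM → subtype FC comparison → SVM), each
writing its tables under `results/`.

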