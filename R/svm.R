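#' Min-max feature scaling to [-1, 1]
#'
#' Affine map sending the training minimum to -1 and maximum to +1,
#' fitted on training data only; held-out values mapped with the same
#' record may fall outside [-1, 1].
#'
#' @param train numeric vector/matrix of training feature values.
#' @param apply values to transform (default `train`).
#' @param record a previous scaling record, to reapply.
#' @return list: `scaled` values and the `record` (per-feature min/max).
#' @export
scale_features <- function(train = NULL, apply = train, record = NULL) {
  if (is.null(record)) {
    tr <- as.matrix(train)
    lo <- vapply(seq_len(ncol(tr)), function(c) min(tr[, c]), numeric(1))
    hi <- vapply(seq_len(ncol(tr)), function(c) max(tr[, c]), numeric(1))
    if (any(hi - lo == 0))
      stop("feature with zero range cannot be scaled")
    record <- list(lo = lo, hi = hi)
  }
  ap <- as.matrix(apply)
  sc <- sweep(sweep(ap, 2, record$lo, "-"), 2,
              (record$hi - record$lo) / 2, "/") - 1
  list(scaled = sc, record = record)
}

#' Confusion-matrix counts
#'
#' @param truth,predicted factors/labels; `positive` names the positive
#'   class (default `"melancholic"`).
#' @param positive the positive-class label.
#' @return list of class `confusion_matrix`: `tp`, `fn`, `tn`, `fp`.
#' @export
confusion_counts <- function(truth, predicted, positive = "melancholic") {
  truth_pos <- truth == positive
  pred_pos <- predicted == positive
  structure(list(tp = sum(truth_pos & pred_pos),
                 fn = sum(truth_pos & !pred_pos),
                 tn = sum(!truth_pos & !pred_pos),
                 fp = sum(!truth_pos & pred_pos)),
            class = "confusion_matrix")
}

#' Sensitivity, specificity and accuracy of a confusion matrix
#'
#' sensitivity = tp/(tp+fn), specificity = tn/(tn+fp),
#' accuracy = (tp+tn)/n; returned as proportions (multiply by 100 for the
#' two-decimal percentage form used in reports).
#'
#' @param cm a [confusion_counts()] result, or a list/vector with `tp`,
#'   `fn`, `tn`, `fp`.
#' @return list: `sensitivity`, `specificity`, `accuracy`.
#' @export
confusion_metrics <- function(cm) {
  tp <- cm$tp; fn <- cm$fn; tn <- cm$tn; fp <- cm$fp
  if (any(c(tp, fn, tn, fp) < 0)) stop("counts must be non-negative")
  if (tp + fn == 0) stop("no positive-class subjects: sensitivity undefined")
  if (tn + fp == 0) stop("no negative-class subjects: specificity undefined")
  list(sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       accuracy = (tp + tn) / (tp + fn + tn + fp))
}

# stratified fold assignment: shuffle within class, deal round-robin
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  offset <- 0L
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- (seq_along(idx) - 1L + offset) %% k + 1L
    offset <- offset + length(idx)
  }
  fold
}

#' RBF-SVM subtype classification with grid-searched c and g
#'
#' Discriminates two classes from FC feature(s) with a Gaussian
#' radial-basis-function support vector machine (LIBSVM via
#' \pkg{e1071}). For each (c, g) on the grid, runs stratified k-fold
#' cross-validation with min-max scaling to [-1, 1] fitted per training
#' fold; selects the pair maximizing mean CV accuracy (ties broken by
#' smallest c, then smallest g) and reports the pooled confusion matrix
#' and per-fold metric standard errors at the selected parameters.
#' Selection is non-nested (the grid is chosen on the same folds whose
#' metrics are reported), mirroring the standard LIBSVM workflow.
#'
#' @param features subjects-by-features numeric matrix (a single FC edge
#'   value is the typical one-column case).
#' @param labels class labels (both classes present).
#' @param c_grid,g_grid cost and kernel-width grids; defaults are the
#'   LIBSVM-convention powers of two, c in 2^(-5..15), g in 2^(-15..3),
#'   step 2 on the exponent.
#' @param k folds (default 5).
#' @param seed seed for fold shuffling.
#' @param positive positive-class label (default `"melancholic"`).
#' @return object of class `svm_cv_result`: `confusion` (pooled),
#'   `sensitivity`, `specificity`, `accuracy` (proportions),
#'   `se_accuracy`, `se_sensitivity`, `se_specificity` (SD of per-fold
#'   metric / sqrt(k)), `best_c`, `best_g`, `fold_assignments`,
#'   `cv_accuracy_grid`, `seed`.
#' @export
grid_search_cv <- function(features, labels,
                           c_grid = 2^seq(-5, 15, by = 2),
                           g_grid = 2^seq(-15, 3, by = 2),
                           k = 5, seed = 1, positive = "melancholic") {
  X <- as.matrix(features)
  labels <- as.character(labels)
  if (length(unique(labels)) != 2)
    stop("exactly two classes are required")
  if (!positive %in% labels) stop("positive class absent from labels")
  if (!length(c_grid) || !length(g_grid)) stop("empty parameter grid")
  n <- nrow(X)
  if (length(labels) != n) stop("labels length differs from feature rows")
  ids <- rownames(X)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
  fold <- stratified_folds(labels, k, seed)
  yf <- factor(labels, levels = c(positive, setdiff(unique(labels), positive)))

  # per-fold scaled train/test splits, shared across the whole grid
  splits <- lapply(seq_len(k), function(f) {
    te <- fold == f
    sc <- scale_features(X[!te, , drop = FALSE])
    list(te = te,
         xtr = sc$scaled,
         xte = scale_features(apply = X[te, , drop = FALSE],
                              record = sc$record)$scaled,
         ytr = yf[!te])
  })

  grid <- expand.grid(c = c_grid, g = g_grid, KEEP.OUT.ATTRS = FALSE)
  run_combo <- function(cost, gamma) {
    pred <- factor(rep(NA_character_, n), levels = levels(yf))
    for (sp in splits) {
      fit <- e1071::svm(sp$xtr, sp$ytr, kernel = "radial",
                        cost = cost, gamma = gamma, scale = FALSE)
      pred[sp$te] <- stats::predict(fit, sp$xte)
    }
    pred
  }
  acc <- numeric(nrow(grid))
  for (gidx in seq_len(nrow(grid))) {
    pred <- run_combo(grid$c[gidx], grid$g[gidx])
    acc[gidx] <- mean(pred == yf)
  }
  # ties: smallest c, then smallest g (grid is ordered c-fastest)
  ord <- order(-acc, grid$c, grid$g)
  best <- ord[1]
  best_pred <- run_combo(grid$c[best], grid$g[best])

  cm <- confusion_counts(yf, best_pred, positive)
  met <- confusion_metrics(cm)
  fold_metric <- function(fun) {
    vapply(seq_len(k), function(f) {
      te <- fold == f
      fun(confusion_counts(yf[te], best_pred[te], positive))
    }, numeric(1))
  }
  fm_acc <- fold_metric(function(c) (c$tp + c$tn) / (c$tp + c$tn + c$fp + c$fn))
  fm_sen <- fold_metric(function(c) if (c$tp + c$fn > 0) c$tp / (c$tp + c$fn) else NA_real_)
  fm_spe <- fold_metric(function(c) if (c$tn + c$fp > 0) c$tn / (c$tn + c$fp) else NA_real_)
  se <- function(v) stats::sd(v[!is.na(v)]) / sqrt(sum(!is.na(v)))

  structure(
    list(confusion = cm,
         sensitivity = met$sensitivity, specificity = met$specificity,
         accuracy = met$accuracy,
         se_accuracy = se(fm_acc), se_sensitivity = se(fm_sen),
         se_specificity = se(fm_spe),
         best_c = grid$c[best], best_g = grid$g[best],
         fold_assignments = stats::setNames(fold, ids),
         cv_accuracy_grid = cbind(grid, accuracy = acc),
         predictions = stats::setNames(as.character(best_pred), ids),
         positive = positive, k = k, seed = seed),
    class = "svm_cv_result")
}

#' @export
print.svm_cv_result <- function(x, ...) {
  cat(sprintf("RBF-SVM %d-fold CV: accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%% (c = %g, g = %g)\n",
              x$k, 100 * x$accuracy, 100 * x$sensitivity,
              100 * x$specificity, x$best_c, x$best_g))
  cat(sprintf("pooled confusion: tp=%d fn=%d tn=%d fp=%d; SEs acc %.3f / sens %.3f / spec %.3f\n",
              x$confusion$tp, x$confusion$fn, x$confusion$tn, x$confusion$fp,
              x$se_accuracy, x$se_sensitivity, x$se_specificity))
  invisible(x)
}
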