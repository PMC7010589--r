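# Classification of decomposed connectome features: gradient-boosted trees
# (xgboost) with Gini/gain-based importance, an SVR-style support-vector
# baseline, stratified k-fold cross-validation with fold-local
# decomposition fitting (no leakage), and the sigma/gamma sensitivity sweep.

default_gbt_params <- function() {
  list(max_depth = 3L, eta = 0.1, subsample = 0.8, nrounds = 200L)
}

#' Train a gradient-boosted tree classifier and extract feature importance
#'
#' Fits an xgboost binary classifier and returns gain-based importance
#' scores (split-quality improvement averaged over all trees), normalized
#' to sum to 1.
#'
#' @param features n x p numeric matrix.
#' @param labels Two-level factor or 0/1 vector; the second factor level
#'   (or 1) is the positive class.
#' @param params List overriding [default_gbt_params()] entries
#'   (`max_depth`, `eta`, `subsample`, `nrounds`).
#' @param seed Seed for the stochastic row subsampling.
#' @return List with `model` (xgb.Booster), `importance` (length-p vector
#'   summing to 1) and `predict(newx)` returning positive-class
#'   probabilities.
#' @export
train_boosted_trees <- function(features, labels, params = list(), seed = 1) {
  features <- as.matrix(features)
  y <- encode_labels(labels)
  if (length(unique(y)) < 2L) stopf("labels contain a single class")
  if (min(table(y)) < 2L) stopf("need at least 2 subjects per class")
  p <- utils::modifyList(default_gbt_params(), params)
  fn <- paste0("f", seq_len(ncol(features)))
  colnames(features) <- fn
  dtrain <- xgboost::xgb.DMatrix(features, label = y, nthread = 1L)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = p$max_depth,
                  eta = p$eta, subsample = p$subsample, nthread = 1L,
                  seed = as.integer(seed)),
    data = dtrain, nrounds = p$nrounds, verbose = 0L)
  imp <- rep(0, ncol(features)); names(imp) <- fn
  it <- tryCatch(xgboost::xgb.importance(model = booster), error = function(e) NULL)
  if (!is.null(it) && nrow(it) > 0) {
    imp[it$Feature] <- it$Gain
    imp <- imp / sum(imp)
  } else {
    warnf("boosted trees made no informative splits; importance set uniform")
    imp[] <- 1 / ncol(features)
  }
  pred <- function(newx) {
    newx <- as.matrix(newx); colnames(newx) <- fn
    stats::predict(booster, xgboost::xgb.DMatrix(newx, nthread = 1L))
  }
  list(model = booster, importance = unname(imp), predict = pred)
}

#' Support-vector baseline with a regression-style continuous output
#'
#' An epsilon-regression SVM on 0/1-coded labels whose continuous output
#' is thresholded at 0.5 — the usual way an "SVR" produces classification
#' metrics.
#'
#' @inheritParams train_boosted_trees
#' @return List with `model` and `predict(newx)` returning scores in which
#'   values > 0.5 mean the positive class.
#' @export
svm_baseline <- function(features, labels) {
  features <- as.matrix(features)
  y <- encode_labels(labels)
  if (length(unique(y)) < 2L) stopf("labels contain a single class")
  model <- e1071::svm(x = features, y = as.numeric(y), type = "eps-regression")
  list(model = model,
       predict = function(newx) as.numeric(stats::predict(model, as.matrix(newx))))
}

encode_labels <- function(labels) {
  if (is.factor(labels)) as.integer(labels) - 1L
  else if (is.numeric(labels) && all(labels %in% c(0, 1))) as.integer(labels)
  else as.integer(factor(labels)) - 1L
}

#' Classification metrics from confusion counts
#'
#' @param tp,fn,tn,fp Nonnegative confusion counts (total > 0).
#' @return List with `sensitivity` = TP/(TP+FN), `specificity` =
#'   TN/(TN+FP), `accuracy` = (TP+TN)/total, as proportions. A zero
#'   denominator yields `NaN`, never a silent 0.
#' @export
classification_metrics <- function(tp, fn, tn, fp) {
  cnt <- c(tp, fn, tn, fp)
  if (any(cnt < 0) || sum(cnt) == 0) stopf("counts must be >= 0 with positive total")
  ratio <- function(num, den) if (den == 0) NaN else num / den
  list(sensitivity = ratio(tp, tp + fn),
       specificity = ratio(tn, tn + fp),
       accuracy = (tp + tn) / sum(cnt))
}

# Stratified fold assignment: within each class, subjects are shuffled and
# dealt round-robin into k folds.
stratified_folds <- function(labels, k_folds, seed) {
  labels <- factor(labels)
  if (any(table(labels) < k_folds))
    stopf("smallest class has %d subjects, fewer than k_folds = %d",
          min(table(labels)), k_folds)
  folds <- integer(length(labels))
  local_seed(seed, {
    for (lv in levels(labels)) {
      idx <- sample(which(labels == lv))
      folds[idx] <- rep(seq_len(k_folds), length.out = length(idx))
    }
  })
  folds
}

#' Pipeline configuration for cross-validated connectome classification
#'
#' @param method Decomposition: `"riemann"` (kernel PCA on the
#'   log-Euclidean metric of regularized Laplacians), `"linear"`,
#'   `"gaussian"` (Euclidean Gaussian-kernel PCA), or `"raw"` (vectorized
#'   FC entries straight to the classifier).
#' @param classifier `"gbt"` (boosted trees) or `"svm"`.
#' @param sigma `"auto"` (data-driven default) or a positive number.
#' @param gamma Laplacian regularization (default 1).
#' @param n_components `NULL` for the 95%-trace default or an integer.
#' @param weight_transform Passed to [graph_laplacian()].
#' @param gbt_params Overrides for [default_gbt_params()].
#' @export
pipeline_config <- function(method = c("riemann", "linear", "gaussian", "raw"),
                            classifier = c("gbt", "svm"),
                            sigma = "auto", gamma = 1, n_components = NULL,
                            weight_transform = c("abs", "clip_negative"),
                            gbt_params = list()) {
  list(method = match.arg(method), classifier = match.arg(classifier),
       sigma = sigma, gamma = gamma, n_components = n_components,
       weight_transform = match.arg(weight_transform),
       gbt_params = gbt_params)
}

resolve_sigma <- function(sigma, laplacians) {
  if (identical(sigma, "auto") || is.null(sigma)) default_sigma(laplacians)
  else sigma
}

fit_decomposition <- function(matrices, laplacians, config) {
  switch(config$method,
    riemann = rkpca_fit(laplacians,
                        sigma = resolve_sigma(config$sigma, laplacians),
                        n_components = config$n_components),
    linear = fit_linear_pca(matrices, n_components = config$n_components),
    gaussian = fit_gaussian_kpca(
      matrices,
      sigma = if (identical(config$sigma, "auto")) NULL else config$sigma,
      n_components = config$n_components),
    raw = NULL)
}

project_features <- function(model, matrices, laplacians, config) {
  if (config$method == "raw") fc_feature_rows(matrices)
  else if (config$method == "riemann") kpca_transform(model, laplacians)
  else kpca_transform(model, matrices)
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' For every fold the decomposition is fitted on the training split only
#' and held-out subjects are projected through the out-of-sample
#' transform — the test fold never influences the fitted model. The
#' positive class for sensitivity is `"patient"` (configurable).
#'
#' @param matrices Named list of [connectivity_matrix] objects, one per
#'   subject, aligned with `cohort$subject_id`.
#' @param cohort Cohort data.frame with `subject_id` and two-level `group`.
#' @param config A [pipeline_config()].
#' @param k_folds Number of folds (default 10).
#' @param seed Seed controlling fold assignment and classifier subsampling.
#' @param positive Group level counted as "patient" for sensitivity;
#'   defaults to `"patient"` if present, else the second level.
#' @return A `cv_report`: per-fold confusion counts, aggregate
#'   sensitivity/specificity/accuracy in percent, and the configuration
#'   snapshot (including per-fold sigma and n').
#' @export
cross_validate <- function(matrices, cohort, config = pipeline_config(),
                           k_folds = 10, seed = 1, positive = NULL) {
  cohort <- validate_cohort(cohort)
  if (!is.null(names(matrices)) &&
      !identical(names(matrices), as.character(cohort$subject_id))) {
    if (!all(cohort$subject_id %in% names(matrices)))
      stopf("matrices missing for subject(s): %s",
            paste(setdiff(cohort$subject_id, names(matrices)), collapse = ", "))
    matrices <- matrices[as.character(cohort$subject_id)]
  }
  if (length(matrices) != nrow(cohort))
    stopf("%d matrices for %d subjects", length(matrices), nrow(cohort))
  if (is.null(positive))
    positive <- if ("patient" %in% levels(cohort$group)) "patient"
                else levels(cohort$group)[2]
  y <- as.integer(cohort$group == positive)
  folds <- stratified_folds(cohort$group, k_folds, seed)
  laplacians <- if (config$method == "riemann")
    lapply(matrices, laplacian_from_fc, gamma = config$gamma,
           weight_transform = config$weight_transform)
  else NULL
  fold_rows <- vector("list", k_folds)
  sigmas <- rep(NA_real_, k_folds); ncomps <- rep(NA_integer_, k_folds)
  for (f in seq_len(k_folds)) {
    tr <- which(folds != f); te <- which(folds == f)
    model <- fit_decomposition(matrices[tr], laplacians[tr], config)
    X_tr <- project_features(model, matrices[tr], laplacians[tr], config)
    X_te <- project_features(model, matrices[te], laplacians[te], config)
    if (!is.null(model)) {
      sigmas[f] <- if (is.null(model$sigma)) NA_real_ else model$sigma
      ncomps[f] <- model$n_components
    }
    clf <- if (config$classifier == "gbt")
      train_boosted_trees(X_tr, y[tr], params = config$gbt_params,
                          seed = seed + f)
    else svm_baseline(X_tr, y[tr])
    pred <- as.integer(clf$predict(X_te) > 0.5)
    fold_rows[[f]] <- data.frame(
      fold = f,
      tp = sum(pred == 1 & y[te] == 1), fn = sum(pred == 0 & y[te] == 1),
      tn = sum(pred == 0 & y[te] == 0), fp = sum(pred == 1 & y[te] == 0))
  }
  folds_df <- do.call(rbind, fold_rows)
  tot <- colSums(folds_df[, c("tp", "fn", "tn", "fp")])
  mets <- classification_metrics(tot[["tp"]], tot[["fn"]],
                                 tot[["tn"]], tot[["fp"]])
  structure(list(
    folds = folds_df, counts = as.list(tot),
    sensitivity = 100 * mets$sensitivity,
    specificity = 100 * mets$specificity,
    accuracy = 100 * mets$accuracy,
    config = c(config, list(k_folds = k_folds, seed = seed,
                            positive = positive,
                            fold_sigma = sigmas, fold_n_components = ncomps)),
    fold_assignment = folds),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report: %s + %s, %d-fold>\n  sensitivity %.1f%%  specificity %.1f%%  accuracy %.1f%%\n",
    x$config$method, x$config$classifier, x$config$k_folds,
    x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' Sigma/gamma sensitivity sweep
#'
#' Full factorial sweep over kernel bandwidths and Laplacian
#' regularizations, each cell a complete [cross_validate()] run with the
#' same fold seed.
#'
#' @inheritParams cross_validate
#' @param sigma_grid Numeric vector of bandwidths (or `"auto"` entries).
#' @param gamma_grid Numeric vector of positive regularizations.
#' @return A tidy data.frame (sigma, gamma, sensitivity, specificity,
#'   accuracy in %), with the full `cv_report` list in attribute
#'   `"reports"`.
#' @export
sweep_parameters <- function(matrices, cohort, sigma_grid, gamma_grid,
                             config = pipeline_config(), k_folds = 10,
                             seed = 1) {
  if (length(sigma_grid) == 0L || length(gamma_grid) == 0L)
    stopf("sigma_grid and gamma_grid must be nonempty")
  grid <- expand.grid(sigma = sigma_grid, gamma = gamma_grid,
                      stringsAsFactors = FALSE)
  reports <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg <- config
    cfg$sigma <- grid$sigma[[g]]
    cfg$gamma <- as.numeric(grid$gamma[[g]])
    rep_g <- cross_validate(matrices, cohort, cfg, k_folds = k_folds,
                            seed = seed)
    reports[[g]] <- rep_g
    rows[[g]] <- data.frame(
      sigma = if (identical(grid$sigma[[g]], "auto")) NA_real_
              else as.numeric(grid$sigma[[g]]),
      gamma = cfg$gamma, sensitivity = rep_g$sensitivity,
      specificity = rep_g$specificity, accuracy = rep_g$accuracy)
  }
  out <- do.call(rbind, rows)
  attr(out, "reports") <- reports
  out
}
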