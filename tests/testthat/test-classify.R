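test_that("metrics follow their defining ratios, with NaN for empty denominators", {
  m <- classification_metrics(9, 1, 8, 2)
  expect_equal(m$sensitivity, 0.90)
  expect_equal(m$specificity, 0.80)
  expect_equal(m$accuracy, 0.85)
  m0 <- classification_metrics(0, 0, 5, 0)
  expect_true(is.nan(m0$sensitivity))
  expect_equal(m0$specificity, 1.0)
  m1 <- classification_metrics(7, 0, 5, 0)
  expect_equal(unlist(m1), c(sensitivity = 1, specificity = 1, accuracy = 1))
  expect_error(classification_metrics(0, 0, 0, 0), "positive total")
})

test_that("boosted trees concentrate importance on a separating feature", {
  set.seed(41)
  n <- 80
  y <- rep(0:1, each = n / 2)
  X <- cbind(sep = y + rnorm(n, sd = 0.05),
             matrix(rnorm(n * 6), n, 6))
  fit <- train_boosted_trees(X, y, seed = 3)
  expect_equal(sum(fit$importance), 1, tolerance = 1e-10)
  expect_true(all(fit$importance >= 0))
  expect_gt(fit$importance[1], 0.5)
  expect_gt(mean((fit$predict(X) > 0.5) == y), 0.95)
  expect_error(train_boosted_trees(X, rep(1, n)), "single class")
})

test_that("uninformative features yield a flagged uniform importance", {
  X <- matrix(1, 20, 3)
  y <- rep(0:1, 10)
  expect_warning(fit <- train_boosted_trees(X, y, seed = 1),
                 "no informative splits")
  expect_equal(fit$importance, rep(1 / 3, 3))
})

test_that("the support-vector baseline solves a linearly separable toy set", {
  set.seed(13)
  n <- 40
  y <- rep(0:1, each = n / 2)
  X <- cbind(y * 4 + rnorm(n, sd = 0.2), rnorm(n))
  fit <- svm_baseline(X, y)
  expect_equal(as.integer(fit$predict(X) > 0.5), y)
})

test_that("stratified folds balance classes and reject tiny classes", {
  g <- factor(rep(c("a", "b"), c(30, 20)))
  f <- riemfc:::stratified_folds(g, 10, seed = 2)
  expect_equal(as.vector(table(f)), rep(5, 10))
  for (i in 1:10) expect_equal(sum(g[f == i] == "a"), 3)
  expect_error(riemfc:::stratified_folds(factor(rep(c("a", "b"), c(30, 5))), 10),
               "fewer than k_folds")
})

test_that("cross-validation separates a planted cohort and collapses under shuffling", {
  sim <- planted_cohort(seed = 11)
  rep_r <- cross_validate(sim$fc, sim$cohort, pipeline_config(),
                          k_folds = 10, seed = 1)
  expect_gte(rep_r$accuracy, 85)
  expect_equal(rep_r$counts$tp + rep_r$counts$fn, 60)
  expect_equal(sum(unlist(rep_r$counts)), 120)
  # aggregate counts equal the fold sums
  expect_equal(rep_r$counts$tp, sum(rep_r$folds$tp))
  # label shuffling collapses accuracy to the chance band
  coh <- sim$cohort
  coh$group <- local({ set.seed(99); sample(coh$group) })
  rep_s <- cross_validate(sim$fc, coh, pipeline_config(), k_folds = 10, seed = 1)
  expect_lt(rep_s$accuracy, 59)
  expect_gt(rep_s$accuracy, 41)
})

test_that("all four decomposition methods and both classifiers run through CV", {
  fx <- sim_laplacians(n_per_group = 10, k = 8, T = 80, seed = 15,
                       effect = 0.45, edges = cbind(c(1, 3), c(2, 4)))
  for (method in c("riemann", "linear", "gaussian", "raw")) {
    cfg <- pipeline_config(method = method,
                           classifier = if (method == "linear") "svm" else "gbt",
                           n_components = if (method == "raw") NULL else 5)
    r <- cross_validate(fx$fc, fx$sim$cohort, cfg, k_folds = 5, seed = 2)
    expect_s3_class(r, "cv_report")
    expect_equal(sum(unlist(r$counts)), 20)
  }
})

test_that("a 1x1 sweep equals a direct cross-validation call", {
  fx <- sim_laplacians(n_per_group = 8, k = 8, T = 80, seed = 19,
                       effect = 0.4, edges = cbind(1, 2))
  sw <- sweep_parameters(fx$fc, fx$sim$cohort, sigma_grid = 0.8,
                         gamma_grid = 2, k_folds = 4, seed = 3)
  direct <- cross_validate(fx$fc, fx$sim$cohort,
                           pipeline_config(sigma = 0.8, gamma = 2),
                           k_folds = 4, seed = 3)
  expect_equal(nrow(sw), 1)
  expect_equal(sw$accuracy, direct$accuracy)
  expect_equal(sw$sensitivity, direct$sensitivity)
  expect_error(sweep_parameters(fx$fc, fx$sim$cohort, numeric(0), 1), "nonempty")
})

test_that("CV accuracy is non-decreasing in planted effect size", {
  med_acc <- vapply(c(0, 0.3), function(eff) {
    acc <- vapply(c(11, 12, 13), function(sd) {
      sim <- planted_cohort(seed = sd, effect = eff, n_per_group = 30, T = 200)
      cross_validate(sim$fc, sim$cohort, pipeline_config(),
                     k_folds = 5, seed = 1)$accuracy
    }, numeric(1))
    stats::median(acc)
  }, numeric(1))
  expect_gt(med_acc[2], med_acc[1])
})
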