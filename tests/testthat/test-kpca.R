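test_that("Riemann kernel has closed-form values at known distances", {
  lap <- sim_laplacians(n_per_group = 3, k = 6, seed = 2)$lap
  K1 <- riemann_kernel(list(lap[[1]], lap[[1]], lap[[1]]), sigma = 0.7)
  expect_equal(K1, matrix(1, 3, 3))
  # two scalar dilations of I: d = c * sqrt(k); choose c so d = sigma * sqrt(2)
  c0 <- 0.4
  S1 <- diag(2); S2 <- exp(c0) * diag(2)
  sig <- c0  # d = c0 * sqrt(2)
  K <- riemann_kernel(list(S1, S2), sigma = sig)
  expect_equal(K[1, 2], exp(-1), tolerance = 1e-12)
  expect_equal(diag(K), c(1, 1))
  expect_error(riemann_kernel(lap, sigma = 0), "sigma")
})

test_that("kernel matrices agree with a pairwise-distance oracle and are PSD", {
  lap <- sim_laplacians(n_per_group = 6, k = 7, seed = 5)$lap
  sig <- default_sigma(lap)
  K <- riemann_kernel(lap, sig)
  # independent route: explicit pairwise log-Euclidean distances
  m <- length(lap)
  K_oracle <- diag(m)
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    K_oracle[i, j] <- K_oracle[j, i] <-
      exp(-log_euclidean_distance(lap[[i]], lap[[j]])^2 / (2 * sig^2))
  }
  expect_equal(K, K_oracle, tolerance = 1e-10)
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})

test_that("default bandwidth reduces to the sample SD in the scalar case and is homogeneous", {
  # two 1x1 SPD inputs with logs {0, ln 2}
  expect_equal(default_sigma(list(matrix(1, 1, 1), matrix(2, 1, 1))),
               stats::sd(c(0, log(2))))
  expect_error(default_sigma(list(diag(3), diag(3))), "identical")
  expect_error(default_sigma(list(diag(3))), "at least 2")
  # scaling every log-matrix by c scales sigma by |c|
  set.seed(14)
  S <- lapply(1:4, function(i) random_spd(5))
  Sc <- lapply(S, function(x) matrix_exp(2.5 * matrix_log(x)))
  expect_equal(default_sigma(Sc), 2.5 * default_sigma(S), tolerance = 1e-8)
  # entrywise variant also available
  expect_gt(default_sigma(S, dispersion = "entry"), 0)
})

test_that("fit drops degenerate inputs and honors the component contract", {
  lap <- sim_laplacians(n_per_group = 5, k = 6, seed = 7)$lap
  expect_error(rkpca_fit(list(lap[[1]], lap[[1]])), "identical|no positive")
  model <- rkpca_fit(lap, n_components = 4)
  expect_equal(model$n_components, 4L)
  expect_equal(dim(model$scores), c(10L, 4L))
  # alpha~ normalization: lambda_j * ||alpha~_j||^2 = 1
  expect_equal(model$eigenvalues * colSums(model$coefficients^2),
               rep(1, 4), tolerance = 1e-10)
  expect_true(all(diff(model$eigenvalues) <= 1e-12))
  expect_warning(rkpca_fit(lap, n_components = 50), "reduced")
  # default retains >= 95% of the centered-kernel trace
  m95 <- rkpca_fit(lap)
  expect_gte(sum(m95$eigenvalues), 0.95 * m95$trace_c - 1e-10)
})

test_that("transform reproduces fit-time projections and is order-invariant", {
  lap <- sim_laplacians(n_per_group = 6, k = 7, seed = 9)$lap
  model <- rkpca_fit(lap, n_components = 5)
  expect_equal(kpca_transform(model, lap), unname(model$scores),
               ignore_attr = TRUE, tolerance = 1e-8)
  new_lap <- sim_laplacians(n_per_group = 2, k = 7, seed = 10)$lap
  f1 <- kpca_transform(model, new_lap)
  # identical new subjects get identical features
  expect_equal(kpca_transform(model, list(new_lap[[1]], new_lap[[1]]))[1, ],
               kpca_transform(model, list(new_lap[[1]], new_lap[[1]]))[2, ])
  # permuting training-subject order leaves new-subject features unchanged
  # up to component sign
  perm <- c(4, 1, 12, 3, 9, 2, 7, 11, 5, 10, 8, 6)
  model_p <- rkpca_fit(lap[perm], n_components = 5)
  f2 <- kpca_transform(model_p, new_lap)
  expect_equal(abs(f1), abs(f2), tolerance = 1e-8)
  expect_error(kpca_transform(model, list(random_spd(4))), "dimension")
})

test_that("kernel matrix is invariant to a common orthogonal conjugation", {
  set.seed(18)
  S <- lapply(1:5, function(i) random_spd(6))
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  SQ <- lapply(S, function(x) Q %*% x %*% t(Q))
  expect_equal(riemann_kernel(S, 0.8), riemann_kernel(SQ, 0.8),
               tolerance = 1e-8)
})

test_that("linear PCA baseline is lossless at full rank and matches prcomp", {
  fx <- sim_laplacians(n_per_group = 6, k = 6, seed = 3)
  model <- fit_linear_pca(fx$fc, n_components = 11)
  X <- do.call(rbind, lapply(fx$fc, function(A) A$values[upper.tri(A$values)]))
  expect_equal(linear_pca_reconstruct(model, model$scores), X,
               ignore_attr = TRUE, tolerance = 1e-8)
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  for (j in 1:5)
    expect_gt(abs(cor(model$scores[, j], pr$x[, j])), 1 - 1e-9)
  # out-of-sample transform agrees with the training projection
  expect_equal(kpca_transform(model, fx$fc), unname(model$scores),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("Gaussian kernel PCA in the large-bandwidth limit matches linear PCA", {
  fx <- sim_laplacians(n_per_group = 8, k = 6, seed = 6)
  lin <- fit_linear_pca(fx$fc, n_components = 5)
  gau <- fit_gaussian_kpca(fx$fc, sigma = 2000, n_components = 5)
  for (j in 1:5)
    expect_gt(abs(cor(lin$scores[, j], gau$scores[, j])), 0.999)
})

test_that("the Riemann model equals the Gaussian machinery run on matrix logs", {
  # code-path equivalence: swapping the Riemann distance into the Euclidean
  # Gaussian-kernel route (by handing it the logs as raw symmetric inputs
  # with unit diagonal restored) must reproduce the Riemann projections.
  lap <- sim_laplacians(n_per_group = 5, k = 6, seed = 4)$lap
  sig <- 0.9
  mR <- rkpca_fit(lap, sigma = sig, n_components = 4)
  logs <- lapply(lap, function(L) L$logm)
  # Euclidean distance on full vectorized logs vs upper-triangle vectors:
  # scale differs (off-diagonals counted twice, diagonals once), so compare
  # against an explicit eigen-solve of the centered kernel instead.
  m <- length(lap)
  D2 <- as.matrix(stats::dist(do.call(rbind, lapply(logs, as.vector))))^2
  K <- exp(-D2 / (2 * sig^2))
  J <- diag(m) - matrix(1 / m, m, m)
  Kc <- J %*% K %*% J
  e <- eigen(Kc, symmetric = TRUE)
  scores_oracle <- Kc %*% sweep(e$vectors[, 1:4], 2, sqrt(e$values[1:4]), "/")
  expect_equal(abs(unname(mR$scores)), abs(scores_oracle), tolerance = 1e-8)
})

test_that("centered-kernel spectrum accounts for the feature-space variance", {
  lap <- sim_laplacians(n_per_group = 7, k = 6, seed = 8)$lap
  model <- rkpca_fit(lap, n_components = 13)
  # with all components retained the spectrum exhausts the centered trace
  expect_equal(sum(model$eigenvalues), model$trace_c, tolerance = 1e-8)
})
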