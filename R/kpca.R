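# Kernel PCA on the SPD manifold of regularized graph Laplacians, using
# the log-Euclidean metric: K_ij = exp(-d_logE(Li, Lj)^2 / (2 sigma^2)).
# Because d_logE is the Frobenius distance of matrix logs, all pairwise
# kernel work reduces to Euclidean geometry on vectorized logs, which is
# what the internal representation stores. Linear-PCA and Euclidean
# Gaussian-kernel baselines share the same fit/transform contract.

# Stack a list of regularized Laplacians (or plain SPD matrices) into an
# m x k^2 matrix of vectorized matrix logs.
stack_logs <- function(laplacians) {
  logs <- lapply(laplacians, function(L)
    if (inherits(L, "regularized_laplacian")) L$logm else matrix_log(L))
  dims <- vapply(logs, nrow, integer(1))
  if (length(unique(dims)) != 1L)
    stopf("all matrices must share one ROI dimension; found {%s}",
          paste(sort(unique(dims)), collapse = ", "))
  M <- do.call(rbind, unname(lapply(logs, as.vector)))
  list(M = M, k = dims[[1]])
}

# Squared Euclidean cross-distances between rows of A (a x p) and B (b x p).
cross_sqdist <- function(A, B) {
  D2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  pmax(D2, 0)
}

#' Riemann (log-Euclidean) kernel matrix
#'
#' K_ij = exp(-d_logE(L_i, L_j)^2 / (2 sigma^2)) over a set of regularized
#' Laplacians. Symmetric, unit diagonal, positive semidefinite.
#'
#' @param laplacians List of `regularized_laplacian` (or SPD matrices).
#' @param sigma Positive kernel bandwidth.
#' @return m x m kernel matrix.
#' @export
riemann_kernel <- function(laplacians, sigma) {
  if (!is_scalar_number(sigma) || sigma <= 0) stopf("sigma must be > 0")
  M <- stack_logs(laplacians)$M
  K <- exp(-cross_sqdist(M, M) / (2 * sigma^2))
  K <- (K + t(K)) / 2
  diag(K) <- 1
  K
}

#' Default kernel bandwidth from the data
#'
#' The standard deviation of the matrix entries across subjects, measured
#' in the space the log-Euclidean distance lives in (the matrix logs).
#' Classification performance peaks when sigma is near the spread of the
#' matrices, so this is the package-wide default.
#'
#' With `dispersion = "subject"` (the default) sigma^2 is the total
#' between-subject variance, `sum_e Var_s(entry_e)` — equivalently the
#' mean squared Frobenius deviation from the mean log-matrix. For
#' independent subjects the expected squared pairwise distance is then
#' `2 sigma^2`, so typical kernel entries sit near `exp(-1)` regardless of
#' the Laplacian regularization gamma; this is what makes the pipeline
#' gamma-insensitive. `dispersion = "entry"` instead pools all entries of
#' all matrices into one sample and takes their SD (a within-matrix
#' spread, which does not track gamma). `on = "fc"` uses the raw
#' FC/Laplacian entries instead of the logs.
#'
#' @param laplacians List of `regularized_laplacian` objects (>= 2).
#' @param on `"log"` (default) or `"fc"`.
#' @param dispersion `"subject"` (default) or `"entry"`; see Details.
#' @return Positive scalar.
#' @export
default_sigma <- function(laplacians, on = c("log", "fc"),
                          dispersion = c("subject", "entry")) {
  on <- match.arg(on)
  dispersion <- match.arg(dispersion)
  if (length(laplacians) < 2L) stopf("need at least 2 subjects")
  M <- if (on == "log") stack_logs(laplacians)$M
  else do.call(rbind, lapply(laplacians, function(L)
    as.vector(if (inherits(L, "regularized_laplacian")) L$values else L)))
  s <- if (dispersion == "subject")
    sqrt(sum(apply(M, 2L, stats::var)))
  else stats::sd(as.vector(M))
  if (!is.finite(s) || s == 0)
    stopf("all matrices are identical (zero entry variance); set sigma manually")
  s
}

# Shared eigen-machinery: kernel double-centering, eigendecomposition,
# component selection and normalization. `F` is the m x p feature matrix
# whose row distances define the kernel (vectorized matrix logs for the
# Riemann method, vectorized upper triangles for the Euclidean baseline).
kpca_core <- function(F, sigma, n_components, var_explained) {
  m <- nrow(F)
  if (m < 2L) stopf("need at least 2 subjects to fit")
  K <- exp(-cross_sqdist(F, F) / (2 * sigma^2))
  K <- (K + t(K)) / 2; diag(K) <- 1
  row_means <- colMeans(K)
  grand_mean <- mean(K)
  Kc <- K - outer(row_means, rep(1, m)) - outer(rep(1, m), row_means) + grand_mean
  e <- eigen(Kc, symmetric = TRUE)
  keep <- e$values > 1e-10 * max(e$values, 0)
  keep[m] <- FALSE  # centering removes one rank
  avail <- sum(keep)
  if (avail == 0L)
    stopf("centered kernel has no positive eigenvalues (all subjects identical?)")
  lambda <- e$values[keep]
  alpha <- e$vectors[, keep, drop = FALSE]
  if (is.null(n_components)) {
    n_components <- which(cumsum(lambda) / sum(lambda) >= var_explained)[1]
  } else if (n_components > avail) {
    warnf("n_components = %d exceeds available rank %d; reduced", n_components, avail)
    n_components <- avail
  }
  n_components <- max(1L, min(as.integer(n_components), avail, m - 1L))
  lambda <- lambda[seq_len(n_components)]
  # alpha columns are unit-norm; alpha~ = alpha / sqrt(lambda) so that the
  # feature-space axes u have unit norm: lambda * ||alpha~||^2 = 1.
  coefficients <- sweep(alpha[, seq_len(n_components), drop = FALSE],
                        2L, sqrt(lambda), "/")
  scores <- Kc %*% coefficients
  list(sigma = sigma, eigenvalues = lambda, coefficients = coefficients,
       n_components = n_components, row_means = row_means,
       grand_mean = grand_mean, scores = scores, trace_c = sum(diag(Kc)))
}

kpca_project <- function(model, F_new) {
  Kx <- exp(-cross_sqdist(F_new, model$train_features) / (2 * model$sigma^2))
  Kc <- Kx - rowMeans(Kx) -
    matrix(model$row_means, nrow(Kx), length(model$row_means), byrow = TRUE) +
    model$grand_mean
  Kc %*% model$coefficients
}

#' Fit Riemann kernel PCA on regularized Laplacians
#'
#' Builds the log-Euclidean Gaussian kernel over the training Laplacians,
#' double-centers it (feature-space centering), eigendecomposes, and keeps
#' the leading components. Components with eigenvalue <= 1e-10 of the
#' largest are dropped with a warning if that reduces a requested count.
#'
#' @param laplacians List of `regularized_laplacian` objects.
#' @param sigma Kernel bandwidth; `NULL` (default) uses [default_sigma()].
#' @param n_components Number of components; `NULL` keeps the smallest
#'   number explaining `var_explained` of the centered-kernel trace.
#' @param var_explained Default 0.95.
#' @return A `kpca_model` (method `"riemann"`) storing the training logs,
#'   sigma, gamma, eigenvalues, normalized coefficients and centering
#'   statistics. `$scores` holds the training projections (m x n').
#' @export
rkpca_fit <- function(laplacians, sigma = NULL, n_components = NULL,
                      var_explained = 0.95) {
  st <- stack_logs(laplacians)
  if (is.null(sigma)) sigma <- default_sigma(laplacians)
  if (!is_scalar_number(sigma) || sigma <= 0) stopf("sigma must be > 0")
  core <- kpca_core(st$M, sigma, n_components, var_explained)
  gamma <- if (inherits(laplacians[[1]], "regularized_laplacian"))
    laplacians[[1]]$gamma else NA_real_
  structure(c(core, list(method = "riemann", train_features = st$M,
                         k = st$k, gamma = gamma, m = nrow(st$M))),
            class = "kpca_model")
}

#' Gaussian-kernel PCA baseline on vectorized FC matrices
#'
#' Identical machinery to [rkpca_fit()] but with plain Euclidean distance
#' between vectorized upper triangles of the FC matrices.
#'
#' @param matrices List of [connectivity_matrix] objects (or symmetric
#'   matrices).
#' @inheritParams rkpca_fit
#' @export
fit_gaussian_kpca <- function(matrices, sigma = NULL, n_components = NULL,
                              var_explained = 0.95) {
  F <- fc_feature_rows(matrices)
  if (is.null(sigma)) {
    sigma <- stats::sd(as.vector(F))
    if (!is.finite(sigma) || sigma == 0)
      stopf("all matrices are identical (zero entry variance); set sigma manually")
  }
  core <- kpca_core(F, sigma, n_components, var_explained)
  structure(c(core, list(method = "gaussian", train_features = F,
                         k = attr(F, "k"), gamma = NA_real_, m = nrow(F))),
            class = "kpca_model")
}

fc_feature_rows <- function(matrices) {
  rows <- lapply(matrices, function(A) {
    V <- if (inherits(A, "connectivity_matrix")) A$values else
      check_symmetric(A, tol = 1e-8, what = "matrix")
    upper_tri_vec(V)
  })
  lens <- vapply(rows, length, integer(1))
  if (length(unique(lens)) != 1L) stopf("matrices differ in ROI dimension")
  F <- do.call(rbind, rows)
  attr(F, "k") <- nrow(if (inherits(matrices[[1]], "connectivity_matrix"))
    matrices[[1]]$values else matrices[[1]])
  F
}

#' Linear PCA baseline on vectorized FC matrices
#'
#' Ordinary PCA of the upper-triangle edge vectors, exposed through the
#' same fit/transform contract as the kernel models.
#'
#' @inheritParams fit_gaussian_kpca
#' @return A `kpca_model` (method `"linear"`) with `$rotation`, `$center`,
#'   `$scores`.
#' @export
fit_linear_pca <- function(matrices, n_components = NULL, var_explained = 0.95) {
  F <- fc_feature_rows(matrices)
  m <- nrow(F)
  if (m < 2L) stopf("need at least 2 subjects to fit")
  ctr <- colMeans(F)
  X <- sweep(F, 2L, ctr)
  sv <- svd(X)
  lambda <- sv$d^2 / m          # eigenvalues of (1/m) X'X
  keep <- lambda > 1e-10 * max(lambda, 0) & seq_along(lambda) <= m - 1L
  avail <- sum(keep)
  if (avail == 0L) stopf("no variance across subjects")
  if (is.null(n_components)) {
    n_components <- which(cumsum(lambda[keep]) / sum(lambda[keep]) >= var_explained)[1]
  } else if (n_components > avail) {
    warnf("n_components = %d exceeds available rank %d; reduced", n_components, avail)
    n_components <- avail
  }
  n_components <- max(1L, min(as.integer(n_components), avail))
  rot <- sv$v[, seq_len(n_components), drop = FALSE]
  structure(list(method = "linear", rotation = rot, center = ctr,
                 eigenvalues = lambda[seq_len(n_components)],
                 n_components = n_components, k = attr(F, "k"), m = m,
                 scores = X %*% rot),
            class = "kpca_model")
}

#' Project subjects onto a fitted decomposition
#'
#' Out-of-sample transform: for kernel models the new subject's kernel row
#' against the stored training set is centered with the training centering
#' statistics and multiplied by the normalized coefficients; training
#' subjects reproduce their fit-time projections. Read-only on the model.
#'
#' @param model A `kpca_model` from [rkpca_fit()], [fit_gaussian_kpca()] or
#'   [fit_linear_pca()].
#' @param newdata For method `"riemann"`: list of `regularized_laplacian`;
#'   otherwise list of connectivity matrices.
#' @return n x n' matrix of component scores (one row per subject).
#' @export
kpca_transform <- function(model, newdata) {
  stopifnot(inherits(model, "kpca_model"))
  if (model$method == "riemann") {
    st <- stack_logs(newdata)
    if (st$k != model$k)
      stopf("ROI dimension mismatch: model %d, data %d", model$k, st$k)
    kpca_project(model, st$M)
  } else {
    F <- fc_feature_rows(newdata)
    if (attr(F, "k") != model$k)
      stopf("ROI dimension mismatch: model %d, data %d", model$k, attr(F, "k"))
    if (model$method == "linear")
      sweep(F, 2L, model$center) %*% model$rotation
    else
      kpca_project(model, F)
  }
}

#' Reconstruct edge vectors from linear-PCA scores
#'
#' Inverse transform of the linear baseline (lossless when all components
#' are retained).
#'
#' @param model A linear `kpca_model`.
#' @param scores n x n' score matrix.
#' @return n x p matrix of reconstructed upper-triangle edge vectors.
#' @export
linear_pca_reconstruct <- function(model, scores) {
  stopifnot(inherits(model, "kpca_model"), model$method == "linear")
  sweep(scores %*% t(model$rotation), 2L, model$center, "+")
}

#' @export
print.kpca_model <- function(x, ...) {
  cat(sprintf("<kpca_model: method=%s, m=%d subjects, n'=%d components, sigma=%s>\n",
              x$method, x$m, x$n_components,
              if (is.null(x$sigma)) "-" else format(x$sigma, digits = 4)))
  invisible(x)
}
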