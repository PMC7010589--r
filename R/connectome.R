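# Connectome geometry: Pearson FC, graph Laplacians, SPD regularization,
# matrix logarithm and the log-Euclidean distance the kernel is built on.

#' Construct a connectivity matrix object
#'
#' A connectivity matrix holds the k x k Pearson correlations between ROI
#' time series: symmetric, unit diagonal, entries in \[-1, 1\].
#'
#' @param values k x k numeric matrix of Pearson correlations.
#' @param roi_labels Optional character vector of k ROI names. Defaults to
#'   the AAL-116 labels when `k == 116`, otherwise `ROI_1 ... ROI_k`.
#' @param tol Symmetry tolerance (the matrix is symmetrized after the check).
#' @return An object of class `connectivity_matrix` with fields `values`
#'   and `roi_labels`.
#' @export
connectivity_matrix <- function(values, roi_labels = NULL, tol = 1e-10) {
  values <- check_symmetric(values, tol = tol, what = "connectivity matrix")
  k <- nrow(values)
  if (k < 2L) stopf("connectivity matrix needs at least 2 ROIs, got %d", k)
  if (max(abs(values)) > 1 + 1e-8)
    stopf("correlation entries must lie in [-1, 1]; max |r| = %.6g",
          max(abs(values)))
  if (max(abs(diag(values) - 1)) > 1e-8)
    stopf("connectivity matrix diagonal must be 1; max deviation %.3g",
          max(abs(diag(values) - 1)))
  diag(values) <- 1
  values[values > 1] <- 1
  values[values < -1] <- -1
  if (is.null(roi_labels)) {
    roi_labels <- if (k == 116L) aal_labels()$label else paste0("ROI_", seq_len(k))
  }
  if (length(roi_labels) != k)
    stopf("roi_labels has length %d but the matrix has %d ROIs",
          length(roi_labels), k)
  dimnames(values) <- list(roi_labels, roi_labels)
  structure(list(values = values, roi_labels = as.character(roi_labels)),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix: %d ROIs, mean off-diagonal r = %.3f>\n",
              nrow(x$values), mean(upper_tri_vec(x$values))))
  invisible(x)
}

#' Pearson functional connectivity from an ROI time-series matrix
#'
#' @param series T x k numeric matrix: T time points, k ROIs (columns).
#' @param roi_labels Optional ROI names; defaults to column names.
#' @return A [connectivity_matrix] with the diagonal forced to exactly 1.
#' @details A column with zero variance has no defined correlation; such
#'   ROIs are reported by index (and name, if available) as an error.
#' @export
fc_from_timeseries <- function(series, roi_labels = NULL) {
  if (!is.matrix(series) || !is.numeric(series))
    stopf("series must be a numeric T x k matrix")
  if (nrow(series) < 3L)
    stopf("need at least 3 time points, got %d", nrow(series))
  sds <- apply(series, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    nm <- if (!is.null(colnames(series))) colnames(series)[bad] else bad
    stopf("constant time series in ROI(s): %s", paste(nm, collapse = ", "))
  }
  if (is.null(roi_labels)) roi_labels <- colnames(series)
  C <- stats::cor(series)
  C <- (C + t(C)) / 2
  diag(C) <- 1
  connectivity_matrix(C, roi_labels = roi_labels)
}

#' Graph Laplacian of a connectivity matrix
#'
#' Builds L = D - W from the FC matrix, where W is the off-diagonal part of
#' the correlations made nonnegative (self-loops are dropped) and D is the
#' diagonal degree matrix of W's row sums. L is symmetric positive
#' semidefinite with zero row sums.
#'
#' @param A A [connectivity_matrix] or a plain symmetric matrix.
#' @param weight_transform How signed correlations become edge weights:
#'   `"abs"` (absolute value, the default) or `"clip_negative"` (negative
#'   correlations set to 0).
#' @return k x k Laplacian matrix with attribute `weight_transform`.
#' @export
graph_laplacian <- function(A, weight_transform = c("abs", "clip_negative")) {
  weight_transform <- match.arg(weight_transform)
  W <- if (inherits(A, "connectivity_matrix")) A$values else
    check_symmetric(A, tol = 1e-10, what = "adjacency matrix")
  diag(W) <- 0
  W <- switch(weight_transform, abs = abs(W), clip_negative = pmax(W, 0))
  L <- diag(rowSums(W), nrow(W)) - W
  dimnames(L) <- dimnames(W)
  attr(L, "weight_transform") <- weight_transform
  L
}

#' Regularize a graph Laplacian to a symmetric positive-definite matrix
#'
#' Adds `gamma * I` so the (PSD) Laplacian becomes SPD and admits a matrix
#' logarithm. The matrix log is computed once here and cached, since every
#' kernel evaluation needs it.
#'
#' @param L Laplacian matrix from [graph_laplacian()].
#' @param gamma Positive ridge; default 1.
#' @return Object of class `regularized_laplacian` with fields `values`,
#'   `gamma`, `weight_transform` and cached `logm`.
#' @export
regularize_laplacian <- function(L, gamma = 1) {
  if (!is_scalar_number(gamma) || gamma <= 0)
    stopf("gamma must be a positive number, got %s", format(gamma))
  wt <- attr(L, "weight_transform")
  L <- check_symmetric(L, tol = 1e-8, what = "Laplacian")
  S <- L + gamma * diag(nrow(L))
  structure(list(values = S, gamma = gamma,
                 weight_transform = if (is.null(wt)) NA_character_ else wt,
                 logm = matrix_log(S)),
            class = "regularized_laplacian")
}

#' FC matrix to regularized Laplacian in one step
#'
#' @inheritParams graph_laplacian
#' @inheritParams regularize_laplacian
#' @export
laplacian_from_fc <- function(A, gamma = 1,
                              weight_transform = c("abs", "clip_negative")) {
  regularize_laplacian(graph_laplacian(A, weight_transform), gamma = gamma)
}

spd_values <- function(S, what = "matrix") {
  if (inherits(S, "regularized_laplacian")) S$values
  else check_symmetric(S, tol = 1e-8, what = what)
}

#' Principal matrix logarithm of an SPD matrix
#'
#' Eigendecomposition-based: log(S) = V diag(log lambda) V'. Inputs are
#' symmetrized as (S + S')/2 before decomposition.
#'
#' @param S Symmetric positive-definite matrix (or `regularized_laplacian`).
#' @param tol Eigenvalues must exceed this (default 1e-10).
#' @return Symmetric matrix log(S).
#' @export
matrix_log <- function(S, tol = 1e-10) {
  S <- spd_values(S)
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) <= tol)
    stopf("matrix is not positive definite: smallest eigenvalue %.3g (tolerance %.3g)",
          min(e$values), tol)
  M <- e$vectors %*% (log(e$values) * t(e$vectors))
  (M + t(M)) / 2
}

#' Matrix exponential of a symmetric matrix
#'
#' Inverse of [matrix_log()] on the SPD cone.
#' @param M Symmetric matrix.
#' @return SPD matrix exp(M).
#' @export
matrix_exp <- function(M) {
  M <- check_symmetric(M, tol = 1e-8, what = "matrix")
  e <- eigen(M, symmetric = TRUE)
  S <- e$vectors %*% (exp(e$values) * t(e$vectors))
  (S + t(S)) / 2
}

#' Log-Euclidean distance between two SPD matrices
#'
#' d(S1, S2) = || log S1 - log S2 ||_F, the log-Euclidean geodesic-style
#' metric on the SPD manifold.
#'
#' @param S1,S2 SPD matrices (or `regularized_laplacian` objects, whose
#'   cached logs are reused).
#' @return Nonnegative scalar distance.
#' @export
log_euclidean_distance <- function(S1, S2) {
  M1 <- if (inherits(S1, "regularized_laplacian")) S1$logm else matrix_log(S1)
  M2 <- if (inherits(S2, "regularized_laplacian")) S2$logm else matrix_log(S2)
  if (!all(dim(M1) == dim(M2)))
    stopf("dimension mismatch: %dx%d vs %dx%d",
          nrow(M1), ncol(M1), nrow(M2), ncol(M2))
  sqrt(sum((M1 - M2)^2))
}

# --- plain-text I/O ---------------------------------------------------------

#' Write connectivity matrices as delimited text, one file per subject
#'
#' @param matrices List of [connectivity_matrix] objects (or plain matrices).
#' @param dir Output directory (created if absent).
#' @param ids Character vector of subject ids used as file stems; defaults
#'   to names of `matrices` or `sub001`-style ids.
#' @return Invisibly, the written file paths.
#' @export
write_matrices <- function(matrices, dir, ids = NULL) {
  if (is.null(ids)) ids <- names(matrices)
  if (is.null(ids)) ids <- sprintf("sub%03d", seq_along(matrices))
  if (length(ids) != length(matrices)) stopf("ids/matrices length mismatch")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(ids, ".txt"))
  for (s in seq_along(matrices)) {
    V <- if (inherits(matrices[[s]], "connectivity_matrix"))
      matrices[[s]]$values else matrices[[s]]
    utils::write.table(format(V, digits = 15, scientific = TRUE, trim = TRUE),
                       paths[s], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}

#' Read connectivity matrices from a directory of delimited text files
#'
#' Each `*.txt` file must hold one square, symmetric, unit-diagonal matrix.
#' Files are read in lexicographic order; stems become subject ids.
#'
#' @param path Directory (or explicit vector of file paths).
#' @param tol Symmetry tolerance for validation (default 1e-8).
#' @return Named list of [connectivity_matrix] objects.
#' @export
read_matrices <- function(path, tol = 1e-8) {
  files <- if (length(path) == 1L && dir.exists(path))
    sort(list.files(path, pattern = "\\.txt$", full.names = TRUE)) else path
  if (length(files) == 0L) stopf("no matrix files found in '%s'", path)
  out <- vector("list", length(files))
  for (s in seq_along(files)) {
    V <- as.matrix(utils::read.table(files[s], sep = "\t", header = FALSE,
                                     colClasses = "numeric"))
    dimnames(V) <- NULL
    if (nrow(V) != ncol(V))
      stopf("%s: matrix is %d x %d, not square", files[s], nrow(V), ncol(V))
    asym <- max(abs(V - t(V)))
    if (asym > tol)
      stopf("%s: asymmetric matrix, max |S - t(S)| = %.3g (tolerance %.3g)",
            files[s], asym, tol)
    out[[s]] <- connectivity_matrix((V + t(V)) / 2, tol = tol)
  }
  names(out) <- sub("\\.txt$", "", basename(files))
  out
}

#' Read a phenotype table
#'
#' Validates the mandatory columns `subject_id`, `group`, `age`, `sex`
#' (optionally `ybocs_total` or `severity_total`), uniqueness of ids and
#' that `group` has exactly two levels.
#'
#' @param path CSV file path.
#' @return A data.frame (a cohort table) with `group` and `sex` as factors.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(ph, where = path)
}

validate_cohort <- function(ph, where = "cohort") {
  need <- c("subject_id", "group", "age", "sex")
  missing_cols <- setdiff(need, names(ph))
  if (length(missing_cols) > 0)
    stopf("%s: missing mandatory column(s): %s",
          where, paste(missing_cols, collapse = ", "))
  if (anyDuplicated(ph$subject_id)) {
    d <- ph$subject_id[duplicated(ph$subject_id)][1]
    stopf("%s: duplicated subject_id '%s'", where, d)
  }
  ph$group <- factor(ph$group)
  if (nlevels(ph$group) != 2L)
    stopf("%s: 'group' must have exactly two levels, found %d (%s)",
          where, nlevels(ph$group), paste(levels(ph$group), collapse = ", "))
  ph$sex <- factor(ph$sex)
  if (!is.numeric(ph$age)) stopf("%s: 'age' must be numeric", where)
  if ("ybocs_total" %in% names(ph) && !("severity_total" %in% names(ph)))
    ph$severity_total <- ph$ybocs_total
  ph
}
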