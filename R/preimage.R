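# Pre-image reconstruction: map classifier importance expressed on the
# kernel-PCA components back to an importance matrix over brain
# connections. The feature-space target sum_k beta_k alpha~_k is a linear
# combination of the (centered) training images, so the classical Gaussian
# pre-image fixed point applies; on the log-Euclidean manifold each update
# is a weighted Frechet mean in the log-matrix domain, exponentiated at the
# end. Kernel centering is handled exactly: the centered combination plus
# the feature-space mean lifts to training weights
#   delta'_i = delta_i + (1 - sum(delta)) / m,   delta_i = sum_k beta_k alpha~_ik.

#' Embed component importances as a hierarchical-space coordinate vector
#'
#' The identity embedding of per-component importance scores as the
#' coordinate vector beta on the retained principal axes. Tree importances
#' are nonnegative and therefore direction-blind; optionally each
#' component's coordinate is signed by the point-biserial correlation of
#' that component's training scores with the class label.
#'
#' @param importance Length-n' nonnegative importance vector (sums to 1).
#' @param scores Optional m x n' training score matrix (for signing).
#' @param labels Optional labels aligned with `scores`.
#' @param sign If TRUE, multiply each coordinate by the sign of
#'   cor(score_j, label).
#' @return Numeric beta of length n'.
#' @export
importance_to_beta <- function(importance, scores = NULL, labels = NULL,
                               sign = FALSE) {
  beta <- as.numeric(importance)
  if (any(!is.finite(beta))) stopf("importance must be finite")
  if (isTRUE(sign)) {
    if (is.null(scores) || is.null(labels))
      stopf("signing requires training scores and labels")
    y <- encode_labels(labels)
    sg <- vapply(seq_len(ncol(scores)), function(j) {
      r <- suppressWarnings(stats::cor(scores[, j], y))
      if (!is.finite(r) || r == 0) 1 else base::sign(r)
    }, numeric(1))
    beta <- beta * sg
  }
  beta
}

#' Reconstruct the connection-space importance matrix (pre-image)
#'
#' Finds the SPD matrix whose kernel-space image best matches the target
#' combination of principal axes, by damped fixed-point iteration on the
#' matrix logs:
#'   log L_new = sum_i w_i log L_i / sum_i w_i,
#'   w_i = delta'_i exp(-d_logE(L_old, L_i)^2 / (2 sigma^2)).
#' The off-diagonal entries of the recovered matrix, sign-flipped back to
#' adjacency convention (A = -L off-diagonals), carry the edge
#' information; the diagonal is set to 0.
#'
#' Because the pre-image target includes the feature-space mean, the
#' recovered matrix is an actual point in the data cloud and its entries
#' are dominated by connectivity shared by all subjects. With
#' `reference = "frechet_mean"` (the default) the reported importance of
#' an edge is therefore the displacement of the pre-image from the
#' cohort's log-Euclidean Frechet mean — exactly the beta = 0
#' reconstruction — which isolates the discriminative component.
#' `reference = "none"` reports the raw recovered adjacency instead
#' (used, e.g., when reconstructing a single subject from its own feature
#' vector).
#'
#' @param model A Riemann `kpca_model` from [rkpca_fit()].
#' @param beta Length-n' coordinate vector (see [importance_to_beta()]);
#'   finite, not all zero.
#' @param reference `"frechet_mean"` (default) or `"none"`; see Details.
#' @param center If TRUE (default) the target includes the exact
#'   kernel-centering correction `delta'_i = delta_i + (1 - sum(delta))/m`,
#'   which makes reconstruction from a training subject's own feature
#'   vector exact at full rank. With `center = FALSE` the raw delta
#'   weights are used; that variant is invariant to positive rescaling of
#'   beta (the weights renormalize).
#' @param max_iter Maximum iterations per restart (default 500).
#' @param tol Relative Frobenius change of the log-iterate at which to stop
#'   (default 1e-6).
#' @param n_restarts Random multiplicative jitters of the initialization
#'   weights (default 5); the restart with the best objective wins.
#' @param seed Seed for restart jitter.
#' @return An `importance_map`: list with `values` (k x k symmetric, zero
#'   diagonal; reference-subtracted per `reference`), `laplacian` (the raw
#'   reconstructed SPD matrix), `delta`, `objective`, `iterations`,
#'   `converged`, `restart`, `reference`.
#' @export
reconstruct_importance <- function(model, beta, max_iter = 500, tol = 1e-6,
                                   n_restarts = 5, seed = 1,
                                   reference = c("frechet_mean", "none"),
                                   center = TRUE) {
  reference <- match.arg(reference)
  stopifnot(inherits(model, "kpca_model"))
  if (model$method != "riemann")
    stopf("pre-image reconstruction is defined for the Riemann model")
  if (length(beta) != model$n_components)
    stopf("beta has length %d but the model retains %d components",
          length(beta), model$n_components)
  if (any(!is.finite(beta))) stopf("beta must be finite")
  if (all(beta == 0)) stopf("beta is identically zero: nothing to reconstruct")
  m <- model$m
  delta <- as.vector(model$coefficients %*% beta)
  # exact centering correction: target + feature-space mean as a single
  # combination of uncentered training images
  delta_eff <- if (center) delta + (1 - sum(delta)) / m else delta
  M <- model$train_features            # m x k^2 vectorized logs
  two_s2 <- 2 * model$sigma^2
  run_restart <- function(w_init) {
    s <- sum(abs(w_init))
    if (s < 1e-12) return(NULL)
    logcur <- colSums(abs(w_init) * M) / s
    obj <- -Inf; it <- 0L; converged <- FALSE
    while (it < max_iter) {
      it <- it + 1L
      d2 <- rowSums(sweep(M, 2L, logcur)^2)
      w <- delta_eff * exp(-d2 / two_s2)
      S <- sum(w)
      if (abs(S) < 1e-12) return(list(failed = TRUE))
      prop <- colSums(w * M) / S
      step <- 1
      repeat {
        cand <- logcur + step * (prop - logcur)
        d2c <- rowSums(sweep(M, 2L, cand)^2)
        obj_c <- sum(delta_eff * exp(-d2c / two_s2))
        if (obj_c >= obj - 1e-12 || step < 1 / 64) break
        step <- step / 2      # damp if the objective would decrease
      }
      delta_log <- sqrt(sum((cand - logcur)^2)) /
        max(sqrt(sum(logcur^2)), 1e-12)
      logcur <- cand; obj <- obj_c
      if (delta_log <= tol) { converged <- TRUE; break }
    }
    list(failed = FALSE, log = logcur, objective = obj,
         iterations = it, converged = converged)
  }
  results <- vector("list", n_restarts)
  local_seed(seed, {
    for (r in seq_len(n_restarts)) {
      jitter <- if (r == 1L) rep(1, m) else exp(stats::rnorm(m, 0, 0.3))
      results[[r]] <- run_restart(delta_eff * jitter)
    }
  })
  ok <- which(vapply(results, function(x) !is.null(x) && !isTRUE(x$failed),
                     logical(1)))
  if (length(ok) == 0L)
    stopf(paste("all restarts hit a vanishing weight-sum denominator;",
                "consider signing beta (importance_to_beta(..., sign = TRUE))",
                "or reducing n_components"))
  best <- ok[which.max(vapply(results[ok], `[[`, numeric(1), "objective"))]
  res <- results[[best]]
  if (!res$converged)
    warnf("pre-image iteration did not converge in %d iterations (relative change above %g)",
          max_iter, tol)
  k <- model$k
  Lhat <- matrix_exp(matrix(res$log, k, k))
  vals <- -Lhat                       # adjacency convention
  diag(vals) <- 0
  vals <- (vals + t(vals)) / 2
  if (reference == "frechet_mean" && m > 1L) {
    Aref <- -matrix_exp(matrix(colMeans(M), k, k))
    diag(Aref) <- 0
    vals <- vals - (Aref + t(Aref)) / 2
  }
  structure(list(values = vals, laplacian = Lhat, delta = delta,
                 objective = res$objective, iterations = res$iterations,
                 converged = res$converged, restart = best,
                 reference = reference,
                 sigma = model$sigma, gamma = model$gamma),
            class = "importance_map")
}

#' @export
print.importance_map <- function(x, ...) {
  cat(sprintf("<importance_map: %d ROIs, %d iterations, converged=%s>\n",
              nrow(x$values), x$iterations, x$converged))
  invisible(x)
}

#' Rank connections by reconstructed importance
#'
#' Edges sorted by absolute importance (descending), ties broken by
#' (i, j) lexicographic order. When FC matrices and a cohort are supplied,
#' each edge also carries the empirical group difference
#' mean FC(patients) - mean FC(controls), which restores the effect
#' direction that nonnegative tree importances lose.
#'
#' @param map An `importance_map` (or plain symmetric matrix).
#' @param top_n Number of edges to return (default all).
#' @param matrices Optional list of [connectivity_matrix] for group deltas.
#' @param cohort Optional cohort table aligned with `matrices`.
#' @param roi_labels Optional ROI names.
#' @param positive Group level treated as patients (default `"patient"`).
#' @return data.frame: rank, i, j, roi_i, roi_j, importance, group_delta.
#' @export
rank_edges <- function(map, top_n = Inf, matrices = NULL, cohort = NULL,
                       roi_labels = NULL, positive = "patient") {
  V <- if (inherits(map, "importance_map")) map$values else
    check_symmetric(map, tol = 1e-8, what = "importance map")
  if (any(!is.finite(V))) stopf("importance map contains non-finite entries")
  k <- nrow(V)
  pairs <- upper_tri_pairs(k)
  imp <- V[pairs]
  ord <- order(-abs(imp), pairs[, 1], pairs[, 2])
  n_out <- min(length(ord), top_n)
  ord <- ord[seq_len(n_out)]
  gd <- rep(NA_real_, n_out)
  if (!is.null(matrices) && !is.null(cohort)) {
    cohort <- validate_cohort(cohort)
    pat <- cohort$group == positive
    edge_mat <- do.call(rbind, lapply(matrices, function(A)
      upper_tri_vec(if (inherits(A, "connectivity_matrix")) A$values else A)))
    gd <- colMeans(edge_mat[pat, ord, drop = FALSE]) -
      colMeans(edge_mat[!pat, ord, drop = FALSE])
  }
  if (is.null(roi_labels))
    roi_labels <- if (k == 116L) aal_labels()$label else paste0("ROI_", seq_len(k))
  data.frame(rank = seq_len(n_out),
             i = pairs[ord, 1], j = pairs[ord, 2],
             roi_i = roi_labels[pairs[ord, 1]],
             roi_j = roi_labels[pairs[ord, 2]],
             importance = imp[ord], group_delta = gd,
             stringsAsFactors = FALSE)
}

#' End-to-end discriminative-edge recovery
#'
#' Convenience pipeline: fit Riemann kernel PCA on all subjects, train
#' boosted trees on the projections, sign the component importances by
#' their point-biserial correlation with the group label, reconstruct the
#' connection-space importance map, and rank edges. Signing is the default
#' here because the sign pattern makes patient- and control-weighted
#' contributions cancel on non-discriminative edges, which is what lets
#' planted effects surface above the shared base connectivity.
#'
#' @inheritParams cross_validate
#' @param top_n Edges to return.
#' @param sign Sign beta by label correlation (default TRUE).
#' @param ... Passed to [reconstruct_importance()].
#' @return List: `edges` (ranked table), `map`, `model`, `importance`
#'   (component importances), `beta`.
#' @export
discriminative_edges <- function(matrices, cohort, config = pipeline_config(),
                                 top_n = 20, sign = TRUE, seed = 1, ...) {
  cohort <- validate_cohort(cohort)
  laplacians <- lapply(matrices, laplacian_from_fc, gamma = config$gamma,
                       weight_transform = config$weight_transform)
  model <- rkpca_fit(laplacians,
                     sigma = resolve_sigma(config$sigma, laplacians),
                     n_components = config$n_components)
  positive <- if ("patient" %in% levels(cohort$group)) "patient"
              else levels(cohort$group)[2]
  y <- as.integer(cohort$group == positive)
  clf <- train_boosted_trees(model$scores, y, params = config$gbt_params,
                             seed = seed)
  beta <- importance_to_beta(clf$importance, scores = model$scores,
                             labels = y, sign = sign)
  map <- reconstruct_importance(model, beta, seed = seed, ...)
  edges <- rank_edges(map, top_n = top_n, matrices = matrices,
                      cohort = cohort, positive = positive)
  list(edges = edges, map = map, model = model,
       importance = clf$importance, beta = beta)
}
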