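# Seed-based connectivity statistics: per-subject Fisher-Z correlation
# maps against a seed region's mean signal, covariate-adjusted group
# comparison per unit, and symptom-severity regression. Units are ROI time
# series or any flat vector of grid cells; the per-unit model is ordinary
# least squares z ~ 1 + group + age + sex (or severity in place of group),
# solved vectorized across all units at once.

#' Fisher-Z transform with clipping
#'
#' z = atanh(r) with r clipped to +/-(1 - 1e-7) so that units perfectly
#' correlated with the seed yield a finite (large) z.
#'
#' @param r Correlations.
#' @return z values.
#' @export
fisher_z <- function(r) atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))

#' Seed-based correlation map for one subject
#'
#' Averages the time series of the seed units and correlates the mean
#' signal with every other unit; seed units themselves are `NA`.
#'
#' @param series T x k time-series matrix.
#' @param seed_indices Column indices of the seed region (nonempty).
#' @param fisher Apply [fisher_z()] (default TRUE).
#' @param seed_name Optional label stored on the result.
#' @return Numeric length-k vector (attributes `seed_name`,
#'   `seed_indices`); `NA` at the seed's own units.
#' @export
seed_map <- function(series, seed_indices, fisher = TRUE, seed_name = NULL) {
  if (!is.matrix(series) || !is.numeric(series))
    stopf("series must be a numeric T x k matrix")
  k <- ncol(series)
  seed_indices <- as.integer(seed_indices)
  if (length(seed_indices) == 0L) stopf("seed_indices must be nonempty")
  if (any(seed_indices < 1L | seed_indices > k))
    stopf("seed index out of range 1..%d", k)
  sig <- rowMeans(series[, seed_indices, drop = FALSE])
  if (stats::sd(sig) == 0) stopf("seed mean signal is constant")
  r <- suppressWarnings(as.vector(stats::cor(sig, series)))
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  out <- if (fisher) atanh(r) else r
  out[seed_indices] <- NA_real_
  attr(out, "seed_name") <- seed_name
  attr(out, "seed_indices") <- seed_indices
  out
}

#' Seed maps for a whole cohort
#'
#' @param series_list Named list of T x k matrices.
#' @inheritParams seed_map
#' @return n x k matrix of z values, rows named by subject.
#' @export
cohort_seed_maps <- function(series_list, seed_indices, fisher = TRUE,
                             seed_name = NULL) {
  maps <- t(vapply(series_list, seed_map, numeric(ncol(series_list[[1]])),
                   seed_indices = seed_indices, fisher = fisher))
  attr(maps, "seed_name") <- seed_name
  attr(maps, "seed_indices") <- as.integer(seed_indices)
  maps
}

# Vectorized per-unit OLS of Y (n x u) on design X (n x p); returns the
# estimate, t and two-sided p for the coefficient in `term_col`.
ols_per_unit <- function(X, Y, term_col) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stopf("rank-deficient design: column(s) %s are collinear or constant",
          paste(bad, collapse = ", "))
  }
  n <- nrow(X); p <- ncol(X); df <- n - p
  coefs <- qr.coef(qrX, Y)                     # p x u
  resid <- Y - X %*% coefs
  sigma2 <- colSums(resid^2) / df
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(pmax(sigma2 * XtX_inv[term_col, term_col], 0))
  est <- coefs[term_col, ]
  tval <- ifelse(se > 0, est / se, NA_real_)
  data.frame(estimate = est, t = tval,
             p = 2 * stats::pt(-abs(tval), df = df))
}

#' Per-unit group comparison co-varying age and sex
#'
#' Ordinary least squares z ~ 1 + group + age + sex for every unit, with a
#' two-sided t test on the group coefficient (patient minus control).
#' Degrees of freedom are n - 4.
#'
#' @param maps n x u matrix of per-subject unit values (e.g. from
#'   [cohort_seed_maps()]); columns that contain `NA` (seed units) are
#'   returned as `NA` rows.
#' @param cohort Cohort table with `group`, `age`, `sex`.
#' @param alpha Significance level for the mask (default 0.05).
#' @param mc_correction `"none"` (default, uncorrected p < alpha) or
#'   `"fdr"` (Benjamini-Hochberg).
#' @param positive Group level coded 1 (default `"patient"` if present).
#' @param covariates Character subset of `c("age", "sex")` to adjust for
#'   (default both). With none, the group t equals a pooled-variance
#'   two-sample t test.
#' @return data.frame per unit: estimate, t, p, p_adj, mean_diff
#'   (unadjusted group mean difference), significant.
#' @export
group_glm <- function(maps, cohort, alpha = 0.05,
                      mc_correction = c("none", "fdr"), positive = NULL,
                      covariates = c("age", "sex")) {
  mc_correction <- match.arg(mc_correction)
  if (!all(covariates %in% c("age", "sex")))
    stopf("covariates must be a subset of c(\"age\", \"sex\")")
  cohort <- validate_cohort(cohort)
  if (nrow(maps) != nrow(cohort))
    stopf("%d map rows for %d subjects", nrow(maps), nrow(cohort))
  if (any(table(cohort$group) < 3L)) stopf("both groups need >= 3 subjects")
  if (is.null(positive))
    positive <- if ("patient" %in% levels(cohort$group)) "patient"
                else levels(cohort$group)[2]
  g <- as.numeric(cohort$group == positive)
  if ("sex" %in% covariates && nlevels(droplevels(cohort$sex)) < 2L)
    stopf("rank-deficient design: column sex is constant")
  X <- cbind(intercept = 1, group = g)
  if ("age" %in% covariates) X <- cbind(X, age = cohort$age)
  if ("sex" %in% covariates)
    X <- cbind(X, sex = as.numeric(cohort$sex == levels(cohort$sex)[2]))
  usable <- colSums(is.na(maps)) == 0L
  out <- data.frame(unit = seq_len(ncol(maps)), estimate = NA_real_,
                    t = NA_real_, p = NA_real_, p_adj = NA_real_,
                    mean_diff = NA_real_, significant = NA)
  if (any(usable)) {
    res <- ols_per_unit(X, maps[, usable, drop = FALSE], term_col = 2L)
    out$estimate[usable] <- res$estimate
    out$t[usable] <- res$t
    out$p[usable] <- res$p
    out$mean_diff[usable] <- colMeans(maps[g == 1, usable, drop = FALSE]) -
      colMeans(maps[g == 0, usable, drop = FALSE])
    out$p_adj[usable] <- if (mc_correction == "fdr")
      stats::p.adjust(res$p, "BH") else res$p
    out$significant <- out$p_adj < alpha
  }
  attr(out, "covariates") <- covariates
  attr(out, "df") <- nrow(X) - ncol(X)
  out
}

#' Per-unit severity regression co-varying age and sex
#'
#' Ordinary least squares z ~ 1 + severity + age + sex, reporting the
#' severity slope, t and two-sided p per unit. By default only patients
#' enter the fit (severity scores of controls are near-floor and would
#' mostly encode group membership).
#'
#' @param maps n x u matrix of per-subject unit values.
#' @param cohort Cohort table with `severity_total` (or `ybocs_total`).
#' @param patients_only Restrict to the patient group (default TRUE).
#' @param positive Patient group level (default `"patient"` if present).
#' @inheritParams group_glm
#' @return data.frame per unit: slope, t, p, p_adj, significant.
#' @export
severity_regression <- function(maps, cohort, patients_only = TRUE,
                                alpha = 0.05,
                                mc_correction = c("none", "fdr"),
                                positive = NULL) {
  mc_correction <- match.arg(mc_correction)
  cohort <- validate_cohort(cohort)
  if (!("severity_total" %in% names(cohort)))
    stopf("cohort lacks a severity_total (or ybocs_total) column")
  if (nrow(maps) != nrow(cohort))
    stopf("%d map rows for %d subjects", nrow(maps), nrow(cohort))
  if (is.null(positive))
    positive <- if ("patient" %in% levels(cohort$group)) "patient"
                else levels(cohort$group)[2]
  keep <- if (patients_only) cohort$group == positive else rep(TRUE, nrow(cohort))
  cohort <- cohort[keep, , drop = FALSE]
  maps <- maps[keep, , drop = FALSE]
  if (any(is.na(cohort$severity_total)))
    stopf("severity_total missing for %d subject(s)",
          sum(is.na(cohort$severity_total)))
  if (stats::sd(cohort$severity_total) == 0)
    stopf("severity_total is constant; slope is not identifiable")
  if (nlevels(droplevels(cohort$sex)) < 2L)
    stopf("rank-deficient design: column sex is constant")
  X <- cbind(intercept = 1, severity = cohort$severity_total,
             age = cohort$age,
             sex = as.numeric(cohort$sex == levels(cohort$sex)[2]))
  usable <- colSums(is.na(maps)) == 0L
  out <- data.frame(unit = seq_len(ncol(maps)), slope = NA_real_,
                    t = NA_real_, p = NA_real_, p_adj = NA_real_,
                    significant = NA)
  if (any(usable)) {
    res <- ols_per_unit(X, maps[, usable, drop = FALSE], term_col = 2L)
    out$slope[usable] <- res$estimate
    out$t[usable] <- res$t
    out$p[usable] <- res$p
    out$p_adj[usable] <- if (mc_correction == "fdr")
      stats::p.adjust(res$p, "BH") else res$p
    out$significant <- out$p_adj < alpha
  }
  attr(out, "df") <- nrow(X) - ncol(X)
  out
}
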