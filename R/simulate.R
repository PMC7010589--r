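# Synthetic cohorts with the statistical structure the classifier assumes:
# two groups of subjects whose ROI time series are drawn from multivariate
# normals sharing a common correlation structure, except on a configurable
# set of "planted" edges whose population correlation is shifted in the
# patient group. A YBOCS-like severity score is linearly coupled to the
# subject's realized planted-edge connectivity.

#' Simulation configuration for a two-group connectome cohort
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param k Number of ROIs (>= 3).
#' @param T Time points per subject; `T > k` is recommended (a warning is
#'   emitted otherwise: sample correlation matrices are singular for T <= k).
#' @param planted_edges Two-column matrix (or list of length-2 vectors) of
#'   ROI index pairs whose population correlation differs between groups.
#' @param effect Target between-group difference in population correlation
#'   on the planted edges, in \[0, 1\].
#' @param noise_sd SD of additive i.i.d. observation noise on the time
#'   series. Default 0: sampling variability alone already perturbs the
#'   correlations, and additive noise attenuates every correlation toward
#'   zero (shrinking the realized effect below the requested one).
#' @param severity_coupling Slope linking the severity score to the
#'   subject's mean planted-edge sample correlation (default 10).
#' @param seed RNG seed; the same config is bit-identical across runs.
#' @param confound_age_sex If TRUE, age and sex distributions differ
#'   between groups (confounded variant); default FALSE (independent).
#' @return A validated `simulation_config` object.
#' @export
simulation_config <- function(n_per_group, k, T, planted_edges = NULL,
                              effect = 0, noise_sd = 0,
                              severity_coupling = 10, seed = 1,
                              confound_age_sex = FALSE) {
  if (!is_scalar_number(n_per_group) || n_per_group < 2)
    stopf("n_per_group must be >= 2")
  if (!is_scalar_number(k) || k < 3) stopf("k must be >= 3")
  if (!is_scalar_number(T) || T < 3) stopf("T must be >= 3")
  if (T <= k) warnf("T = %d <= k = %d: sample FC matrices will be singular; T > k is recommended", T, k)
  if (!is_scalar_number(effect) || effect < 0 || effect > 1)
    stopf("effect must lie in [0, 1]")
  if (!is_scalar_number(noise_sd) || noise_sd < 0) stopf("noise_sd must be >= 0")
  edges <- normalize_edges(planted_edges, k)
  if (effect > 0 && nrow(edges) == 0L)
    stopf("effect > 0 requires at least one planted edge")
  structure(list(n_per_group = as.integer(n_per_group), k = as.integer(k),
                 T = as.integer(T), planted_edges = edges,
                 effect = effect, noise_sd = noise_sd,
                 severity_coupling = severity_coupling,
                 seed = as.integer(seed),
                 confound_age_sex = isTRUE(confound_age_sex)),
            class = "simulation_config")
}

normalize_edges <- function(planted_edges, k) {
  if (is.null(planted_edges)) return(matrix(integer(0), 0, 2,
                                            dimnames = list(NULL, c("i", "j"))))
  if (is.list(planted_edges)) planted_edges <- do.call(rbind, planted_edges)
  edges <- matrix(as.integer(planted_edges), ncol = 2)
  if (any(edges < 1 | edges > k))
    stopf("planted edge index out of range 1..%d", k)
  if (any(edges[, 1] == edges[, 2]))
    stopf("planted edges must join two distinct ROIs")
  edges <- t(apply(edges, 1L, sort))
  if (anyDuplicated(edges)) stopf("duplicated planted edge")
  colnames(edges) <- c("i", "j")
  edges
}

# Random base correlation matrix: Wishart draw with df = 2k rescaled to
# unit diagonal. Moderately heterogeneous off-diagonals (|r| mostly < 0.5)
# and well-conditioned, so planting modest shifts rarely needs repair.
base_correlation <- function(k) {
  W <- stats::rWishart(1L, df = 2L * k, Sigma = diag(k))[, , 1L]
  stats::cov2cor(W)
}

# Shift planted edges by `effect` and repair to a valid correlation matrix:
# eigenvalues clipped at 1e-6, diagonal renormalized.
plant_edges <- function(R, edges, effect) {
  R1 <- R
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    r <- R1[i, j] + effect
    if (abs(r) > 1)
      stopf("planted edge (%d, %d): shifted correlation %.3f lies outside [-1, 1]; reduce effect",
            i, j, r)
    R1[i, j] <- R1[j, i] <- r
  }
  e <- eigen(R1, symmetric = TRUE)
  if (min(e$values) < 1e-6) {
    vals <- pmax(e$values, 1e-6)
    R1 <- e$vectors %*% (vals * t(e$vectors))
    R1 <- stats::cov2cor((R1 + t(R1)) / 2)
  }
  R1
}

#' Simulate a two-group cohort of ROI time series
#'
#' Controls are drawn from a multivariate normal with a random base
#' correlation matrix; patients from the same matrix with the planted edges
#' shifted by `effect` (repaired to a valid correlation matrix). Severity
#' is `baseline + severity_coupling * (mean planted-edge sample r, centered
#' within group) + noise`, scaled to a YBOCS-like range (patients
#' ~ 25 +/- 7, controls ~ 2.4 +/- 2.9, clipped at 0). Centering keeps the
#' baseline on that scale for any coupling strength.
#'
#' @param config A [simulation_config()].
#' @return List with elements `series` (named list of T x k matrices),
#'   `cohort` (data.frame: subject_id, group, age, sex, severity_total),
#'   `population` (list with the two generating correlation matrices and
#'   the planted edges), and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  local_seed(config$seed, {
    k <- config$k; n <- config$n_per_group; Tt <- config$T
    R_control <- base_correlation(k)
    R_patient <- if (config$effect > 0)
      plant_edges(R_control, config$planted_edges, config$effect) else R_control
    chol_c <- chol(R_control); chol_p <- chol(R_patient)
    ids <- sprintf("sub%03d", seq_len(2L * n))
    group <- rep(c("control", "patient"), each = n)
    series <- vector("list", 2L * n)
    for (s in seq_len(2L * n)) {
      Z <- matrix(stats::rnorm(Tt * k), Tt, k)
      X <- Z %*% (if (group[s] == "patient") chol_p else chol_c)
      if (config$noise_sd > 0)
        X <- X + matrix(stats::rnorm(Tt * k, sd = config$noise_sd), Tt, k)
      series[[s]] <- X
    }
    names(series) <- ids
    if (config$confound_age_sex) {
      age <- ifelse(group == "patient",
                    stats::rnorm(2L * n, 26.1, 8.1), stats::rnorm(2L * n, 21.3, 5.0))
      sex <- ifelse(stats::runif(2L * n) < ifelse(group == "patient", 0.58, 0.60),
                    "M", "F")
    } else {
      age <- stats::rnorm(2L * n, 24, 7)
      sex <- ifelse(stats::runif(2L * n) < 0.55, "M", "F")
    }
    age <- round(pmin(pmax(age, 18), 59), 1)
    mean_planted <- if (nrow(config$planted_edges) > 0)
      vapply(series, function(X) {
        C <- stats::cor(X)
        mean(C[config$planted_edges])
      }, numeric(1))
    else rep(0, 2L * n)
    baseline <- ifelse(group == "patient", 25, 2.4)
    sev_noise <- ifelse(group == "patient", 7, 2.9)
    # coupling covariate centered within group so the baseline stays on the
    # YBOCS scale (and the 0-floor stays inactive) at any coupling strength
    planted_dev <- mean_planted -
      stats::ave(mean_planted, group, FUN = mean)
    severity <- baseline + config$severity_coupling * planted_dev +
      stats::rnorm(2L * n, 0, sev_noise)
    severity <- round(pmax(severity, 0), 1)
    cohort <- data.frame(subject_id = ids, group = factor(group),
                         age = age, sex = factor(sex),
                         severity_total = severity,
                         stringsAsFactors = FALSE)
    list(series = series, cohort = cohort,
         population = list(control = R_control, patient = R_patient,
                           planted_edges = config$planted_edges),
         config = config)
  })
}

#' Simulate null per-unit z-maps with random covariates
#'
#' A test harness for covariate-adjusted group statistics: per-subject
#' unit-wise values i.i.d. N(0, 1), group labels assigned independently of
#' the data, random age and sex.
#'
#' @param n_subjects Number of subjects (>= 8; split evenly into groups).
#' @param n_units Number of units (ROIs or grid cells) per subject.
#' @param seed RNG seed.
#' @return List with `maps` (n_subjects x n_units matrix) and `cohort`.
#' @export
simulate_null_maps <- function(n_subjects, n_units, seed = 1) {
  if (!is_scalar_number(n_subjects) || n_subjects < 8)
    stopf("n_subjects must be >= 8")
  if (!is_scalar_number(n_units) || n_units < 1) stopf("n_units must be >= 1")
  local_seed(seed, {
    n <- as.integer(n_subjects)
    maps <- matrix(stats::rnorm(n * n_units), n, n_units,
                   dimnames = list(sprintf("sub%03d", seq_len(n)), NULL))
    cohort <- data.frame(
      subject_id = rownames(maps),
      group = factor(rep(c("control", "patient"), length.out = n)),
      age = round(stats::rnorm(n, 24, 7), 1),
      sex = factor(ifelse(stats::runif(n) < 0.5, "M", "F")),
      stringsAsFactors = FALSE)
    list(maps = maps, cohort = cohort)
  })
}

#' Write a simulated cohort to disk in the package's exchange format
#'
#' One tab-delimited time-series file per subject (T rows, k columns) plus
#' `phenotypes.csv`.
#'
#' @param sim Result of [simulate_cohort()].
#' @param dir Output directory.
#' @param what `"series"` writes raw time series; `"fc"` writes Pearson FC
#'   matrices instead.
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(sim, dir, what = c("fc", "series")) {
  what <- match.arg(what)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (what == "fc") {
    mats <- lapply(sim$series, fc_from_timeseries)
    write_matrices(mats, dir, ids = names(sim$series))
  } else {
    for (id in names(sim$series))
      utils::write.table(format(sim$series[[id]], digits = 15, trim = TRUE),
                         file.path(dir, paste0(id, ".txt")), sep = "\t",
                         quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  ph <- sim$cohort
  names(ph)[names(ph) == "severity_total"] <- "ybocs_total"
  utils::write.csv(ph, file.path(dir, "phenotypes.csv"), row.names = FALSE)
  invisible(dir)
}
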