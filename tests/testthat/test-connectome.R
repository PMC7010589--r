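test_that("fc_from_timeseries matches hand-checkable correlation structure", {
  t <- seq_len(40)
  x <- rnorm(40)
  S <- cbind(a = x, b = 2 * x + 3, c = -x)
  A <- fc_from_timeseries(S)
  expect_equal(A$values["a", "b"], 1)
  expect_equal(A$values["a", "c"], -1)
  expect_equal(diag(A$values), c(a = 1, b = 1, c = 1))

  # quadrature pair over whole periods is orthogonal
  ph <- 2 * pi * (seq_len(64) - 1) / 64
  Q <- fc_from_timeseries(cbind(sin(ph), cos(ph), rnorm(64)))
  expect_lt(abs(Q$values[1, 2]), 1e-10)
})

test_that("constant ROI columns are rejected by name", {
  S <- cbind(x = rnorm(20), flat = rep(2, 20), y = rnorm(20))
  expect_error(fc_from_timeseries(S), "flat")
  expect_error(fc_from_timeseries(matrix(rnorm(4), 2, 2)), "3 time points")
})

test_that("graph Laplacian matches hand evaluation and removes self-loops", {
  A2 <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  expect_equal(unclass(graph_laplacian(A2))[1:2, 1:2],
               matrix(c(0.5, -0.5, -0.5, 0.5), 2), ignore_attr = TRUE)
  expect_equal(graph_laplacian(diag(3))[1:3, 1:3],
               matrix(0, 3, 3), ignore_attr = TRUE)
  # chain 1-2 (0.2), 2-3 (0.4)
  A3 <- diag(3); A3[1, 2] <- A3[2, 1] <- 0.2; A3[2, 3] <- A3[3, 2] <- 0.4
  L3 <- graph_laplacian(A3)
  expect_equal(diag(L3), c(0.2, 0.6, 0.4))
  expect_equal(L3[1, 2], -0.2); expect_equal(L3[2, 3], -0.4)
  # negative weights: abs vs clip
  An <- diag(2); An[1, 2] <- An[2, 1] <- -0.3
  expect_equal(graph_laplacian(An, "abs")[1, 1], 0.3)
  expect_equal(graph_laplacian(An, "clip_negative")[1, 1], 0)
})

test_that("graph Laplacians are PSD with zero row sums for any FC input", {
  set.seed(31)
  for (rep in 1:10) {
    S <- matrix(rnorm(30 * 7), 30, 7)
    L <- graph_laplacian(fc_from_timeseries(S))
    expect_lt(max(abs(rowSums(L))), 1e-10)
    expect_gt(min(eigen(L, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  }
})

test_that("regularization shifts the spectrum by exactly gamma", {
  L2 <- matrix(c(0.5, -0.5, -0.5, 0.5), 2)
  R <- regularize_laplacian(L2, gamma = 1)
  expect_equal(R$values, matrix(c(1.5, -0.5, -0.5, 1.5), 2))
  expect_equal(sort(eigen(R$values, only.values = TRUE)$values), c(1, 2))
  expect_equal(regularize_laplacian(matrix(0, 3, 3), 1)$values, diag(3))
  set.seed(4)
  L <- graph_laplacian(fc_from_timeseries(matrix(rnorm(200), 40, 5)))
  ev0 <- min(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  ev1 <- min(eigen(regularize_laplacian(L, 2.5)$values,
                   symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(ev1, ev0 + 2.5, tolerance = 1e-10)
  expect_error(regularize_laplacian(L, 0), "gamma")
  expect_error(regularize_laplacian(L, -1), "gamma")
})

test_that("matrix log/exp are mutually inverse on the SPD cone", {
  expect_equal(matrix_log(diag(3)), matrix(0, 3, 3))
  expect_equal(matrix_log(diag(c(1, 2))), diag(c(0, log(2))))
  set.seed(9)
  for (rep in 1:20) {
    S <- random_spd(6)
    expect_equal(matrix_exp(matrix_log(S)), S, tolerance = 1e-8)
  }
  M <- diag(2); M[1, 1] <- -0.5
  expect_error(matrix_log(M), "smallest eigenvalue")
})

test_that("log-Euclidean distance is a metric with known closed forms", {
  S <- random_spd(5)
  expect_equal(log_euclidean_distance(S, S), 0)
  expect_equal(log_euclidean_distance(2 * diag(2), diag(2)),
               sqrt(2) * log(2), tolerance = 1e-12)
  expect_error(log_euclidean_distance(diag(2), diag(3)), "dimension")
  set.seed(12)
  for (rep in 1:30) {
    A <- random_spd(5); B <- random_spd(5); C <- random_spd(5)
    dab <- log_euclidean_distance(A, B)
    expect_equal(dab, log_euclidean_distance(B, A))
    expect_lte(dab,
               log_euclidean_distance(A, C) + log_euclidean_distance(C, B) + 1e-9)
  }
})

test_that("the FC -> Laplacian -> regularize pipeline always admits a log", {
  set.seed(21)
  for (rep in 1:10) {
    A <- fc_from_timeseries(matrix(rnorm(50 * 8), 50, 8))
    for (wt in c("abs", "clip_negative")) {
      R <- laplacian_from_fc(A, gamma = 0.5, weight_transform = wt)
      expect_true(is.matrix(matrix_log(R$values)))
    }
  }
})

test_that("matrix round-trip through text files is faithful to 12 digits", {
  set.seed(8)
  mats <- lapply(1:3, function(i) fc_from_timeseries(matrix(rnorm(120), 30, 4)))
  d <- withr::local_tempdir()
  write_matrices(mats, d, ids = c("s1", "s2", "s3"))
  back <- read_matrices(d)
  expect_identical(names(back), c("s1", "s2", "s3"))
  for (i in 1:3)
    expect_equal(back[[i]]$values, mats[[i]]$values, tolerance = 1e-12)
})

test_that("malformed matrix and phenotype files fail with diagnostics", {
  d <- withr::local_tempdir()
  V <- diag(3); V[1, 2] <- 0.5; V[2, 1] <- 0.1
  utils::write.table(V, file.path(d, "bad.txt"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  expect_error(read_matrices(d), "asymmetric")
  expect_error(read_matrices(withr::local_tempdir()), "no matrix files")

  f <- file.path(withr::local_tempdir(), "ph.csv")
  utils::write.csv(data.frame(subject_id = c("a", "b"), age = c(20, 30),
                              sex = c("M", "F")), f, row.names = FALSE)
  expect_error(read_phenotypes(f), "group")
  utils::write.csv(data.frame(subject_id = c("a", "a"),
                              group = c("patient", "control"),
                              age = c(20, 30), sex = c("M", "F")),
                   f, row.names = FALSE)
  expect_error(read_phenotypes(f), "duplicated")
})

test_that("AAL metadata covers 116 ROIs with three cerebellar lobes", {
  df <- aal_labels()
  expect_equal(nrow(df), 116)
  expect_equal(sum(!is.na(df$lobe)), 26)
  seeds <- cerebellar_seeds()
  expect_named(seeds, c("flocculonodular", "anterior", "posterior"))
  expect_equal(sort(unlist(seeds, use.names = FALSE)), 91:116)
})
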