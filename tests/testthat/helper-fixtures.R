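# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files.

# Random SPD matrix: shifted Gram matrix of a Gaussian draw.
random_spd <- function(k, jitter = 0.5) {
  A <- matrix(rnorm(k * k), k, k)
  crossprod(A) / k + jitter * diag(k)
}

# A list of regularized Laplacians from a small simulated cohort.
sim_laplacians <- function(n_per_group = 5, k = 8, T = 60, seed = 1,
                           gamma = 1, effect = 0, edges = NULL) {
  sim <- simulate_cohort(simulation_config(
    n_per_group = n_per_group, k = k, T = T, seed = seed,
    planted_edges = edges, effect = effect))
  fc <- lapply(sim$series, fc_from_timeseries)
  list(sim = sim, fc = fc,
       lap = lapply(fc, laplacian_from_fc, gamma = gamma))
}

# The planted-edge study cohort used by the end-to-end checks.
planted_edges_default <- cbind(c(1, 3, 5, 7, 9), c(2, 4, 6, 8, 10))

planted_cohort <- function(seed, effect = 0.3, n_per_group = 60, k = 20,
                           T = 300, severity_coupling = 10) {
  sim <- simulate_cohort(simulation_config(
    n_per_group = n_per_group, k = k, T = T,
    planted_edges = planted_edges_default, effect = effect,
    severity_coupling = severity_coupling, seed = seed))
  sim$fc <- lapply(sim$series, fc_from_timeseries)
  sim
}

count_planted_hits <- function(edge_table, edges = planted_edges_default) {
  sum(apply(edge_table[, c("i", "j")], 1L, function(e)
    any(edges[, 1] == e[1] & edges[, 2] == e[2])))
}
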