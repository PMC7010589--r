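# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All user-facing stochastic operations route through this so
# that a given seed yields bit-identical output regardless of call order.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Symmetrize before any eigendecomposition; reject if the asymmetry is
# beyond `tol` (callers pass the tolerance appropriate to their contract).
check_symmetric <- function(S, tol = 1e-10, what = "matrix") {
  if (!is.matrix(S) || !is.numeric(S) || nrow(S) != ncol(S))
    stopf("%s must be a square numeric matrix", what)
  if (any(!is.finite(S)))
    stopf("%s contains missing or non-finite entries", what)
  asym <- max(abs(S - t(S)))
  if (asym > tol)
    stopf("%s is not symmetric: max |S - t(S)| = %.3g exceeds tolerance %.3g",
          what, asym, tol)
  (S + t(S)) / 2
}

# Vectorize the upper triangle (i < j) of a square matrix; the canonical
# edge ordering used for linear/Gaussian baselines and edge tables.
upper_tri_vec <- function(S) S[upper.tri(S)]

# Index pairs (i, j), i < j, in the same order as upper_tri_vec().
upper_tri_pairs <- function(k) {
  m <- diag(k)
  cbind(i = row(m)[upper.tri(m)], j = col(m)[upper.tri(m)])
}
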