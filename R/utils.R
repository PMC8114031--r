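#' @keywords internal
"_PACKAGE"

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic child seed for a (parent seed, index) pair; stays < 2^31 - 1.
# Multiplications stay below 2^53 so double arithmetic is exact.
child_seed <- function(seed, index) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m)
  as.integer((((s * 48271) %% m) + (as.numeric(index) * 7919)) %% m)
}

# Pairwise correlation distance (1 - Pearson r) between rows of `values`,
# with deterministic conventions for zero-variance rows: two constant rows are
# at distance 0 if identical and 1 otherwise; a constant row is at distance 1
# from any non-constant row.
correlation_distances <- function(values) {
  n <- nrow(values)
  sds <- apply(values, 1, stats::sd)
  constant <- sds == 0 | !is.finite(sds)
  d <- matrix(1, n, n)
  if (any(!constant)) {
    r <- suppressWarnings(stats::cor(t(values[!constant, , drop = FALSE])))
    d[!constant, !constant] <- 1 - r
  }
  if (any(constant)) {
    idx <- which(constant)
    for (i in idx) {
      same <- vapply(idx, function(j) {
        isTRUE(all.equal(values[i, ], values[j, ], tolerance = 0))
      }, logical(1))
      d[i, idx] <- ifelse(same, 0, 1)
    }
  }
  diag(d) <- 0
  # numerical guard: correlations can stray beyond [-1, 1] by eps
  d[d < 0] <- 0
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a
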