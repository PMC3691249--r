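# Programmatic fixtures shared across test files.

# Planted-signal expression matrix: first `k` features shifted by `effect`
# in the case columns; everything else pure noise.
plantedMatrix <- function(p, k, n1, n0, effect, seed, noise_sd = 1) {
  set.seed(seed)
  n <- n1 + n0
  x <- matrix(rnorm(p * n, sd = noise_sd), p, n,
              dimnames = list(sprintf("f%04d", seq_len(p)),
                              sprintf("s%04d", seq_len(n))))
  y <- rep(c(TRUE, FALSE), c(n1, n0))
  if (k > 0) x[seq_len(k), y] <- x[seq_len(k), y] + effect
  list(x = x, y = y, informative = rownames(x)[seq_len(k)])
}

# Small simulated cohort for pipeline-level tests.
smallSimConfig <- function(seed = 42, ...) {
  args <- modifyList(
    list(n_features = 600L, n_informative = 15L, n_cases = 60L,
         n_ned = 30L, n_psa = 30L, n_batches = 5L, n_tech_reps = 5L,
         seed = seed),
    list(...))
  do.call(simConfig, args)
}

fastSelection <- function(...) {
  args <- modifyList(list(n_boot = 40L, seed = 1L), list(...))
  do.call(selectionConfig, args)
}

fastForest <- function(...) {
  args <- modifyList(
    list(n_trees = 100L, cv_folds = 5L, tune_boot = 5L,
         nodesize_grid = c(1L, 5L), seed = 1L),
    list(...))
  do.call(forestConfig, args)
}
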