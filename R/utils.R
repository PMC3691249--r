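## Internal helpers: seeded evaluation and small numeric utilities.

#' @importFrom stats rnorm rbinom runif rexp var quantile qnorm pnorm pchisq
#'   pt sd median predict coef glm binomial rmultinom setNames complete.cases
#'   lm anova
NULL

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
## afterwards so that exported functions are pure in (inputs, seed).
.withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

## Deterministic sub-seed for a named random substream. All randomness in the
## package flows from one master seed through these; offsets keep substreams
## (bootstraps, folds, forests) independent while staying in 32-bit range.
.subSeed <- function(seed, offset) {
  as.integer((as.double(seed) + as.double(offset)) %% 2147483587L)
}

## Row variances of a matrix (no matrixStats dependency).
.rowVars <- function(x) {
  n <- ncol(x)
  if (n < 2L) stop("need at least 2 columns to compute a variance")
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}

## Stratified with-replacement resample of sample indices, preserving the
## number of cases and controls.
.stratifiedResample <- function(is_case) {
  idx_case <- which(is_case)
  idx_ctrl <- which(!is_case)
  c(sample(idx_case, length(idx_case), replace = TRUE),
    sample(idx_ctrl, length(idx_ctrl), replace = TRUE))
}

## Fold assignment for k-fold CV, stratified by class.
.cvFolds <- function(is_case, k) {
  fold <- integer(length(is_case))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(is_case == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

## MD5 fingerprint of an arbitrary R object (used for the pipeline manifest).
.fingerprint <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2L)
  close(con)
  unname(tools::md5sum(f))
}

.assertFraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single value in [0, 1]", name))
  invisible(x)
}

.assertCount <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min))
  invisible(as.integer(x))
}
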