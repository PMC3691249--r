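#' Per-feature t-test filter
#'
#' First-stage complexity reduction: each feature is tested for a
#' case-vs-control mean difference with a two-sided two-sample t-test
#' (Welch by default), and features with p below the threshold are retained.
#' No multiplicity adjustment is applied at this stage; the filter only
#' reduces the candidate space for the stability-selection stage.
#'
#' Features with zero variance in both classes have an undefined t statistic
#' and are excluded with a warning.
#'
#' @param x a [MetCohort-class] or expression matrix (features x samples).
#' @param is_case logical case indicator per sample; taken from the cohort
#'   annotation when `x` is a `MetCohort`.
#' @param p_threshold two-sided p-value threshold (default 0.01).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return Character vector of retained feature ids.
#' @export
tFilter <- function(x, is_case = NULL, p_threshold = 0.01,
                    var_equal = FALSE) {
  m <- .asExprs(x)
  if (is(x, "MetCohort") && is.null(is_case)) is_case <- isCase(x)
  is_case <- as.logical(is_case)
  if (sum(is_case) < 2L || sum(!is_case) < 2L)
    stop("both classes need at least 2 samples for a t-test")
  .assertFraction(p_threshold, "p_threshold")

  p <- .rowWelchP(m, is_case, var_equal = var_equal)
  if (anyNA(p)) {
    warning(sum(is.na(p)), " feature(s) with degenerate (zero) variance ",
            "in both classes were excluded from the t-filter")
  }
  rownames(m)[!is.na(p) & p < p_threshold]
}

## Vectorized two-sample t-test p-values over matrix rows.
.rowWelchP <- function(m, is_case, var_equal = FALSE) {
  x1 <- m[, is_case, drop = FALSE]
  x0 <- m[, !is_case, drop = FALSE]
  n1 <- ncol(x1); n0 <- ncol(x0)
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  v1 <- .rowVars(x1); v0 <- .rowVars(x0)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n0)
    df <- rep(n1 + n0 - 2, length(se2))
  } else {
    se2 <- v1 / n1 + v0 / n0
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  }
  tt <- (m1 - m0) / sqrt(se2)
  p <- 2 * pt(abs(tt), df = df, lower.tail = FALSE)
  p[se2 == 0] <- NA_real_
  p
}

#' Selection configuration
#'
#' @param t_p_threshold t-filter p-value threshold (default 0.01).
#' @param alpha elastic-net mixing parameter in `[0, 1]` (default 0.5;
#'   1 = lasso, 0 = ridge).
#' @param n_boot number of bootstrap rounds (default 1000).
#' @param tally_threshold selection-frequency threshold: features selected in
#'   at least this fraction of rounds survive (default 0.25).
#' @param cv_folds folds for the internal penalty-strength cross-validation
#'   within each bootstrap round (default 5).
#' @param tune_per_resample re-tune the penalty strength on every bootstrap
#'   resample (default `TRUE`); when `FALSE` a single penalty is chosen once
#'   on the full training data and reused.
#' @param seed master seed for the bootstrap substreams.
#' @return A named list of class `"SelectionConfig"`.
#' @export
selectionConfig <- function(t_p_threshold = 0.01, alpha = 0.5,
                            n_boot = 1000L, tally_threshold = 0.25,
                            cv_folds = 5L, tune_per_resample = TRUE,
                            seed = 1L) {
  stopifnot(t_p_threshold > 0, t_p_threshold <= 1,
            alpha >= 0, alpha <= 1,
            tally_threshold > 0, tally_threshold <= 1)
  structure(list(t_p_threshold = t_p_threshold, alpha = alpha,
                 n_boot = .assertCount(n_boot, "n_boot", 1L),
                 tally_threshold = tally_threshold,
                 cv_folds = .assertCount(cv_folds, "cv_folds", 3L),
                 tune_per_resample = isTRUE(tune_per_resample),
                 seed = .assertCount(seed, "seed", 0L)),
            class = "SelectionConfig")
}

#' Bootstrapped elastic-net stability selection
#'
#' Second-stage feature selection. For each of `n_boot` bootstrap rounds a
#' class-stratified resample of the samples (size n, with replacement) is
#' drawn, an elastic-net-penalized logistic regression of case status on all
#' candidate features is fitted at mixing parameter `alpha` with the penalty
#' strength chosen by internal cross-validation on that resample, and every
#' feature with a nonzero coefficient (exact zero from the solver's active
#' set) has its tally incremented. Features selected in at least
#' `tally_threshold` of the rounds survive.
#'
#' Rounds in which the solver fails are skipped and counted; a warning is
#' emitted if more than 1% of rounds were skipped.
#'
#' @param x a [MetCohort-class] or expression matrix restricted to the
#'   t-filter survivors (features x samples).
#' @param is_case logical case indicator; from the cohort annotation when
#'   `x` is a `MetCohort`.
#' @param config a `SelectionConfig` from [selectionConfig()].
#' @return A [StabilityResult-class].
#' @export
stabilitySelect <- function(x, is_case = NULL, config = selectionConfig()) {
  m <- .asExprs(x)
  if (is(x, "MetCohort") && is.null(is_case)) is_case <- isCase(x)
  is_case <- as.logical(is_case)
  stopifnot(inherits(config, "SelectionConfig"))
  if (sum(is_case) < 2L || sum(!is_case) < 2L)
    stop("both classes need at least 2 samples")
  if (nrow(m) < 2L)
    stop("need at least 2 candidate features")

  xt <- t(m)  # glmnet wants samples x features
  y <- as.integer(is_case)
  tally <- setNames(integer(nrow(m)), rownames(m))
  n_skipped <- 0L

  fixed_lambda <- NULL
  if (!config$tune_per_resample) {
    fixed_lambda <- .withSeed(.subSeed(config$seed, 15485863L), {
      cv <- glmnet::cv.glmnet(xt, y, family = "binomial",
                              alpha = config$alpha,
                              nfolds = config$cv_folds)
      cv$lambda.min
    })
  }

  for (b in seq_len(config$n_boot)) {
    res <- .withSeed(.subSeed(config$seed, b), {
      idx <- .stratifiedResample(is_case)
      tryCatch({
        if (is.null(fixed_lambda)) {
          cv <- glmnet::cv.glmnet(xt[idx, , drop = FALSE], y[idx],
                                  family = "binomial", alpha = config$alpha,
                                  nfolds = config$cv_folds)
          beta <- coef(cv, s = "lambda.min")
        } else {
          fit <- glmnet::glmnet(xt[idx, , drop = FALSE], y[idx],
                                family = "binomial", alpha = config$alpha)
          beta <- coef(fit, s = fixed_lambda)
        }
        as.numeric(beta)[-1L] != 0  # drop intercept; exact-zero test
      }, error = function(e) NULL)
    })
    if (is.null(res)) n_skipped <- n_skipped + 1L
    else tally <- tally + res
  }
  if (n_skipped > 0.01 * config$n_boot)
    warning(n_skipped, " of ", config$n_boot,
            " bootstrap rounds were skipped for solver failure")

  selected <- names(tally)[tally / config$n_boot >= config$tally_threshold]
  new("StabilityResult", tally = tally, nBoot = config$n_boot,
      threshold = config$tally_threshold, selected = selected,
      tPass = rownames(m), nSkipped = n_skipped)
}
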