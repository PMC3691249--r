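#' Random-forest configuration
#'
#' @param n_trees trees per forest (default 1000).
#' @param mtry_grid candidate `mtry` values for the tuning grid; `NULL`
#'   (default) expands to `{1, ceil(sqrt(p)), ceil(p/3), ceil(p/2), p}`
#'   clipped to `[1, p]` at tuning time.
#' @param nodesize_grid candidate minimum terminal-node sizes
#'   (default `c(1, 2, 5, 10, 20)`).
#' @param cv_folds folds for the elimination curve's cross-validated MSE
#'   (default 10).
#' @param drop_frac fraction of lowest-Gini features dropped per elimination
#'   round (default 0.10; at least one feature is always dropped).
#' @param tune_boot random train/test splits per tuning grid cell
#'   (default 1000).
#' @param tune_train_frac fraction of the training samples used to fit within
#'   each tuning split (default 1/3; the remaining 2/3 score accuracy).
#' @param seed master seed for fold, split and forest substreams.
#' @return A named list of class `"ForestConfig"`.
#' @export
forestConfig <- function(n_trees = 1000L, mtry_grid = NULL,
                         nodesize_grid = c(1L, 2L, 5L, 10L, 20L),
                         cv_folds = 10L, drop_frac = 0.10,
                         tune_boot = 1000L, tune_train_frac = 1 / 3,
                         seed = 1L) {
  stopifnot(drop_frac > 0, drop_frac < 1,
            tune_train_frac > 0, tune_train_frac < 1,
            length(nodesize_grid) >= 1L)
  structure(list(n_trees = .assertCount(n_trees, "n_trees", 1L),
                 mtry_grid = mtry_grid,
                 nodesize_grid = as.integer(nodesize_grid),
                 cv_folds = .assertCount(cv_folds, "cv_folds", 2L),
                 drop_frac = drop_frac,
                 tune_boot = .assertCount(tune_boot, "tune_boot", 1L),
                 tune_train_frac = tune_train_frac,
                 seed = .assertCount(seed, "seed", 0L)),
            class = "ForestConfig")
}

.defaultMtryGrid <- function(p) {
  sort(unique(pmin(pmax(
    c(1L, ceiling(sqrt(p)), ceiling(p / 3), ceiling(p / 2), p), 1L), p)))
}

## One seeded forest fit; y as factor for classification forests.
.fitForest <- function(xt, y, ntree, mtry = NULL, nodesize = 1L, seed = 1L) {
  .withSeed(seed, {
    args <- list(x = xt, y = factor(y, levels = c(0L, 1L)), ntree = ntree,
                 nodesize = nodesize)
    if (!is.null(mtry)) args$mtry <- mtry
    do.call(randomForest::randomForest, args)
  })
}

.forestProb <- function(fit, xt) {
  unname(predict(fit, xt, type = "prob")[, "1"])
}

## k-fold cross-validated Brier score: mean squared difference between the
## out-of-fold case probability and the 0/1 label.
.cvBrier <- function(xt, y, features, cfg, seed) {
  k <- min(cfg$cv_folds, sum(y == 1L), sum(y == 0L))
  folds <- .withSeed(seed, .cvFolds(y == 1L, k))
  pred <- numeric(length(y))
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- .fitForest(xt[tr, features, drop = FALSE], y[tr],
                      ntree = cfg$n_trees, seed = .subSeed(seed, f))
    pred[!tr] <- .forestProb(fit, xt[!tr, features, drop = FALSE])
  }
  mean((pred - y)^2)
}

#' Gini-ranked backward elimination
#'
#' Final feature-set optimization for the genomic classifier. Starting from
#' the stability-selection survivors, a random forest is fitted on the
#' current feature set, the k-fold cross-validated mean squared error
#' (Brier score of out-of-fold case probabilities against the 0/1 label) is
#' recorded, and the `drop_frac` of features with the lowest mean-decrease-
#' Gini importance (at least one) is removed; this repeats until a single
#' feature remains. The chosen model size minimizes the cross-validated MSE,
#' with ties broken toward the smaller size — the knee of the error curve.
#'
#' @param x a [MetCohort-class] or expression matrix (features x samples).
#' @param is_case logical case indicator; from the annotation for a cohort.
#' @param candidates character vector of candidate feature ids (at least 2).
#' @param config a `ForestConfig` from [forestConfig()].
#' @return An [EliminationCurve-class].
#' @export
backwardEliminate <- function(x, is_case = NULL, candidates,
                              config = forestConfig()) {
  m <- .asExprs(x)
  if (is(x, "MetCohort") && is.null(is_case)) is_case <- isCase(x)
  y <- as.integer(as.logical(is_case))
  if (length(candidates) < 1L) stop("no candidate features")
  if (!all(candidates %in% rownames(m)))
    stop("candidates absent from the expression matrix: ",
         paste(utils::head(setdiff(candidates, rownames(m)), 5L),
               collapse = ", "))
  if (length(candidates) < 2L)
    stop("backward elimination needs at least 2 candidates")

  xt <- t(m[candidates, , drop = FALSE])
  current <- candidates
  sizes <- integer(0)
  mses <- numeric(0)
  surviving <- list()
  round <- 0L
  repeat {
    round <- round + 1L
    sizes <- c(sizes, length(current))
    surviving[[round]] <- current
    mses <- c(mses, .cvBrier(xt, y, current, config,
                             seed = .subSeed(config$seed, 1000L * round)))
    if (length(current) == 1L) break
    fit <- .fitForest(xt[, current, drop = FALSE], y,
                      ntree = config$n_trees,
                      seed = .subSeed(config$seed, 1000L * round + 500L))
    gini <- randomForest::importance(fit, type = 2L)[, 1L]
    n_drop <- max(1L, floor(config$drop_frac * length(current)))
    ## rank ascending by importance; order() index tie-break keeps the
    ## elimination deterministic
    drop <- names(sort(gini, method = "radix"))[seq_len(n_drop)]
    current <- setdiff(current, drop)
  }
  best <- which(mses == min(mses))
  best <- best[which.min(sizes[best])]  # tie -> smaller size
  new("EliminationCurve", sizes = sizes, cvMSE = mses,
      chosenSize = sizes[best],
      chosenFeatures = surviving[[best]])
}

#' Grid-search tuning of forest hyperparameters
#'
#' Accuracy-optimizing grid search over `mtry` and `nodesize`. For each grid
#' cell the training samples are repeatedly split (`tune_boot` times) into a
#' `tune_train_frac` fitting part and a held-out part; a forest is fitted and
#' held-out accuracy at the 0.5 score threshold is averaged. The cell with
#' the highest mean accuracy wins; ties break toward smaller `nodesize`,
#' then smaller `mtry`.
#'
#' @inheritParams backwardEliminate
#' @param features feature ids of the final marker set.
#' @return A list with elements `mtry`, `nodesize` and the grid of mean
#'   accuracies (`accuracy` data.frame).
#' @export
tuneForest <- function(x, is_case = NULL, features,
                       config = forestConfig()) {
  m <- .asExprs(x)
  if (is(x, "MetCohort") && is.null(is_case)) is_case <- isCase(x)
  y <- as.integer(as.logical(is_case))
  if (length(features) < 1L) stop("no features to tune on")
  xt <- t(m[features, , drop = FALSE])
  p <- length(features)
  mtry_grid <- if (is.null(config$mtry_grid)) .defaultMtryGrid(p)
  else as.integer(config$mtry_grid)
  bad <- mtry_grid > p
  if (any(bad)) {
    warning("skipping mtry values exceeding the feature count: ",
            paste(mtry_grid[bad], collapse = ", "))
    mtry_grid <- mtry_grid[!bad]
  }
  if (!length(mtry_grid)) stop("no usable mtry values in the grid")

  grid <- expand.grid(mtry = mtry_grid, nodesize = config$nodesize_grid)
  n <- length(y)
  n_tr <- max(2L, round(config$tune_train_frac * n))
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    hits <- numeric(config$tune_boot)
    for (b in seq_len(config$tune_boot)) {
      seed_b <- .subSeed(config$seed, 7000L + b)
      idx <- .withSeed(seed_b, {
        ## stratified split keeps both classes in the fitting part
        tr <- c(sample(which(y == 1L),
                       max(1L, round(config$tune_train_frac * sum(y == 1L)))),
                sample(which(y == 0L),
                       max(1L, round(config$tune_train_frac * sum(y == 0L)))))
        tr
      })
      fit <- .fitForest(xt[idx, , drop = FALSE], y[idx],
                        ntree = config$n_trees, mtry = grid$mtry[g],
                        nodesize = grid$nodesize[g],
                        seed = .subSeed(seed_b, 13L * g))
      prob <- .forestProb(fit, xt[-idx, , drop = FALSE])
      hits[b] <- mean((prob > 0.5) == (y[-idx] == 1L))
    }
    acc[g] <- mean(hits)
  }
  ## argmax with deterministic tie-break: smaller nodesize, then smaller mtry
  ord <- order(-acc, grid$nodesize, grid$mtry)
  best <- ord[1L]
  list(mtry = as.integer(grid$mtry[best]),
       nodesize = as.integer(grid$nodesize[best]),
       accuracy = cbind(grid, accuracy = acc))
}

#' Train the genomic classifier
#'
#' Fits the final probability random forest on the training samples over the
#' chosen marker set with the tuned hyperparameters. The score of a sample
#' is the fraction of trees voting "case", a continuous value in `[0, 1]`
#' where higher means higher predicted probability of early clinical
#' metastasis.
#'
#' @inheritParams tuneForest
#' @param mtry,nodesize tuned hyperparameters (e.g. from [tuneForest()]).
#' @return A [GCModel-class].
#' @export
trainGC <- function(x, is_case = NULL, features, mtry, nodesize,
                    config = forestConfig()) {
  m <- .asExprs(x)
  if (is(x, "MetCohort") && is.null(is_case)) is_case <- isCase(x)
  y <- as.integer(as.logical(is_case))
  if (length(unique(y)) < 2L)
    stop("both classes must be present to train the genomic classifier")
  xt <- t(m[features, , drop = FALSE])
  fit <- .fitForest(xt, y, ntree = config$n_trees, mtry = as.integer(mtry),
                    nodesize = as.integer(nodesize),
                    seed = .subSeed(config$seed, 424243L))
  new("GCModel", kind = "GC", features = features, forest = fit,
      mtry = as.integer(mtry), nodesize = as.integer(nodesize))
}

## Clinical covariate encoding: GS dichotomized at >=8, pPSA log2-transformed
## with median imputation plus a missingness indicator, binaries as 0/1.
.clinicalDesign <- function(annot, ppsa_median = NULL) {
  need <- c("gleason", "ppsa", "svi", "sm_pos", "ece", "node_pos")
  miss <- setdiff(need, colnames(annot))
  if (length(miss))
    stop("annotation is missing clinical covariates: ",
         paste(miss, collapse = ", "))
  lppsa <- log2(annot$ppsa)
  ppsa_missing <- !is.finite(lppsa)
  if (is.null(ppsa_median)) ppsa_median <- median(lppsa[!ppsa_missing])
  lppsa[ppsa_missing] <- ppsa_median
  list(design = data.frame(
         gs8 = as.integer(annot$gleason >= 8L),
         lppsa = lppsa,
         ppsa_missing = as.integer(ppsa_missing),
         svi = as.integer(annot$svi),
         sm_pos = as.integer(annot$sm_pos),
         ece = as.integer(annot$ece),
         node_pos = as.integer(annot$node_pos)),
       ppsa_median = ppsa_median)
}

#' Train the clinical-only classifier
#'
#' Logistic regression of case status on the six clinicopathologic
#' variables: Gleason score dichotomized at >=8, log2 pre-operative PSA
#' (median-imputed with a missingness indicator), surgical-margin
#' positivity, seminal vesicle invasion, extra-capsular extension and
#' lymph-node involvement. The score is the predicted case probability.
#'
#' @param annot training-split sample annotation data.frame (e.g.
#'   `cohortInfo(trainingSet(cohort))`), with an `is_case` column.
#' @return A [CCModel-class].
#' @export
trainCC <- function(annot) {
  y <- as.integer(as.logical(annot$is_case))
  if (length(unique(y)) < 2L) stop("both classes must be present")
  enc <- .clinicalDesign(annot)
  df <- cbind(enc$design, .y = y)
  covars <- colnames(enc$design)
  fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
  offending <- function(f) {
    cf <- coef(f)[-1L]
    names(cf)[!is.na(cf) & abs(cf) > 15]
  }
  bad <- offending(fit)
  if (identical(bad, "ppsa_missing")) {
    ## the handful of missing-pPSA samples can separate by chance; the
    ## auxiliary indicator is not a substantive covariate, so drop it
    warning("missingness indicator for pPSA separates the outcome; ",
            "dropping it (median imputation is kept)")
    covars <- setdiff(covars, "ppsa_missing")
    df$ppsa_missing <- NULL
    fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
    bad <- offending(fit)
  }
  if (length(bad))
    stop("complete separation in the clinical model driven by covariate(s): ",
         paste(bad, collapse = ", "))
  new("CCModel", kind = "CC", fit = fit, ppsaMedian = enc$ppsa_median,
      covariates = covars)
}

#' Train the integrated genomic-clinical classifier
#'
#' Logistic regression of case status on the GC and CC scores of the
#' training samples. If the two score vectors are collinear the redundant
#' one is dropped with a warning (a single effective predictor remains).
#'
#' @param gc_scores,cc_scores numeric training-set score vectors in `[0, 1]`.
#' @param is_case logical case indicator.
#' @return A [GCCModel-class].
#' @export
trainGCC <- function(gc_scores, cc_scores, is_case) {
  y <- as.integer(as.logical(is_case))
  stopifnot(length(gc_scores) == length(y), length(cc_scores) == length(y))
  df <- data.frame(gc = gc_scores, cc = cc_scores, .y = y)
  fit <- suppressWarnings(glm(.y ~ gc + cc, data = df, family = binomial()))
  if (anyNA(coef(fit))) {
    warning("GC and CC scores are collinear; refitting on a single ",
            "effective predictor")
    fit <- suppressWarnings(glm(.y ~ gc, data = df, family = binomial()))
  }
  new("GCCModel", kind = "GCC", fit = fit)
}

#' Score samples with a fitted classifier
#'
#' @param model a fitted [ClassifierModel-class] (GC, CC or GCC).
#' @param newdata for a `GCModel`, a [MetCohort-class] or expression matrix
#'   covering the model's markers; for a `CCModel`, a sample-annotation
#'   data.frame; for a `GCCModel`, a data.frame with `gc` and `cc` columns.
#' @return Numeric scores in `[0, 1]`, one per sample.
#' @export
setGeneric("scoreSamples", function(model, newdata)
  standardGeneric("scoreSamples"))

#' @rdname scoreSamples
#' @export
setMethod("scoreSamples", "GCModel", function(model, newdata) {
  m <- .asExprs(newdata)
  miss <- setdiff(model@features, rownames(m))
  if (length(miss))
    stop("markers absent from the input: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  p <- .forestProb(model@forest, t(m[model@features, , drop = FALSE]))
  setNames(p, colnames(m))
})

#' @rdname scoreSamples
#' @export
setMethod("scoreSamples", "CCModel", function(model, newdata) {
  if (is(newdata, "MetCohort")) newdata <- cohortInfo(newdata)
  enc <- .clinicalDesign(newdata, ppsa_median = model@ppsaMedian)
  p <- predict(model@fit, newdata = enc$design, type = "response")
  setNames(as.numeric(p), rownames(newdata))
})

#' @rdname scoreSamples
#' @export
setMethod("scoreSamples", "GCCModel", function(model, newdata) {
  stopifnot(all(c("gc", "cc") %in% colnames(newdata)))
  p <- predict(model@fit, newdata = as.data.frame(newdata),
               type = "response")
  as.numeric(p)
})

#' Dichotomize a classifier score into a risk call
#'
#' Scores strictly greater than 0.5 are high risk; scores lower than or
#' equal to 0.5 (including exactly 0.5) are low risk.
#'
#' @param score numeric score(s) in `[0, 1]`.
#' @return factor with levels `low`, `high`.
#' @export
classifyRisk <- function(score) {
  if (any(!is.finite(score)) || any(score < 0) || any(score > 1))
    stop("scores must lie in [0, 1]")
  factor(ifelse(score > 0.5, "high", "low"), levels = c("low", "high"))
}
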