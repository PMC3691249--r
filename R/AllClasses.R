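#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Case-control expression cohort
#'
#' `MetCohort` extends [SummarizedExperiment::SummarizedExperiment] and is the
#' central container of the package: a log2-scale expression matrix
#' (features x samples) in the `"exprs"` assay, feature annotation in
#' `rowData()` (at least `probe_count` and `crosshyb`), and per-sample cohort
#' annotation in `colData()` (outcome `group` in NED/PSA/MET, the derived
#' `is_case` flag, hybridization `batch`, `split` into train/validation, and
#' the clinicopathologic and survival fields used by the clinical models).
#'
#' @section Validity:
#' The `"exprs"` assay must be a numeric matrix with no missing values;
#' `is_case` must equal `group == "MET"`; `split` values must be `"train"` or
#' `"validation"`; salvage-therapy flags must be `FALSE` in the NED group
#' (patients without biochemical recurrence are never eligible for salvage
#' treatment); and a prostate-cancer-death event implies an overall-survival
#' event.
#'
#' @export
setClass("MetCohort", contains = "SummarizedExperiment")

.validMetCohort <- function(object) {
  msg <- character()
  if (!("exprs" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'exprs' is required")
  else {
    x <- SummarizedExperiment::assay(object, "exprs")
    if (!is.numeric(x)) msg <- c(msg, "'exprs' must be numeric")
    if (anyNA(x)) msg <- c(msg, "'exprs' must not contain missing values")
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("group", "is_case", "batch", "split")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData is missing: ", paste(miss, collapse = ", ")))
  if (!length(miss)) {
    if (!all(cd$group %in% c("NED", "PSA", "MET")))
      msg <- c(msg, "group must be one of NED, PSA, MET")
    if (!identical(as.logical(cd$is_case), cd$group == "MET"))
      msg <- c(msg, "is_case must be TRUE exactly for the MET group")
    if (!all(cd$split %in% c("train", "validation")))
      msg <- c(msg, "split must be 'train' or 'validation'")
    for (fl in intersect(c("salv_radiation", "salv_adt"), colnames(cd)))
      if (any(cd[[fl]][cd$group == "NED"]))
        msg <- c(msg, sprintf("%s must be FALSE for the NED group", fl))
    if (all(c("e_pcsm", "e_os") %in% colnames(cd)) &&
        any(cd$e_pcsm & !cd$e_os))
      msg <- c(msg, "a PCSM event implies an OS event")
  }
  fd <- SummarizedExperiment::rowData(object)
  missf <- setdiff(c("probe_count", "crosshyb"), colnames(fd))
  if (length(missf))
    msg <- c(msg, paste0("rowData is missing: ", paste(missf, collapse = ", ")))
  if (length(msg)) msg else TRUE
}

setValidity("MetCohort", .validMetCohort)

#' Construct a MetCohort
#'
#' @param exprs numeric matrix, features x samples, log2 scale, with feature
#'   ids as rownames and sample ids as colnames.
#' @param featureData data.frame (or DataFrame) of feature annotation, one row
#'   per feature; must include `probe_count` and `crosshyb`.
#' @param sampleData data.frame (or DataFrame) of per-sample annotation; must
#'   include `group`, `is_case`, `batch` and `split`.
#' @return A [MetCohort-class] object.
#' @export
MetCohort <- function(exprs, featureData, sampleData) {
  if (is.null(rownames(exprs)) || is.null(colnames(exprs)))
    stop("'exprs' must carry feature ids (rownames) and sample ids (colnames)")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs),
    rowData = S4Vectors::DataFrame(featureData, row.names = rownames(exprs)),
    colData = S4Vectors::DataFrame(sampleData, row.names = colnames(exprs)))
  new("MetCohort", se)
}

#' @describeIn MetCohort the expression matrix (`"exprs"` assay).
#' @param x,object a `MetCohort`.
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "exprs")

#' @describeIn MetCohort feature annotation as a data.frame.
#' @export
featureInfo <- function(x)
  as.data.frame(SummarizedExperiment::rowData(x))

#' @describeIn MetCohort sample annotation as a data.frame.
#' @export
cohortInfo <- function(x)
  as.data.frame(SummarizedExperiment::colData(x))

#' @describeIn MetCohort logical case indicator (MET group).
#' @export
isCase <- function(x) as.logical(SummarizedExperiment::colData(x)$is_case)

#' @describeIn MetCohort integer batch labels.
#' @export
batchOf <- function(x) as.integer(SummarizedExperiment::colData(x)$batch)

#' @describeIn MetCohort train/validation assignment.
#' @export
splitOf <- function(x) as.character(SummarizedExperiment::colData(x)$split)

#' @describeIn MetCohort the training-split samples.
#' @export
trainingSet <- function(x) x[, splitOf(x) == "train"]

#' @describeIn MetCohort the withheld validation-split samples.
#' @export
validationSet <- function(x) x[, splitOf(x) == "validation"]

setMethod("show", "MetCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("MetCohort:", nrow(object), "features x", ncol(object), "samples\n")
  cat("  groups: ", paste(sprintf("%s=%d", names(table(cd$group)),
                                  as.integer(table(cd$group))),
                          collapse = ", "), "\n", sep = "")
  cat("  split:  ", paste(sprintf("%s=%d", names(table(cd$split)),
                                  as.integer(table(cd$split))),
                          collapse = ", "), "\n", sep = "")
  cat("  batches:", length(unique(cd$batch)), "\n")
})

#' Simulation configuration
#'
#' Parameters of the synthetic cohort generator. Defaults mirror the study
#' design the pipeline was built for: a 545-patient nested case-control
#' cohort (192 metastasis cases, 184 PSA-recurrence and 169
#' no-evidence-of-disease controls), 19 hybridization batches, a 359/545
#' training fraction, and one technical-replicate control array per batch.
#'
#' @slot n_features number of expression features.
#' @slot n_informative number of features given a true case-vs-control shift.
#' @slot n_cases,n_ned,n_psa group sizes (cases = early-metastasis group).
#' @slot n_batches number of hybridization batches.
#' @slot batch_sd standard deviation of the additive per-(batch, feature)
#'   offsets (log2 units).
#' @slot effect_size mean log2-expression shift of informative features in
#'   cases.
#' @slot noise_sd per-sample biological + technical noise SD (log2 units).
#' @slot n_tech_reps number of technical replicate profiles (one per batch).
#' @slot tech_unreliable_frac fraction of features given ~10x inflated
#'   technical variance.
#' @slot frac_low_probe fraction of features flagged with probe_count < 4.
#' @slot frac_crosshyb fraction flagged as cross-hybridizing.
#' @slot train_frac fraction of samples assigned to the training split.
#' @slot seed integer master seed.
#' @export
setClass("SimConfig", representation(
  n_features = "integer", n_informative = "integer",
  n_cases = "integer", n_ned = "integer", n_psa = "integer",
  n_batches = "integer", batch_sd = "numeric", effect_size = "numeric",
  noise_sd = "numeric", n_tech_reps = "integer",
  tech_unreliable_frac = "numeric", frac_low_probe = "numeric",
  frac_crosshyb = "numeric", train_frac = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  cnt <- c(n_features = object@n_features, n_informative = object@n_informative,
           n_cases = object@n_cases, n_ned = object@n_ned,
           n_psa = object@n_psa, n_batches = object@n_batches,
           n_tech_reps = object@n_tech_reps)
  if (any(cnt < 0L)) msg <- c(msg, "all counts must be >= 0")
  if (object@n_informative > object@n_features)
    msg <- c(msg, "n_informative must not exceed n_features")
  for (f in c("tech_unreliable_frac", "frac_low_probe", "frac_crosshyb",
              "train_frac"))
    if (slot(object, f) < 0 || slot(object, f) > 1)
      msg <- c(msg, sprintf("%s must lie in [0, 1]", f))
  if (object@batch_sd < 0) msg <- c(msg, "batch_sd must be >= 0")
  if (object@effect_size < 0) msg <- c(msg, "effect_size must be >= 0")
  if (object@noise_sd <= 0) msg <- c(msg, "noise_sd must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname SimConfig-class
#' @param n_features,n_informative,n_cases,n_ned,n_psa,n_batches,batch_sd,effect_size,noise_sd,n_tech_reps,tech_unreliable_frac,frac_low_probe,frac_crosshyb,train_frac,seed
#'   see the corresponding slots.
#' @return A validated `SimConfig`.
#' @export
simConfig <- function(n_features = 5000L, n_informative = 30L,
                      n_cases = 192L, n_ned = 169L, n_psa = 184L,
                      n_batches = 19L, batch_sd = 0.5, effect_size = 1.0,
                      noise_sd = 1.0, n_tech_reps = 19L,
                      tech_unreliable_frac = 0.10, frac_low_probe = 0.05,
                      frac_crosshyb = 0.05, train_frac = 359 / 545,
                      seed = 1L) {
  new("SimConfig",
      n_features = .assertCount(n_features, "n_features"),
      n_informative = .assertCount(n_informative, "n_informative"),
      n_cases = .assertCount(n_cases, "n_cases"),
      n_ned = .assertCount(n_ned, "n_ned"),
      n_psa = .assertCount(n_psa, "n_psa"),
      n_batches = .assertCount(n_batches, "n_batches", min = 1L),
      batch_sd = batch_sd, effect_size = effect_size, noise_sd = noise_sd,
      n_tech_reps = .assertCount(n_tech_reps, "n_tech_reps"),
      tech_unreliable_frac = tech_unreliable_frac,
      frac_low_probe = frac_low_probe, frac_crosshyb = frac_crosshyb,
      train_frac = train_frac, seed = .assertCount(seed, "seed", min = 0L))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@n_features, "features (",
      object@n_informative, "informative ),",
      object@n_cases + object@n_ned + object@n_psa, "samples in",
      object@n_batches, "batches; effect", object@effect_size,
      "; seed", object@seed, "\n")
})

#' Batch-effect correction result
#'
#' Returned by [removeBatchComponents()]. Holds the corrected expression
#' matrix, the 1-based indices of the principal components that were removed,
#' the batch-association R-squared of every examined component, the fraction
#' of total variance captured by the examined components, and the removed
#' sample-space directions (for diagnostics).
#'
#' @slot corrected numeric matrix, same dimensions as the input.
#' @slot removedPCs integer vector of removed component indices.
#' @slot batchR2 named numeric vector, one-way ANOVA R-squared of each
#'   examined component's scores on batch.
#' @slot varianceCaptured fraction of total (feature-centered) variance
#'   carried by the examined components.
#' @slot removedDirections samples x n_remove matrix of the removed
#'   right-singular vectors.
#' @export
setClass("BatchCorrection", representation(
  corrected = "matrix", removedPCs = "integer", batchR2 = "numeric",
  varianceCaptured = "numeric", removedDirections = "matrix"))

setValidity("BatchCorrection", function(object) {
  msg <- character()
  if (!all(object@removedPCs %in% seq_along(object@batchR2)))
    msg <- c(msg, "removedPCs must index the examined components")
  if (length(object@removedPCs) != ncol(object@removedDirections))
    msg <- c(msg, "one removed direction per removed component")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BatchCorrection", function(object) {
  cat("BatchCorrection:", nrow(object@corrected), "x",
      ncol(object@corrected), "matrix; removed PCs",
      paste(object@removedPCs, collapse = ", "),
      sprintf("(%.0f%% of variance in the examined components)\n",
              100 * object@varianceCaptured))
  cat("  batch R2 per examined PC:",
      paste(sprintf("%.2f", object@batchR2), collapse = " "), "\n")
})

#' Stability-selection result
#'
#' Per-feature tallies of how often the bootstrapped elastic-net logistic
#' regression assigned a feature a nonzero coefficient, and the surviving
#' feature set at the selection-frequency threshold.
#'
#' @slot tally named integer vector of selection counts.
#' @slot nBoot number of bootstrap rounds performed.
#' @slot threshold selection-frequency threshold (fraction of rounds).
#' @slot selected ids of features with `tally / nBoot >= threshold`.
#' @slot tPass ids of the candidate features that entered the bootstrap
#'   (the t-filter survivors).
#' @slot nSkipped rounds skipped for solver non-convergence.
#' @export
setClass("StabilityResult", representation(
  tally = "integer", nBoot = "integer", threshold = "numeric",
  selected = "character", tPass = "character", nSkipped = "integer"))

setValidity("StabilityResult", function(object) {
  msg <- character()
  if (any(object@tally < 0L) || any(object@tally > object@nBoot))
    msg <- c(msg, "tallies must lie in [0, nBoot]")
  if (!all(object@selected %in% object@tPass))
    msg <- c(msg, "selected features must be a subset of the candidates")
  if (length(msg)) msg else TRUE
})

setMethod("show", "StabilityResult", function(object) {
  cat("StabilityResult:", length(object@tPass), "candidates,",
      object@nBoot, "bootstraps ->", length(object@selected),
      sprintf("features at threshold %.2f", object@threshold))
  if (object@nSkipped > 0L)
    cat(" (", object@nSkipped, " rounds skipped)", sep = "")
  cat("\n")
})

#' @rdname StabilityResult-class
#' @param x a `StabilityResult`.
#' @return `selectedFeatures()`: character vector of surviving feature ids;
#'   `selectionTally()`: data.frame with columns feature_id, tally, fraction,
#'   selected.
#' @export
selectedFeatures <- function(x) x@selected

#' @rdname StabilityResult-class
#' @export
selectionTally <- function(x) {
  data.frame(feature_id = names(x@tally), tally = unname(x@tally),
             fraction = unname(x@tally) / x@nBoot,
             selected = names(x@tally) %in% x@selected,
             row.names = NULL)
}

#' Backward-elimination curve
#'
#' The trace of the Gini-ranked backward elimination: candidate-set sizes,
#' the 10-fold cross-validated mean squared error (Brier score of the
#' out-of-fold case probability against the 0/1 label) at each size, and the
#' chosen model size (the curve's minimum, smaller size on ties).
#'
#' @slot sizes strictly decreasing integer vector of feature-set sizes.
#' @slot cvMSE cross-validated MSE at each size.
#' @slot chosenSize the size minimizing cvMSE.
#' @slot chosenFeatures the surviving feature ids at `chosenSize`.
#' @export
setClass("EliminationCurve", representation(
  sizes = "integer", cvMSE = "numeric", chosenSize = "integer",
  chosenFeatures = "character"))

setValidity("EliminationCurve", function(object) {
  msg <- character()
  if (length(object@sizes) > 1L && any(diff(object@sizes) >= 0L))
    msg <- c(msg, "sizes must be strictly decreasing")
  if (!(object@chosenSize %in% object@sizes))
    msg <- c(msg, "chosenSize must be one of the recorded sizes")
  if (length(object@chosenFeatures) != object@chosenSize)
    msg <- c(msg, "chosenFeatures length must equal chosenSize")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EliminationCurve", function(object) {
  cat("EliminationCurve:", length(object@sizes), "sizes from",
      max(object@sizes), "to", min(object@sizes), "; chosen size",
      object@chosenSize,
      sprintf("(cv MSE %.4f)\n",
              object@cvMSE[match(object@chosenSize, object@sizes)]))
})

#' Classifier models
#'
#' `GCModel` is the genomic classifier: a probability random forest over the
#' final marker set; its score is the fraction of trees voting "case".
#' `CCModel` is the clinical-only logistic model over GS>=8, log2 pPSA (with
#' median imputation and a missingness indicator), SM+, SVI, ECE and N+.
#' `GCCModel` is the logistic combination of the GC and CC scores. All three
#' score a sample into `[0, 1]` via [scoreSamples()].
#'
#' @slot kind one of "GC", "CC", "GCC".
#' @export
setClass("ClassifierModel", representation(kind = "character", "VIRTUAL"))

#' @rdname ClassifierModel-class
#' @slot features marker feature ids (GC).
#' @slot forest the fitted randomForest ensemble.
#' @slot mtry,nodesize tuned forest hyperparameters.
#' @export
setClass("GCModel", contains = "ClassifierModel", representation(
  features = "character", forest = "ANY", mtry = "integer",
  nodesize = "integer"))

#' @rdname ClassifierModel-class
#' @slot fit the fitted `glm` object.
#' @slot ppsaMedian training-set median of log2 pPSA used for imputation.
#' @slot covariates names of the model covariates.
#' @export
setClass("CCModel", contains = "ClassifierModel", representation(
  fit = "ANY", ppsaMedian = "numeric", covariates = "character"))

#' @rdname ClassifierModel-class
#' @export
setClass("GCCModel", contains = "ClassifierModel", representation(
  fit = "ANY"))

setMethod("show", "GCModel", function(object) {
  cat("GCModel: random forest on", length(object@features),
      "markers (mtry", object@mtry, ", nodesize", object@nodesize, ",",
      object@forest$ntree, "trees)\n")
})
setMethod("show", "CCModel", function(object) {
  cat("CCModel: logistic model on",
      paste(object@covariates, collapse = ", "), "\n")
})
setMethod("show", "GCCModel", function(object) {
  cat("GCCModel: logistic combination of GC and CC scores\n")
})

#' Evaluation report
#'
#' The output of [runPipeline()]: validation-set AUCs for the three
#' classifiers and GS, odds-ratio tables, Kaplan-Meier results, the
#' Gleason-by-GC reclassification table, reverse-KM median follow-up, the
#' per-sample score table, and a manifest of seeds, stage dimensions and
#' content hashes.
#'
#' @slot auc named list of [AUCResult-class].
#' @slot orUVA,orMVA data.frames of univariable / multivariable odds ratios.
#' @slot km named list of [KMResult-class].
#' @slot reclass the reclassification data.frame.
#' @slot followupYears reverse-KM median follow-up (years).
#' @slot scores data.frame: sample_id, split, is_case, gc, cc, gcc, risk.
#' @slot stability the [StabilityResult-class].
#' @slot elimination the [EliminationCurve-class].
#' @slot models named list: gc, cc, gcc models.
#' @slot manifest list of seeds, stage dimensions and md5 hashes.
#' @export
setClass("EvaluationReport", representation(
  auc = "list", orUVA = "data.frame", orMVA = "data.frame", km = "list",
  reclass = "data.frame", followupYears = "numeric", scores = "data.frame",
  stability = "StabilityResult", elimination = "EliminationCurve",
  models = "list", manifest = "list"))

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport\n")
  f <- object@manifest$funnel
  if (!is.null(f))
    cat("  feature funnel:", paste(f, collapse = " -> "), "\n")
  for (nm in names(object@auc)) {
    a <- object@auc[[nm]]
    cat(sprintf("  validation AUC %-4s %.3f (%.3f-%.3f)\n",
                paste0(nm, ":"), a@auc, a@ciLow, a@ciHigh))
  }
  cat(sprintf("  median follow-up (reverse KM): %.2f years\n",
              object@followupYears))
})
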