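#' Assemble a pipeline configuration
#'
#' Bundles the stage configurations and the master seed. Exactly one of
#' `simulation` (a [SimConfig-class]) or `input` (a list of file paths:
#' `matrix`, `features`, `samples`, optional `tech`, plus `format`) must be
#' supplied.
#'
#' @param simulation a [SimConfig-class], or `NULL` when reading from files.
#' @param input list of input paths, or `NULL` when simulating.
#' @param selection a `SelectionConfig` ([selectionConfig()]).
#' @param forest a `ForestConfig` ([forestConfig()]).
#' @param master_seed integer master seed; stage seeds are derived from it.
#' @param n_examine,n_remove batch-correction settings (see
#'   [removeBatchComponents()]).
#' @param batch_fit one of `"all"` (fit the batch correction on all samples,
#'   the default) or `"train"` (refit on the training split only; stricter
#'   validation hygiene at the cost of deviating from the global-correction
#'   convention).
#' @param auc_boot bootstrap replicates for validation AUC CIs.
#' @param output_dir optional directory; when given, all intermediate
#'   artifacts (filtered matrix, tally table, elimination curve, scores,
#'   report JSON, manifest) are written there.
#' @return A named list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(simulation = NULL, input = NULL,
                           selection = selectionConfig(),
                           forest = forestConfig(),
                           master_seed = 1L,
                           n_examine = 10L, n_remove = 2L,
                           batch_fit = c("all", "train"),
                           auc_boot = 2000L,
                           output_dir = NULL) {
  if (is.null(simulation) == is.null(input))
    stop("supply exactly one of 'simulation' or 'input'")
  structure(list(simulation = simulation, input = input,
                 selection = selection, forest = forest,
                 master_seed = .assertCount(master_seed, "master_seed", 0L),
                 n_examine = n_examine, n_remove = n_remove,
                 batch_fit = match.arg(batch_fit),
                 auc_boot = .assertCount(auc_boot, "auc_boot", 1L),
                 output_dir = output_dir),
            class = "PipelineConfig")
}

.loadCohort <- function(cfg) {
  if (!is.null(cfg$simulation)) {
    cohort <- simulateCohort(cfg$simulation)
    tech <- simulateTechReplicates(cfg$simulation, featureInfo(cohort))
    return(list(cohort = cohort, tech = tech))
  }
  inp <- cfg$input
  fmt <- inp$format %||% "tsv"
  m <- readExprMatrix(inp$matrix, format = fmt)
  feats <- readAnnotation(inp$features)
  samps <- readAnnotation(inp$samples)
  if (!setequal(feats$feature_id, rownames(m)))
    stop("feature annotation does not cover the matrix rows; offenders: ",
         paste(utils::head(setdiff(rownames(m), feats$feature_id), 5L),
               collapse = ", "))
  if (!setequal(samps$sample_id, colnames(m)))
    stop("sample annotation does not cover the matrix columns; offenders: ",
         paste(utils::head(setdiff(colnames(m), samps$sample_id), 5L),
               collapse = ", "))
  rownames(feats) <- feats$feature_id
  rownames(samps) <- samps$sample_id
  cohort <- MetCohort(m, feats[rownames(m), , drop = FALSE],
                      samps[colnames(m), , drop = FALSE])
  tech <- if (!is.null(inp$tech)) readExprMatrix(inp$tech, format = fmt)
  list(cohort = cohort, tech = tech)
}

#' Run the full development-and-validation pipeline
#'
#' Orchestrates every stage on one master seed: (1) feature-reliability
#' filtering by annotation and by technical-replicate variance, (2) removal
#' of the two most batch-associated principal components, (3) per-feature
#' t-filter on the training split, (4) bootstrapped elastic-net stability
#' selection, (5) Gini-ranked backward elimination to the error-curve knee,
#' (6) grid-search tuning and final forest fit (genomic classifier), plus
#' the clinical-only and integrated logistic models, and (7) evaluation on
#' the withheld validation split (AUCs with bootstrap CIs, univariable and
#' multivariable odds ratios, Kaplan-Meier by risk group among cases,
#' Gleason reclassification, reverse-KM median follow-up).
#'
#' Validation samples are never seen by any fitting stage; the only global
#' step is the batch correction, which by convention is fitted on all
#' samples (set `batch_fit = "train"` in the config for strict hygiene).
#'
#' @param config a `PipelineConfig` from [pipelineConfig()].
#' @param verbose log stage boundaries with feature/sample counts.
#' @return An [EvaluationReport-class].
#' @export
runPipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  say <- function(...) if (verbose) message(...)
  stage <- "load"
  report <- tryCatch({
    dat <- .loadCohort(config)
    cohort <- dat$cohort
    n0 <- nrow(cohort)
    say("loaded cohort: ", n0, " features x ", ncol(cohort), " samples")

    stage <- "preprocess"
    cohort <- filterByAnnotation(cohort)
    n1 <- nrow(cohort)
    if (!is.null(dat$tech)) {
      tech <- dat$tech[rownames(cohort), , drop = FALSE]
      cohort <- filterByTechnicalVariance(cohort, tech)
    }
    n2 <- nrow(cohort)
    say("reliability filters: ", n0, " -> ", n1, " -> ", n2, " features")
    bc_input <- if (config$batch_fit == "train") trainingSet(cohort)
    else cohort
    bc <- removeBatchComponents(bc_input, n_examine = config$n_examine,
                                n_remove = config$n_remove)
    if (config$batch_fit == "all") {
      SummarizedExperiment::assay(cohort, "exprs") <- bc@corrected
    } else {
      ## project all samples off the training-fitted directions
      m <- exprValues(cohort)
      xc <- m - rowMeans(m)
      ## directions live in training-sample space; recompute loadings there
      tr <- splitOf(cohort) == "train"
      u <- (exprValues(trainingSet(cohort)) -
              rowMeans(exprValues(trainingSet(cohort)))) %*%
        bc@removedDirections
      u <- sweep(u, 2L, sqrt(colSums(u^2)), "/")
      SummarizedExperiment::assay(cohort, "exprs") <-
        m - u %*% (t(u) %*% xc)
    }
    say("batch correction removed PCs ",
        paste(bc@removedPCs, collapse = ", "),
        sprintf(" (max batch R2 %.2f)", max(bc@batchR2)))

    train <- trainingSet(cohort)
    valid <- validationSet(cohort)

    stage <- "t-filter"
    sel_seed <- .subSeed(config$master_seed, 11L)
    t_pass <- tFilter(train, p_threshold = config$selection$t_p_threshold)
    say("t-filter: ", n2, " -> ", length(t_pass), " features")
    if (length(t_pass) < 2L)
      stop("fewer than 2 features passed the t-filter")

    stage <- "stability-selection"
    sel_cfg <- config$selection
    sel_cfg$seed <- sel_seed
    stab <- stabilitySelect(exprValues(train)[t_pass, , drop = FALSE],
                            isCase(train), sel_cfg)
    say("stability selection: ", length(t_pass), " -> ",
        length(stab@selected), " features")
    if (length(stab@selected) < 2L)
      stop("fewer than 2 features survived stability selection")

    stage <- "backward-elimination"
    f_cfg <- config$forest
    f_cfg$seed <- .subSeed(config$master_seed, 22L)
    curve <- backwardEliminate(train, candidates = stab@selected,
                               config = f_cfg)
    say("backward elimination: ", length(stab@selected), " -> ",
        curve@chosenSize, " markers")

    stage <- "tuning"
    tuned <- tuneForest(train, features = curve@chosenFeatures,
                        config = f_cfg)
    say("tuned forest: mtry ", tuned$mtry, ", nodesize ", tuned$nodesize)

    stage <- "training"
    gc <- trainGC(train, features = curve@chosenFeatures,
                  mtry = tuned$mtry, nodesize = tuned$nodesize,
                  config = f_cfg)
    cc <- trainCC(cohortInfo(train))
    gc_tr <- scoreSamples(gc, train)
    cc_tr <- scoreSamples(cc, cohortInfo(train))
    gcc <- trainGCC(gc_tr, cc_tr, isCase(train))

    stage <- "evaluation"
    va <- cohortInfo(valid)
    gc_va <- scoreSamples(gc, valid)
    cc_va <- scoreSamples(cc, va)
    gcc_va <- scoreSamples(gcc, data.frame(gc = gc_va, cc = cc_va))
    scores <- data.frame(
      sample_id = rownames(va), split = "validation",
      is_case = va$is_case, gc = unname(gc_va), cc = unname(cc_va),
      gcc = unname(gcc_va),
      risk = as.character(classifyRisk(unname(gc_va))))

    eval_seed <- .subSeed(config$master_seed, 33L)
    auc <- list(
      GC = aucCI(scores$gc, scores$is_case, n_boot = config$auc_boot,
                 seed = eval_seed),
      CC = aucCI(scores$cc, scores$is_case, n_boot = config$auc_boot,
                 seed = .subSeed(eval_seed, 1L)),
      GCC = aucCI(scores$gcc, scores$is_case, n_boot = config$auc_boot,
                  seed = .subSeed(eval_seed, 2L)),
      GS = aucCI(as.numeric(va$gleason), scores$is_case,
                 n_boot = config$auc_boot, seed = .subSeed(eval_seed, 3L)))

    uva <- .orTable(va, scores, multivariable = FALSE)
    mva <- .orTable(va, scores, multivariable = TRUE)

    cases <- va$is_case
    km <- list(
      PCSM = kmLogrank(va$t_pcsm[cases], va$e_pcsm[cases],
                       classifyRisk(scores$gc[cases]), label = "PCSM"),
      OS = kmLogrank(va$t_os[cases], va$e_os[cases],
                     classifyRisk(scores$gc[cases]), label = "OS"))
    reclass <- reclassificationTable(va$gleason, scores$gc, va$e_met,
                                     va$e_pcsm)
    fu <- medianFollowup(cohortInfo(cohort)$t_os, cohortInfo(cohort)$e_os)

    manifest <- list(
      master_seed = config$master_seed,
      funnel = c(input = n0, reliable = n2, t_filter = length(t_pass),
                 stability = length(stab@selected),
                 final = curve@chosenSize),
      n_train = ncol(train), n_validation = ncol(valid),
      removed_pcs = bc@removedPCs,
      batch_r2 = bc@batchR2,
      variance_captured = bc@varianceCaptured,
      tuned = tuned[c("mtry", "nodesize")],
      hashes = list(exprs = .fingerprint(exprValues(cohort)),
                    tally = .fingerprint(stab@tally),
                    markers = .fingerprint(curve@chosenFeatures),
                    scores = .fingerprint(scores)))

    new("EvaluationReport", auc = auc, orUVA = uva, orMVA = mva, km = km,
        reclass = reclass, followupYears = fu, scores = scores,
        stability = stab, elimination = curve,
        models = list(gc = gc, cc = cc, gcc = gcc), manifest = manifest)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(config$output_dir)) .writeArtifacts(report, config)
  report
}

## Univariable / multivariable odds-ratio tables on the validation split.
.orTable <- function(va, scores, multivariable) {
  orRow <- function(nm, r) {
    if (is.null(r)) return(NULL)
    data.frame(variable = nm, or = r@or, ci_low = r@ciLow,
               ci_high = r@ciHigh, p = r@p)
  }
  if (!multivariable) {
    tryOR <- function(...) tryCatch(uvaLogisticOR(...),
                                    error = function(e) NULL)
    vars <- list(
      gc = tryOR(scores$gc, scores$is_case, "per_10pct_score"),
      gcc = tryOR(scores$gcc, scores$is_case, "per_10pct_score"),
      cc = tryOR(scores$cc, scores$is_case, "per_10pct_score"),
      ppsa = tryOR(va$ppsa, scores$is_case, "log2"),
      gs8 = tryOR(va$gleason >= 8, scores$is_case),
      svi = tryOR(va$svi, scores$is_case),
      node_pos = tryOR(va$node_pos, scores$is_case),
      sm_pos = tryOR(va$sm_pos, scores$is_case),
      ece = tryOR(va$ece, scores$is_case))
    out <- do.call(rbind, Map(orRow, names(vars), vars))
  } else {
    lppsa <- log2(va$ppsa)
    lppsa[!is.finite(lppsa)] <- median(lppsa[is.finite(lppsa)])
    cov <- data.frame(gc = scores$gc, lppsa = lppsa,
                      gs8 = va$gleason >= 8, svi = va$svi,
                      node_pos = va$node_pos, sm_pos = va$sm_pos,
                      ece = va$ece,
                      adj_radiation = va$adj_radiation,
                      adj_adt = va$adj_adt,
                      salv_radiation = va$salv_radiation,
                      salv_adt = va$salv_adt)
    res <- mvaLogisticOR(cov, scores$is_case, adjust_for_treatment = TRUE)
    out <- do.call(rbind, Map(orRow, names(res), res))
  }
  rownames(out) <- NULL
  out
}

.writeArtifacts <- function(report, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  writeAnnotation(selectionTally(report@stability), out("tally.tsv"))
  writeAnnotation(data.frame(size = report@elimination@sizes,
                             cv_mse = report@elimination@cvMSE),
                  out("elimination_curve.tsv"))
  writeAnnotation(report@scores, out("scores.tsv"))
  writeAnnotation(report@reclass, out("reclassification.tsv"))
  writeAnnotation(report@orUVA, out("or_univariable.tsv"))
  writeAnnotation(report@orMVA, out("or_multivariable.tsv"))
  jsonlite::write_json(reportAsList(report), out("report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$output_dir)
}

#' Flatten an EvaluationReport to plain lists
#'
#' JSON-ready summary of an [EvaluationReport-class]: AUCs with CIs,
#' odds-ratio tables, KM medians and log-rank p-values, the
#' reclassification table, follow-up and the manifest.
#'
#' @param report an [EvaluationReport-class].
#' @return A nested list of scalars, vectors and data.frames.
#' @export
reportAsList <- function(report) {
  list(
    auc = lapply(report@auc, function(a)
      list(auc = a@auc, ci_low = a@ciLow, ci_high = a@ciHigh,
           n_boot = a@nBoot)),
    or_univariable = report@orUVA,
    or_multivariable = report@orMVA,
    km = lapply(report@km, function(k)
      list(label = k@label, medians = as.list(k@medians),
           logrank_p = k@logrankP)),
    reclassification = report@reclass,
    median_followup_years = report@followupYears,
    manifest = report@manifest)
}
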