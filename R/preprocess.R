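## Feature-reliability filtering and PCA-based batch-effect removal.

## Accept either a MetCohort or a bare matrix; return the matrix plus a
## rebuild closure so filters preserve container metadata.
.asExprs <- function(x) {
  if (is(x, "MetCohort")) exprValues(x) else as.matrix(x)
}

#' Remove features unreliable by annotation
#'
#' Drops every feature interrogated by fewer than four probes or flagged as
#' cross-hybridizing, preserving feature order.
#'
#' @param x a [MetCohort-class], or a numeric expression matrix (features in
#'   rows) when `features` is supplied.
#' @param features feature annotation data.frame with `probe_count` and
#'   `crosshyb` columns and feature ids as rownames or in `feature_id`;
#'   ignored when `x` is a `MetCohort` (its `rowData()` is used).
#' @return Object of the same class as `x`, restricted to reliable features.
#' @export
filterByAnnotation <- function(x, features = NULL) {
  if (is(x, "MetCohort")) features <- featureInfo(x)
  if (is.null(features)) stop("feature annotation is required")
  ids <- if ("feature_id" %in% colnames(features)) features$feature_id
  else rownames(features)
  expr_ids <- rownames(.asExprs(x))
  missing <- setdiff(expr_ids, ids)
  if (length(missing))
    stop("features present in the matrix but absent from the annotation: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  ann <- features[match(expr_ids, ids), , drop = FALSE]
  keep <- ann$probe_count >= 4L & !ann$crosshyb
  x[keep, , drop = FALSE]
}

#' Remove features with high technical variance
#'
#' Computes the per-feature sample variance across technical-replicate
#' control profiles and removes every feature whose variance is at or above
#' the `1 - top_frac` quantile (ties at the cutoff are all removed). This is
#' the control-array reliability screen: high replicate-to-replicate variance
#' marks technical rather than biological variability.
#'
#' @param x a [MetCohort-class] or expression matrix.
#' @param tech numeric matrix of technical replicate profiles with the same
#'   feature set (rownames) as `x`; at least 2 columns.
#' @param top_frac fraction of highest-variance features to remove
#'   (default 0.10).
#' @return Same class as `x`, restricted to retained features. For a
#'   `MetCohort` the measured variance is recorded in
#'   `rowData()$tech_variance` (for all input features it is computed before
#'   filtering; retained rows keep their value).
#' @export
filterByTechnicalVariance <- function(x, tech, top_frac = 0.10) {
  .assertFraction(top_frac, "top_frac")
  expr_ids <- rownames(.asExprs(x))
  if (ncol(tech) < 2L)
    stop("need at least 2 technical replicates")
  if (!setequal(rownames(tech), expr_ids))
    stop("technical replicate matrix and expression matrix must cover the ",
         "same feature set")
  tech <- tech[expr_ids, , drop = FALSE]
  v <- .rowVars(tech)
  if (is(x, "MetCohort"))
    SummarizedExperiment::rowData(x)$tech_variance <- v
  if (top_frac == 0) return(x)
  cutoff <- quantile(v, probs = 1 - top_frac, names = FALSE)
  x[v < cutoff, , drop = FALSE]
}

#' Remove batch-associated principal components
#'
#' Decomposes the feature-centered expression matrix into principal
#' components over samples (via SVD), scores the association of each of the
#' first `n_examine` components with batch as the R-squared of a one-way
#' ANOVA of component scores on batch label, and reconstructs the data
#' without the `n_remove` most batch-associated components. No re-scaling is
#' applied after removal.
#'
#' @param x a [MetCohort-class] or expression matrix (features x samples).
#' @param batches integer batch label per sample; taken from the cohort
#'   annotation when `x` is a `MetCohort`.
#' @param n_examine number of leading components examined (default 10,
#'   capped at `n_samples - 1`).
#' @param n_remove number of components removed (default 2).
#' @return A [BatchCorrection-class]. When `x` is a `MetCohort` the
#'   corrected matrix replaces its `"exprs"` assay and the cohort is
#'   returned in the `corrected` slot's attribute-free matrix form; use
#'   [applyBatchCorrection()] to obtain a corrected cohort in one call.
#' @export
removeBatchComponents <- function(x, batches = NULL, n_examine = 10L,
                                  n_remove = 2L) {
  m <- .asExprs(x)
  if (is(x, "MetCohort") && is.null(batches)) batches <- batchOf(x)
  if (is.null(batches)) stop("batch labels are required")
  if (length(batches) != ncol(m))
    stop("one batch label per sample is required")
  if (length(unique(batches)) < 2L)
    stop("batch association is undefined with a single batch")
  n_examine <- min(.assertCount(n_examine, "n_examine", 1L), ncol(m) - 1L)
  n_remove <- .assertCount(n_remove, "n_remove", 1L)
  if (n_remove > n_examine)
    stop("n_remove must not exceed n_examine")

  mu <- rowMeans(m)
  xc <- m - mu
  sv <- svd(xc, nu = 0, nv = n_examine)
  d2 <- sv$d^2
  variance_captured <- sum(d2[seq_len(n_examine)]) / sum(d2)

  batch_f <- factor(batches)
  r2 <- vapply(seq_len(n_examine), function(k) {
    score <- sv$v[, k]
    fit <- lm(score ~ batch_f)
    summary(fit)$r.squared
  }, numeric(1))
  names(r2) <- paste0("PC", seq_len(n_examine))

  drop_idx <- order(r2, decreasing = TRUE)[seq_len(n_remove)]
  drop_idx <- sort(drop_idx)
  vdrop <- sv$v[, drop_idx, drop = FALSE]
  ## reconstruction without the removed sample-space components
  corrected <- m - (xc %*% vdrop) %*% t(vdrop)
  dimnames(corrected) <- dimnames(m)
  new("BatchCorrection", corrected = corrected,
      removedPCs = as.integer(drop_idx), batchR2 = r2,
      varianceCaptured = variance_captured,
      removedDirections = vdrop)
}

#' @rdname removeBatchComponents
#' @param cohort a [MetCohort-class].
#' @param ... passed to [removeBatchComponents()].
#' @return `applyBatchCorrection()`: the cohort with its `"exprs"` assay
#'   replaced by the corrected matrix.
#' @export
applyBatchCorrection <- function(cohort, ...) {
  stopifnot(is(cohort, "MetCohort"))
  bc <- removeBatchComponents(cohort, ...)
  SummarizedExperiment::assay(cohort, "exprs") <- bc@corrected
  cohort
}

#' Maximum batch R-squared over leading components
#'
#' Diagnostic: the largest one-way-ANOVA R-squared of any of the first
#' `n_examine` principal-component score vectors on batch. Used to verify
#' that batch correction reduced batch-associated variation.
#'
#' @inheritParams removeBatchComponents
#' @return A single numeric value in `[0, 1]`.
#' @export
maxBatchR2 <- function(x, batches = NULL, n_examine = 10L) {
  m <- .asExprs(x)
  if (is(x, "MetCohort") && is.null(batches)) batches <- batchOf(x)
  n_examine <- min(n_examine, ncol(m) - 1L)
  xc <- m - rowMeans(m)
  sv <- svd(xc, nu = 0, nv = n_examine)
  batch_f <- factor(batches)
  max(vapply(seq_len(n_examine), function(k)
    summary(lm(sv$v[, k] ~ batch_f))$r.squared, numeric(1)))
}
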