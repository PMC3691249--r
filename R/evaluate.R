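#' Odds-ratio and AUC result containers
#'
#' `ORResult` holds an odds ratio with its Wald confidence interval and
#' two-sided p-value; `AUCResult` holds a Mann-Whitney AUC with a
#' class-stratified percentile-bootstrap confidence interval; `KMResult`
#' holds per-group Kaplan-Meier step functions, medians and the two-group
#' log-rank p-value.
#'
#' @slot or,ciLow,ciHigh,p odds ratio, 95% CI bounds, two-sided p-value.
#' @slot method `"wald_2x2"` or `"logistic"`.
#' @slot corrected `TRUE` when the Haldane-Anscombe +0.5 correction was
#'   applied to a table with a zero cell.
#' @aliases AUCResult-class KMResult-class
#' @export
setClass("ORResult", representation(
  or = "numeric", ciLow = "numeric", ciHigh = "numeric", p = "numeric",
  method = "character", corrected = "logical"))

setValidity("ORResult", function(object) {
  if (object@ciLow > object@or || object@or > object@ciHigh)
    "confidence interval must bracket the odds ratio" else TRUE
})

setMethod("show", "ORResult", function(object) {
  cat(sprintf("OR %.2f (95%% CI %.2f-%.2f), p = %.3g [%s]%s\n",
              object@or, object@ciLow, object@ciHigh, object@p,
              object@method,
              if (object@corrected) " (+0.5 zero-cell correction)" else ""))
})

#' @rdname ORResult-class
#' @slot auc,nBoot AUC point estimate and bootstrap replicate count.
#' @export
setClass("AUCResult", representation(
  auc = "numeric", ciLow = "numeric", ciHigh = "numeric",
  nBoot = "integer"))

setMethod("show", "AUCResult", function(object) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f; %d bootstraps)\n",
              object@auc, object@ciLow, object@ciHigh, object@nBoot))
})

#' @rdname ORResult-class
#' @slot label endpoint label.
#' @slot curves named list per group: data.frame(time, n_risk, surv).
#' @slot medians named numeric median survival per group (NA when the curve
#'   never crosses 0.5).
#' @slot logrankP log-rank p-value (NA for a single group).
#' @export
setClass("KMResult", representation(
  label = "character", curves = "list", medians = "numeric",
  logrankP = "numeric"))

setMethod("show", "KMResult", function(object) {
  cat("KMResult [", object@label, "]: ",
      paste(sprintf("%s median %.2f", names(object@medians),
                    object@medians), collapse = "; "),
      sprintf("; log-rank p = %.3g\n", object@logrankP), sep = "")
})

#' Odds ratio of a 2x2 contingency table
#'
#' Computes `OR = ad / (bc)` with the Wald confidence interval
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` and a two-sided p-value
#' from the Wald z statistic. Cell layout: `a` exposed cases, `b` exposed
#' controls, `c` unexposed cases, `d` unexposed controls. A zero cell
#' triggers the Haldane-Anscombe correction (+0.5 to every cell, flagged in
#' the result); a fully zero row or column is an error.
#'
#' @param a,b,c,d nonnegative integer cell counts.
#' @param level confidence level (default 0.95).
#' @return An [ORResult-class].
#' @examples
#' oddsRatio2x2(42, 28, 21, 95)  # OR 6.79 (3.46-13.29)
#' @export
oddsRatio2x2 <- function(a, b, c, d, level = 0.95) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be nonnegative integers")
  if (sum(cells) == 0) stop("empty table")
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    stop("a fully zero row or column leaves the odds ratio undefined")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  lor <- log(cells["a"]) + log(cells["d"]) - log(cells["b"]) - log(cells["c"])
  se <- sqrt(sum(1 / cells))
  z <- qnorm(1 - (1 - level) / 2)
  new("ORResult", or = unname(exp(lor)),
      ciLow = unname(exp(lor - z * se)), ciHigh = unname(exp(lor + z * se)),
      p = unname(2 * pnorm(abs(lor / se), lower.tail = FALSE)),
      method = "wald_2x2", corrected = corrected)
}

## Wald OR for one glm coefficient, per `scale` units of the covariate.
.glmOR <- function(fit, term, scale = 1, level = 0.95) {
  cf <- summary(fit)$coefficients
  if (!(term %in% rownames(cf)))
    stop("term dropped from the fit: ", term)
  est <- cf[term, "Estimate"] * scale
  se <- cf[term, "Std. Error"] * scale
  z <- qnorm(1 - (1 - level) / 2)
  new("ORResult", or = exp(est), ciLow = exp(est - z * se),
      ciHigh = exp(est + z * se),
      p = 2 * pnorm(abs(est / se), lower.tail = FALSE),
      method = "logistic", corrected = FALSE)
}

#' Univariable logistic odds ratio
#'
#' Logistic regression of case status on a single covariate; the odds ratio
#' is reported per unit of the transformed covariate. For classifier scores
#' use `transform = "per_10pct_score"` to express the OR per 0.10 score
#' increment; `"log2"` log2-transforms a positive covariate.
#'
#' @param covariate numeric or logical covariate vector.
#' @param is_case logical case indicator.
#' @param transform one of `"identity"`, `"per_10pct_score"`, `"log2"`.
#' @param level confidence level.
#' @return An [ORResult-class].
#' @export
uvaLogisticOR <- function(covariate, is_case,
                          transform = c("identity", "per_10pct_score",
                                        "log2"),
                          level = 0.95) {
  transform <- match.arg(transform)
  y <- as.integer(as.logical(is_case))
  v <- as.numeric(covariate)
  if (transform == "log2") v <- log2(v)
  keep <- is.finite(v) & !is.na(y)
  v <- v[keep]; y <- y[keep]
  if (length(unique(v)) < 2L)
    stop("covariate has no variation; odds ratio undefined")
  fit <- withCallingHandlers(
    glm(y ~ v, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        stop("complete separation: univariable odds ratio unbounded",
             call. = FALSE)
      invokeRestart("muffleWarning")
    })
  scale <- if (transform == "per_10pct_score") 0.10 else 1
  .glmOR(fit, "v", scale = scale, level = level)
}

#' Multivariable logistic odds ratios
#'
#' Joint logistic model of case status on a covariate table; returns the
#' adjusted Wald odds ratio per covariate. Rank-deficient columns are
#' dropped with a warning. Set `adjust_for_treatment` to include the four
#' post-surgery treatment binaries (adjuvant/salvage radiation and androgen
#' deprivation) as adjustment covariates when present in `covariates`.
#'
#' @param covariates data.frame of covariates (numeric/logical columns).
#'   Score columns named `gc`, `cc` or `gcc` are reported per 0.10 score
#'   increment.
#' @param is_case logical case indicator.
#' @param adjust_for_treatment logical; when `FALSE`, treatment columns
#'   (`adj_radiation`, `adj_adt`, `salv_radiation`, `salv_adt`) are excluded
#'   from the fit.
#' @param level confidence level.
#' @return Named list of [ORResult-class], one per (non-treatment)
#'   covariate.
#' @export
mvaLogisticOR <- function(covariates, is_case, adjust_for_treatment = TRUE,
                          level = 0.95) {
  y <- as.integer(as.logical(is_case))
  df <- as.data.frame(lapply(covariates, as.numeric))
  treat <- c("adj_radiation", "adj_adt", "salv_radiation", "salv_adt")
  if (!adjust_for_treatment)
    df <- df[, setdiff(colnames(df), treat), drop = FALSE]
  if (ncol(df) == 0L) return(structure(list(), names = character()))
  keep <- complete.cases(df)
  df <- df[keep, , drop = FALSE]; y <- y[keep]
  fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
  cf <- coef(fit)
  dropped <- names(cf)[is.na(cf)]
  if (length(dropped))
    warning("rank-deficient covariates dropped: ",
            paste(dropped, collapse = ", "))
  report <- setdiff(colnames(df), treat)
  res <- lapply(report, function(nm) {
    if (nm %in% dropped) return(NULL)
    scale <- if (nm %in% c("gc", "cc", "gcc")) 0.10 else 1
    .glmOR(fit, nm, scale = scale, level = level)
  })
  names(res) <- report
  res[!vapply(res, is.null, logical(1))]
}

#' AUC with bootstrap confidence interval
#'
#' The area under the ROC curve computed as the Mann-Whitney concordance
#' probability (ties count one half), with a class-stratified percentile
#' bootstrap confidence interval.
#'
#' @param scores numeric classifier scores.
#' @param is_case logical case indicator; both classes must be present.
#' @param n_boot bootstrap replicates (default 2000).
#' @param level confidence level.
#' @param seed seed for the bootstrap.
#' @return An [AUCResult-class].
#' @examples
#' aucCI(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE), n_boot = 50)
#' @export
aucCI <- function(scores, is_case, n_boot = 2000L, level = 0.95,
                  seed = 1L) {
  y <- as.logical(is_case)
  stopifnot(length(scores) == length(y))
  if (!any(y) || all(y)) stop("both classes must be present")
  auc <- .mannWhitneyAUC(scores, y)
  boots <- .withSeed(seed, {
    idx_case <- which(y); idx_ctrl <- which(!y)
    vapply(seq_len(n_boot), function(b) {
      i <- c(sample(idx_case, length(idx_case), replace = TRUE),
             sample(idx_ctrl, length(idx_ctrl), replace = TRUE))
      .mannWhitneyAUC(scores[i], y[i])
    }, numeric(1))
  })
  alpha <- 1 - level
  ci <- quantile(boots, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  new("AUCResult", auc = auc, ciLow = min(ci[1], auc),
      ciHigh = max(ci[2], auc), nBoot = as.integer(n_boot))
}

.mannWhitneyAUC <- function(scores, y) {
  r <- rank(scores)
  n1 <- sum(y); n0 <- sum(!y)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Kaplan-Meier curves with a log-rank test
#'
#' Product-limit survival estimates per group, per-group median survival
#' (the first time survival drops to 0.5 or below; undefined when the curve
#' never does), and the unweighted two-group log-rank chi-square p-value
#' (1 degree of freedom).
#'
#' @param times nonnegative event/censoring times (years).
#' @param events logical or 0/1 event indicators.
#' @param group group label per observation.
#' @param label endpoint label for the result.
#' @return A [KMResult-class].
#' @export
kmLogrank <- function(times, events, group = rep("all", length(times)),
                      label = "survival") {
  if (any(times < 0)) stop("survival times must be nonnegative")
  events <- as.integer(as.logical(events))
  group <- factor(group)
  fit <- survival::survfit(survival::Surv(times, events) ~ group)
  smry <- summary(fit, censored = TRUE)
  strata <- if (is.null(smry$strata)) factor(rep(levels(group)[1],
                                                 length(smry$time)))
  else smry$strata
  curves <- lapply(levels(strata), function(s) {
    sel <- strata == s
    data.frame(time = smry$time[sel], n_risk = smry$n.risk[sel],
               surv = smry$surv[sel])
  })
  names(curves) <- sub("^group=", "", levels(strata))
  tbl <- summary(fit)$table
  medians <- if (is.matrix(tbl)) setNames(tbl[, "median"],
                                          sub("^group=", "", rownames(tbl)))
  else setNames(tbl[["median"]], levels(group)[1])
  p <- NA_real_
  if (nlevels(group) >= 2L) {
    sd <- survival::survdiff(survival::Surv(times, events) ~ group)
    p <- pchisq(sd$chisq, df = nlevels(group) - 1L, lower.tail = FALSE)
  }
  new("KMResult", label = label, curves = curves,
      medians = as.numeric(medians) |> setNames(names(medians)),
      logrankP = p)
}

#' Gleason-by-risk reclassification table
#'
#' Cross-tabulates pathologic Gleason category (<=6, 7, 8, >=9) against the
#' dichotomized classifier risk group (score <=0.5 vs >0.5), reporting per
#' cell the sample count, the number (and percent) of metastasis events and
#' of prostate-cancer deaths.
#'
#' @param gs integer Gleason scores in 2..10.
#' @param scores classifier scores in `[0, 1]`.
#' @param met_events,pcsm_events logical event indicators, aligned with `gs`.
#' @return data.frame with one row per (Gleason category, risk group).
#' @export
reclassificationTable <- function(gs, scores, met_events, pcsm_events) {
  if (any(gs < 2L | gs > 10L)) stop("Gleason scores must lie in 2..10")
  risk <- classifyRisk(scores)
  cat_gs <- cut(gs, breaks = c(-Inf, 6, 7, 8, Inf),
                labels = c("<=6", "7", "8", ">=9"))
  met_events <- as.logical(met_events)
  pcsm_events <- as.logical(pcsm_events)
  out <- expand.grid(gs_category = levels(cat_gs),
                     gc_group = c("<=0.5", ">0.5"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(out)), function(i) {
    sel <- cat_gs == out$gs_category[i] &
      risk == (if (out$gc_group[i] == ">0.5") "high" else "low")
    n <- sum(sel)
    data.frame(n = n, n_met = sum(met_events[sel]),
               pct_met = if (n) round(100 * sum(met_events[sel]) / n, 1)
               else 0,
               n_pcsm = sum(pcsm_events[sel]),
               pct_pcsm = if (n) round(100 * sum(pcsm_events[sel]) / n, 1)
               else 0)
  })
  cbind(out, do.call(rbind, rows))
}

#' Median potential follow-up (reverse Kaplan-Meier)
#'
#' Estimates the cohort's potential follow-up duration by reversing the
#' roles in the Kaplan-Meier estimator: end of contact is the "event" and
#' death censors. Returns the median of that curve (`NA` when it never
#' reaches 0.5, reported as not reached).
#'
#' @param times nonnegative time to last contact or death (years).
#' @param death_events logical death indicators.
#' @return Median potential follow-up in years (`NA` if not reached).
#' @export
medianFollowup <- function(times, death_events) {
  if (!length(times)) stop("no follow-up times supplied")
  if (any(times < 0)) stop("times must be nonnegative")
  rev_event <- 1L - as.integer(as.logical(death_events))
  fit <- survival::survfit(survival::Surv(times, rev_event) ~ 1)
  unname(summary(fit)$table[["median"]])
}
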