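#' Simulate a nested case-control expression cohort
#'
#' Generates a desk-scale cohort with the statistical structure the pipeline
#' assumes: log2-scale expression with additive per-(batch, feature) offsets,
#' a subset of informative features shifted by `effect_size` in cases only
#' (the NED and PSA control groups draw from the same expression
#' distribution), clinicopathologic covariates correlated with case status
#' (higher Gleason, SVI, ECE and node-positivity rates in cases), and
#' survival endpoints in which a larger planted-signal burden implies
#' shorter time to prostate-cancer death.
#'
#' The generator is a pure function of its configuration: the same
#' `SimConfig` (seed included) yields bit-identical output, and the caller's
#' RNG state is left untouched.
#'
#' @param config a [SimConfig-class] from [simConfig()].
#' @return A [MetCohort-class]. `rowData()` carries the feature annotation
#'   (`probe_count`, `crosshyb`) plus ground-truth columns (`is_informative`,
#'   `effect_sign`, `base_mean`, `tech_sd`) used by
#'   [simulateTechReplicates()] and by recovery diagnostics.
#' @seealso [simulateTechReplicates()]
#' @examples
#' coh <- simulateCohort(simConfig(n_features = 200, n_cases = 20,
#'                                 n_ned = 10, n_psa = 10, seed = 7))
#' coh
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  .withSeed(config@seed, .simulateCohortImpl(config))
}

.simulateCohortImpl <- function(cfg) {
  p <- cfg@n_features
  n <- cfg@n_cases + cfg@n_psa + cfg@n_ned
  if (n < 2L) stop("need at least 2 samples")

  feature_ids <- sprintf("feat%06d", seq_len(p))
  sample_ids <- sprintf("samp%04d", seq_len(n))
  group <- c(rep("MET", cfg@n_cases), rep("PSA", cfg@n_psa),
             rep("NED", cfg@n_ned))
  is_case <- group == "MET"

  ## --- feature annotation -------------------------------------------------
  informative <- sort(sample.int(p, cfg@n_informative))
  is_informative <- seq_len(p) %in% informative
  effect_sign <- integer(p)
  effect_sign[informative] <- sample(c(-1L, 1L), cfg@n_informative,
                                     replace = TRUE)
  base_mean <- rnorm(p, mean = 7, sd = 1.5)
  probe_count <- ifelse(runif(p) < cfg@frac_low_probe,
                        sample(1:3, p, replace = TRUE), 4L)
  crosshyb <- runif(p) < cfg@frac_crosshyb
  ## baseline technical replicate noise 0.2 log2 units; unreliable features
  ## get a 10x inflated technical SD so they land in the top variance decile
  tech_sd <- rep(0.2, p)
  tech_sd[runif(p) < cfg@tech_unreliable_frac] <- 2.0

  ## --- expression ---------------------------------------------------------
  batch <- sample.int(cfg@n_batches, n, replace = TRUE)
  batch_offsets <- matrix(rnorm(cfg@n_batches * p, sd = cfg@batch_sd),
                          nrow = p, ncol = cfg@n_batches)
  x <- matrix(rnorm(p * n, sd = cfg@noise_sd), nrow = p, ncol = n,
              dimnames = list(feature_ids, sample_ids))
  x <- x + base_mean
  x <- x + batch_offsets[, batch, drop = FALSE]
  if (cfg@n_informative > 0L && any(is_case))
    x[informative, is_case] <- x[informative, is_case] +
      cfg@effect_size * effect_sign[informative]

  ## planted-signal burden: mean signed deviation from the feature baseline
  ## over informative features (0 when nothing is planted)
  burden <- if (cfg@n_informative > 0L)
    colMeans((x[informative, , drop = FALSE] - base_mean[informative]) *
               effect_sign[informative])
  else rep(0, n)

  ## --- clinical covariates (rates mirror the study's cohort table) --------
  gs_levels <- 5:10
  gs_p_case <- c(0.01, 0.02, 0.36, 0.14, 0.43, 0.04)
  gs_p_ctrl <- c(0.04, 0.12, 0.56, 0.14, 0.13, 0.01)
  gleason <- ifelse(is_case,
                    gs_levels[max.col(t(rmultinom(n, 1, gs_p_case)))],
                    gs_levels[max.col(t(rmultinom(n, 1, gs_p_ctrl)))])
  ppsa <- 2^rnorm(n, mean = ifelse(is_case, 3.3, 3.5), sd = 1.3)
  ppsa[runif(n) < 0.03] <- NA_real_  # ~3% missing pre-operative PSA
  svi <- runif(n) < ifelse(is_case, 0.49, 0.28)
  sm_pos <- runif(n) < ifelse(is_case, 0.54, 0.46)
  ece <- runif(n) < ifelse(is_case, 0.61, 0.40)
  node_pos <- runif(n) < ifelse(is_case, 0.23, 0.08)
  adj_radiation <- runif(n) < ifelse(is_case, 0.15, 0.07)
  adj_adt <- runif(n) < ifelse(is_case, 0.32, 0.12)
  has_bcr <- group %in% c("MET", "PSA")
  salv_radiation <- has_bcr & runif(n) < 0.25
  salv_adt <- has_bcr & runif(n) < 0.45

  ## --- survival from BCR: exponential, rate scaled by burden --------------
  zburden <- if (sd(burden) > 0) (burden - mean(burden)) / sd(burden)
  else burden
  censor_t <- runif(n, 5, 20)
  t_met <- rep(Inf, n)
  t_met[is_case] <- rexp(sum(is_case),
                         rate = 0.5 * exp(0.7 * zburden[is_case]))
  t_met[is_case] <- pmin(t_met[is_case], 4.99)  # cases metastasize within 5y
  ## ~10% of PSA controls metastasize late (outside the case definition)
  late <- group == "PSA" & runif(n) < 0.10
  t_met[late] <- runif(sum(late), 5.5, 12)
  e_met <- is.finite(t_met)
  t_met[!e_met] <- censor_t[!e_met]

  ## prostate-cancer death follows metastasis; faster for higher burden
  t_pcsm_raw <- ifelse(e_met,
                       t_met + rexp(n, rate = 0.25 * exp(0.5 * zburden)),
                       Inf)
  t_other <- rexp(n, rate = 1 / 25)  # other-cause mortality
  e_pcsm <- is.finite(t_pcsm_raw) & t_pcsm_raw <= pmin(censor_t, t_other)
  t_pcsm <- ifelse(e_pcsm, t_pcsm_raw, pmin(censor_t, t_other))
  e_os <- e_pcsm | (t_other <= censor_t)
  t_os <- ifelse(e_pcsm, t_pcsm, pmin(censor_t, t_other))

  ## --- train/validation split, stratified by case status ------------------
  split <- rep("validation", n)
  for (cls in c(TRUE, FALSE)) {
    idx <- which(is_case == cls)
    k <- round(cfg@train_frac * length(idx))
    split[sample(idx, k)] <- "train"
  }

  featureData <- data.frame(
    feature_id = feature_ids, probe_count = as.integer(probe_count),
    crosshyb = crosshyb, tech_variance = NA_real_,
    is_informative = is_informative, effect_sign = effect_sign,
    base_mean = base_mean, tech_sd = tech_sd, row.names = feature_ids)
  sampleData <- data.frame(
    sample_id = sample_ids, group = group, is_case = is_case,
    batch = as.integer(batch), split = split,
    gleason = as.integer(gleason), ppsa = ppsa, svi = svi,
    sm_pos = sm_pos, ece = ece, node_pos = node_pos,
    adj_radiation = adj_radiation, adj_adt = adj_adt,
    salv_radiation = salv_radiation, salv_adt = salv_adt,
    t_met = t_met, e_met = e_met, t_pcsm = t_pcsm, e_pcsm = e_pcsm,
    t_os = t_os, e_os = e_os, burden = burden, row.names = sample_ids)
  MetCohort(x, featureData, sampleData)
}

#' Simulate technical-replicate control profiles
#'
#' Emulates the cell-line control array run with each hybridization batch:
#' every replicate is the fixed ground-truth profile (`base_mean` in the
#' feature annotation) plus technical noise with per-feature SD `tech_sd`.
#' Features flagged as technically unreliable carry a ~10x inflated SD, so
#' with the default 19 replicates they land in the top variance decile with
#' high probability and are removed by [filterByTechnicalVariance()].
#'
#' @param config a [SimConfig-class]; `n_tech_reps` must be at least 2.
#' @param features feature annotation data.frame as produced by
#'   [simulateCohort()] (needs `base_mean` and `tech_sd` columns, feature ids
#'   as rownames or in a `feature_id` column).
#' @return numeric matrix, features x `n_tech_reps`, log2 scale.
#' @export
simulateTechReplicates <- function(config, features) {
  stopifnot(is(config, "SimConfig"))
  if (config@n_tech_reps < 2L)
    stop("n_tech_reps must be >= 2: a technical variance is undefined ",
         "for fewer than two replicates")
  if (!all(c("base_mean", "tech_sd") %in% colnames(features)))
    stop("feature annotation must carry 'base_mean' and 'tech_sd'")
  ids <- if ("feature_id" %in% colnames(features)) features$feature_id
  else rownames(features)
  p <- nrow(features)
  r <- config@n_tech_reps
  .withSeed(.subSeed(config@seed, 104729L), {
    matrix(rnorm(p * r, mean = features$base_mean, sd = features$tech_sd),
           nrow = p, ncol = r,
           dimnames = list(ids, sprintf("techrep%02d", seq_len(r))))
  })
}
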