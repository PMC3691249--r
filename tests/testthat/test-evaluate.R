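test_that("2x2 odds ratios reproduce the validation-cohort tables", {
  # dichotomized genomic-classifier risk vs case status
  r <- oddsRatio2x2(42, 28, 21, 95)
  expect_equal(round(r@or, 2), 6.79)
  expect_equal(round(r@ciLow, 2), 3.46)
  expect_equal(round(r@ciHigh, 2), 13.29)
  # Gleason >= 8
  r <- oddsRatio2x2(35, 36, 28, 87)
  expect_equal(round(r@or, 2), 3.02)
  expect_equal(round(r@ciLow, 2), 1.61)
  expect_equal(round(r@ciHigh, 2), 5.68)
  # seminal vesicle invasion
  r <- oddsRatio2x2(31, 35, 32, 88)
  expect_equal(round(r@or, 2), 2.44)
  expect_equal(round(r@ciLow, 2), 1.30)
  expect_equal(round(r@ciHigh, 2), 4.58)
})

test_that("2x2 odds ratio symmetries and edge handling hold", {
  r <- oddsRatio2x2(1, 1, 1, 1)
  expect_equal(r@or, 1)
  expect_equal(log(r@ciHigh), -log(r@ciLow))  # symmetric on the log scale
  # swapping exposed/unexposed rows inverts the OR and the CI
  a <- oddsRatio2x2(42, 28, 21, 95)
  b <- oddsRatio2x2(21, 95, 42, 28)
  expect_equal(b@or, 1 / a@or)
  expect_equal(b@ciLow, 1 / a@ciHigh)
  expect_equal(b@ciHigh, 1 / a@ciLow)
  # transpose (exposure/outcome exchange) leaves the OR unchanged
  tr <- oddsRatio2x2(42, 21, 28, 95)
  expect_equal(tr@or, a@or)
  # zero cell: Haldane-Anscombe correction, flagged
  z <- oddsRatio2x2(0, 10, 5, 10)
  expect_true(z@corrected)
  expect_true(is.finite(z@or))
  # a fully zero margin is an error
  expect_error(oddsRatio2x2(0, 0, 5, 10), "zero row or column")
  expect_error(oddsRatio2x2(0, 5, 0, 10), "zero row or column")
})

test_that("univariable logistic OR on a binary covariate equals the 2x2 OR", {
  set.seed(71)
  y <- runif(200) < 0.4
  x <- runif(200) < ifelse(y, 0.6, 0.3)
  r_glm <- uvaLogisticOR(x, y)
  a <- sum(x & y); b <- sum(x & !y); c_ <- sum(!x & y); d_ <- sum(!x & !y)
  r_2x2 <- oddsRatio2x2(a, b, c_, d_)
  expect_equal(r_glm@or, r_2x2@or, tolerance = 1e-6)
  expect_equal(r_glm@ciLow, r_2x2@ciLow, tolerance = 1e-4)
  expect_equal(r_glm@ciHigh, r_2x2@ciHigh, tolerance = 1e-4)
  expect_error(uvaLogisticOR(rep(1, 200), y), "no variation")
})

test_that("per-10-percent score ORs scale the logistic coefficient", {
  set.seed(73)
  y <- rep(c(TRUE, FALSE), each = 100)
  s <- pmin(pmax(ifelse(y, 0.6, 0.4) + rnorm(200, 0, 0.15), 0), 1)
  r <- uvaLogisticOR(s, y, transform = "per_10pct_score")
  fit <- glm(y ~ s, family = binomial())
  expect_equal(r@or, exp(0.1 * coef(fit)["s"]), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("multivariable adjustment behaves on independent covariates", {
  set.seed(79)
  n <- 600
  x1 <- runif(n) < 0.4           # truly associated
  x2 <- runif(n) < 0.5           # pure noise
  x3 <- rnorm(n)                 # pure noise
  eta <- -0.8 + 1.2 * x1
  y <- runif(n) < plogis(eta)
  uni <- uvaLogisticOR(x1, y)
  res <- mvaLogisticOR(data.frame(x1 = x1, x2 = x2, x3 = x3), y)
  expect_named(res, c("x1", "x2", "x3"))
  # adjusted OR of the associated covariate tracks its univariable OR
  expect_lt(abs(log(res$x1@or) - log(uni@or)), 0.25)
  # noise covariates stay near OR 1 (CI covers 1)
  expect_true(res$x2@ciLow < 1 && res$x2@ciHigh > 1)
  # rank-deficient duplicate columns are dropped with a warning
  expect_warning(
    res2 <- mvaLogisticOR(data.frame(x1 = x1, dup = x1), y), "dropped")
  expect_false("dup" %in% names(res2))
  # intercept-only fit reports no covariate ORs
  expect_length(mvaLogisticOR(data.frame()[seq_len(n), , drop = FALSE], y),
                0L)
})

test_that("AUC equals the Mann-Whitney concordance and matches pROC", {
  # brute force over all 4 case-control pairs: 3 of 4 concordant
  r <- aucCI(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE),
             n_boot = 100, seed = 1)
  expect_equal(r@auc, 0.75)
  expect_true(r@ciLow <= r@auc && r@auc <= r@ciHigh)
  # perfect separation
  expect_equal(aucCI(c(1, 2, 3, 10, 11), c(F, F, F, T, T),
                     n_boot = 10)@auc, 1.0)
  # label-free scores at large n sit near 1/2
  set.seed(83)
  s <- rnorm(2000); y <- runif(2000) < 0.4
  expect_lt(abs(aucCI(s, y, n_boot = 10)@auc - 0.5), 0.04)
  # complementarity for tie-free scores
  expect_equal(aucCI(s, y, n_boot = 10)@auc + aucCI(-s, y, n_boot = 10)@auc,
               1.0)
  # independent oracle
  skip_if_not_installed("pROC")
  set.seed(89)
  s2 <- rnorm(150); y2 <- runif(150) < 0.5
  auc_proc <- as.numeric(pROC::auc(pROC::roc(y2, s2, quiet = TRUE,
                                             direction = "<")))
  expect_equal(aucCI(s2, y2, n_boot = 10)@auc, auc_proc, tolerance = 1e-12)
  expect_error(aucCI(s, rep(TRUE, 2000)), "both classes")
})

test_that("Kaplan-Meier estimates match the hand product-limit calculation", {
  # events at t=1 and t=2, censoring at 1.5 and 3:
  # S(1) = 3/4; S(2) = 3/4 * 1/2 = 0.375
  km <- kmLogrank(c(1, 1.5, 2, 3), c(1, 0, 1, 0))
  cv <- km@curves[[1]]
  expect_equal(cv$surv[cv$time == 1], 0.75)
  expect_equal(cv$surv[cv$time == 2], 0.375)
  # without censoring the estimator is the empirical survival function
  tt <- c(1, 2, 3, 4, 5)
  km2 <- kmLogrank(tt, rep(1, 5))
  cv2 <- km2@curves[[1]]
  expect_equal(cv2$surv, 1 - seq_len(5) / 5)
  # no events: survival stays 1, median undefined
  km3 <- kmLogrank(c(2, 3, 4), c(0, 0, 0))
  expect_true(all(km3@curves[[1]]$surv == 1))
  expect_true(is.na(km3@medians))
  # two identical groups: log-rank chi-square 0, p = 1
  km4 <- kmLogrank(rep(tt, 2), rep(1, 10), rep(c("a", "b"), each = 5))
  expect_equal(km4@logrankP, 1)
  expect_error(kmLogrank(c(-1, 2), c(1, 1)), "nonnegative")
})

test_that("reclassification tables partition the cohort", {
  set.seed(97)
  n <- 120
  gs <- sample(c(6L, 7L, 8L, 9L, 10L), n, replace = TRUE)
  sc <- runif(n)
  met <- runif(n) < 0.3
  pcsm <- met & runif(n) < 0.5          # death requires metastasis
  tab <- reclassificationTable(gs, sc, met, pcsm)
  expect_equal(sum(tab$n), n)           # conservation
  expect_true(all(tab$n_pcsm <= tab$n_met))
  expect_true(all(tab$n_met <= tab$n))
  # a cell with n=18 and 2 events reports 11.1%
  tab2 <- reclassificationTable(rep(6L, 18), rep(0.2, 18),
                                c(rep(TRUE, 2), rep(FALSE, 16)),
                                rep(FALSE, 18))
  cell <- tab2[tab2$gs_category == "<=6" & tab2$gc_group == "<=0.5", ]
  expect_equal(cell$n, 18)
  expect_equal(cell$pct_met, round(100 * 2 / 18, 1))
  # all-low scores leave the high column empty
  expect_true(all(tab2$n[tab2$gc_group == ">0.5"] == 0))
  expect_error(reclassificationTable(c(1L, 7L), c(0.1, 0.2),
                                     c(TRUE, FALSE), c(FALSE, FALSE)),
               "2..10")
})

test_that("reverse-KM follow-up matches hand computation", {
  # reversed roles: end of contact is the event, death censors.
  # times (2,4,5,7,9,12), deaths at 4 and 9:
  # S(2)=5/6, S(5)=5/6*3/4=0.625, S(7)=0.625*2/3=0.4167 -> median 7
  expect_equal(medianFollowup(c(2, 4, 5, 7, 9, 12),
                              c(0, 1, 0, 0, 1, 0)), 7)
  # no deaths: the median of the observed times
  expect_equal(medianFollowup(c(1, 2, 3, 4, 5), rep(FALSE, 5)), 3)
  # all deaths: everything is censored, median not reached
  expect_true(is.na(medianFollowup(c(1, 2, 3), rep(TRUE, 3))))
  expect_error(medianFollowup(numeric(0), logical(0)), "no follow-up")
})
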