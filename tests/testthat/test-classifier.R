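test_that("elimination curve has the expected shape and ordering", {
  d <- plantedMatrix(p = 2, k = 1, n1 = 20, n0 = 20, effect = 2, seed = 3)
  ec <- backwardEliminate(d$x, d$y, rownames(d$x), fastForest())
  expect_identical(ec@sizes, c(2L, 1L))
  expect_true(ec@chosenSize %in% ec@sizes)
  expect_length(ec@chosenFeatures, ec@chosenSize)
  # chosen-size error never exceeds the full candidate set's error
  expect_lte(ec@cvMSE[match(ec@chosenSize, ec@sizes)], ec@cvMSE[1L])
  expect_error(backwardEliminate(d$x, d$y, character(0)), "candidate")
})

test_that("backward elimination recovers the planted feature subset", {
  # 5 informative among 20 candidates; the curve's minimum lands at or just
  # above the planted dimension and retains every planted marker
  chosen <- integer(10); recovered <- numeric(10)
  for (s in seq_len(10)) {
    d <- plantedMatrix(p = 20, k = 5, n1 = 60, n0 = 60, effect = 1.0,
                       seed = 100 + s)
    ec <- backwardEliminate(d$x, d$y, rownames(d$x),
                            forestConfig(n_trees = 300, cv_folds = 5,
                                         seed = s))
    chosen[s] <- ec@chosenSize
    recovered[s] <- mean(d$informative %in% ec@chosenFeatures)
  }
  expect_gte(sum(chosen >= 5 & chosen <= 10), 9)
  expect_gte(sum(recovered == 1), 9)
})

test_that("forest tuning honors its grid and tie-break contracts", {
  d <- plantedMatrix(p = 5, k = 2, n1 = 20, n0 = 20, effect = 3, seed = 11)
  # 1x1 grid: returned verbatim
  t1 <- tuneForest(d$x, d$y, rownames(d$x),
                   fastForest(mtry_grid = 2L, nodesize_grid = 3L,
                              tune_boot = 2L))
  expect_identical(t1$mtry, 2L)
  expect_identical(t1$nodesize, 3L)
  # oversized mtry values are skipped with a warning
  expect_warning(
    t2 <- tuneForest(d$x, d$y, rownames(d$x),
                     fastForest(mtry_grid = c(2L, 99L), nodesize_grid = 1L,
                                tune_boot = 2L)),
    "mtry")
  expect_identical(t2$mtry, 2L)
  expect_error(
    suppressWarnings(
      tuneForest(d$x, d$y, rownames(d$x),
                 fastForest(mtry_grid = 99L, nodesize_grid = 1L))),
    "no usable mtry")
})

test_that("degenerate nodesize cells lose to informative ones", {
  d <- plantedMatrix(p = 6, k = 3, n1 = 30, n0 = 30, effect = 3, seed = 23)
  tu <- tuneForest(d$x, d$y, rownames(d$x),
                   fastForest(mtry_grid = 2L, nodesize_grid = c(1L, 60L),
                              tune_boot = 10L))
  # nodesize >= n_train grows stump-less trees; never selected here
  expect_identical(tu$nodesize, 1L)
  acc <- tu$accuracy
  expect_gt(acc$accuracy[acc$nodesize == 1], acc$accuracy[acc$nodesize == 60])
})

test_that("the genomic classifier separates a separable training set", {
  d <- plantedMatrix(p = 10, k = 4, n1 = 25, n0 = 25, effect = 4, seed = 31)
  gc <- trainGC(d$x, d$y, rownames(d$x), mtry = 3, nodesize = 1,
                config = fastForest(n_trees = 200))
  s <- scoreSamples(gc, d$x)
  expect_true(all(s >= 0 & s <= 1))
  expect_true(all(s[d$y] > 0.5))
  expect_true(all(s[!d$y] < 0.5))
  # determinism: identical refit gives identical scores
  gc2 <- trainGC(d$x, d$y, rownames(d$x), mtry = 3, nodesize = 1,
                 config = fastForest(n_trees = 200))
  expect_identical(s, scoreSamples(gc2, d$x))
  # reload stability: serialization round-trip preserves every score
  f <- tempfile(fileext = ".rds")
  saveRDS(gc, f)
  expect_identical(s, scoreSamples(readRDS(f), d$x))
  unlink(f)
  expect_error(trainGC(d$x, rep(TRUE, 50), rownames(d$x), 3, 1), "classes")
})

test_that("forest scores tolerate feature reordering and monotone rescaling", {
  d <- plantedMatrix(p = 12, k = 4, n1 = 30, n0 = 30, effect = 1.5,
                     seed = 37)
  gc <- trainGC(d$x, d$y, rownames(d$x), mtry = 3, nodesize = 1,
                config = fastForest(n_trees = 500))
  s0 <- scoreSamples(gc, d$x)
  # scoring is invariant to the row order of the input matrix
  set.seed(2); perm <- sample(nrow(d$x))
  expect_identical(s0, scoreSamples(gc, d$x[perm, ]))
  # a strictly monotone rescaling of one feature in train+test preserves
  # every within-tree ordering; scores move only through the (data-dependent)
  # midpoint placement of splits, so they stay essentially unchanged
  x2 <- d$x
  x2[1, ] <- exp(x2[1, ])
  gc_r <- trainGC(x2, d$y, rownames(x2), mtry = 3, nodesize = 1,
                  config = fastForest(n_trees = 500))
  s_r <- scoreSamples(gc_r, x2)
  expect_gt(cor(s0, s_r), 0.98)
  expect_lt(max(abs(s0 - s_r)), 0.1)
  expect_identical(classifyRisk(s0), classifyRisk(s_r))
})

test_that("clinical model reproduces closed-form odds ratios and imputes", {
  set.seed(51)
  n <- 120
  ann <- data.frame(
    is_case = rep(c(TRUE, FALSE), each = n / 2), gleason = 7L, ppsa = 10,
    svi = FALSE, sm_pos = FALSE, ece = FALSE, node_pos = FALSE)
  ann$svi <- runif(n) < ifelse(ann$is_case, 0.6, 0.3)
  cc <- trainCC(ann)
  a <- sum(ann$svi & ann$is_case); b <- sum(ann$svi & !ann$is_case)
  c_ <- sum(!ann$svi & ann$is_case); d_ <- sum(!ann$svi & !ann$is_case)
  expect_equal(unname(exp(coef(cc@fit)["svi"])), a * d_ / (b * c_),
               tolerance = 1e-6)
  # intercept-only behavior when no covariate varies
  ann2 <- ann; ann2$svi <- FALSE
  cc2 <- trainCC(ann2)
  expect_true(all(abs(scoreSamples(cc2, ann2) - mean(ann2$is_case)) < 1e-9))
  # missing pPSA: median-imputed with an indicator, scores stay finite
  ann3 <- ann; ann3$ppsa[c(1:4, 61:64)] <- NA  # missing in both classes
  cc3 <- trainCC(ann3)
  expect_true("ppsa_missing" %in% cc3@covariates)
  expect_true(all(is.finite(scoreSamples(cc3, ann3))))
  # when missingness itself separates, the auxiliary indicator is dropped
  ann5 <- ann; ann5$ppsa[1:6] <- NA  # all missing values are cases
  expect_warning(cc5 <- trainCC(ann5), "missingness indicator")
  expect_false("ppsa_missing" %in% cc5@covariates)
  expect_true(all(is.finite(scoreSamples(cc5, ann5))))
  # complete separation fails loudly, naming the covariate
  ann4 <- ann; ann4$svi <- ann4$is_case
  expect_error(trainCC(ann4), "separation.*svi")
})

test_that("the integrated model composes GC and CC scores sensibly", {
  set.seed(61)
  y <- rep(c(TRUE, FALSE), each = 40)
  gc_s <- pmin(pmax(ifelse(y, 0.7, 0.3) + rnorm(80, 0, 0.1), 0), 1)
  # constant CC: GCC is monotone in the GC score alone
  gcc <- trainGCC(gc_s, rep(0.5, 80), y)
  s <- scoreSamples(gcc, data.frame(gc = sort(gc_s), cc = 0.5))
  expect_true(all(diff(s) >= 0))
  # identical score vectors: collinearity collapses to one predictor
  expect_warning(gcc2 <- trainGCC(gc_s, gc_s, y), "collinear")
  expect_true(all(is.finite(
    scoreSamples(gcc2, data.frame(gc = gc_s, cc = gc_s)))))
})

test_that("risk dichotomization is strict at one half", {
  expect_identical(as.character(classifyRisk(c(0, 0.5, 0.51, 1))),
                   c("low", "low", "high", "high"))
  expect_error(classifyRisk(1.2), "\\[0, 1\\]")
  expect_error(classifyRisk(-0.1), "\\[0, 1\\]")
})
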