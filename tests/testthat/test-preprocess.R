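toy_annot <- function(probe_count, crosshyb) {
  ids <- sprintf("f%02d", seq_along(probe_count))
  data.frame(feature_id = ids, probe_count = probe_count,
             crosshyb = crosshyb, row.names = ids)
}
toy_matrix <- function(ids, n = 4) {
  matrix(seq_len(length(ids) * n), length(ids), n,
         dimnames = list(ids, sprintf("s%02d", seq_len(n))))
}

test_that("annotation filter keeps >=4-probe non-cross-hybridizing features", {
  ann <- toy_annot(probe_count = c(3, 3, 3, rep(4L, 7)),
                   crosshyb = c(rep(FALSE, 3), TRUE, TRUE, rep(FALSE, 5)))
  x <- toy_matrix(ann$feature_id)
  kept <- filterByAnnotation(x, ann)
  expect_identical(rownames(kept), sprintf("f%02d", 6:10))  # 5 of 10 survive
  # identity when everything is reliable
  ann_ok <- toy_annot(rep(4L, 10), rep(FALSE, 10))
  expect_identical(filterByAnnotation(x, ann_ok), x)
  # idempotent
  expect_identical(filterByAnnotation(kept, ann), kept)
  # unknown feature is an error naming the offender
  expect_error(filterByAnnotation(x, ann[-1L, ]), "f01")
})

test_that("technical-variance filter removes the top decile, ties included", {
  ids <- sprintf("f%02d", 1:10)
  # two replicates (m, m + sqrt(2 v)) have sample variance exactly v
  v <- c(1:8, 9, 9)
  tech <- cbind(rep(0, 10), sqrt(2 * v))
  rownames(tech) <- ids
  x <- toy_matrix(ids)
  kept <- filterByTechnicalVariance(x, tech, top_frac = 0.10)
  # both features tied at the cutoff variance 9 are removed
  expect_identical(rownames(kept), ids[1:8])
  # distinct variances: exactly the single top feature goes
  v2 <- 1:10
  tech2 <- cbind(rep(0, 10), sqrt(2 * v2)); rownames(tech2) <- ids
  expect_identical(rownames(filterByTechnicalVariance(x, tech2, 0.10)),
                   ids[1:9])
  # top_frac = 0 is the identity
  expect_identical(filterByTechnicalVariance(x, tech, 0), x)
  # mismatched feature sets error
  expect_error(filterByTechnicalVariance(x, tech[-1L, ]), "feature set")
  expect_error(filterByTechnicalVariance(x, tech[, 1, drop = FALSE]),
               "2 technical replicates")
})

test_that("batch-component removal has the stated algebraic properties", {
  set.seed(5)
  p <- 80; n <- 40
  batch <- rep(1:4, each = 10)
  x <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("f%02d", 1:p), sprintf("s%02d", 1:n)))
  off <- matrix(rnorm(p * 4, sd = 2), p, 4)
  x <- x + off[, batch]
  bc <- removeBatchComponents(x, batch, n_examine = 10, n_remove = 2)
  expect_identical(dim(bc@corrected), dim(x))
  expect_length(bc@removedPCs, 2L)
  expect_true(all(bc@removedPCs %in% 1:10))
  # total variance drops by exactly the removed components' variance
  xc <- x - rowMeans(x)
  cc <- bc@corrected - rowMeans(bc@corrected)
  removed_ss <- sum((xc %*% bc@removedDirections)^2)
  expect_equal(sum(xc^2) - sum(cc^2), removed_ss,
               tolerance = 1e-8)
  # corrected data projects to ~0 on the removed directions
  expect_lt(max(abs(cc %*% bc@removedDirections)), 1e-8)
  # errors
  expect_error(removeBatchComponents(x, rep(1L, n)), "single batch")
  expect_error(removeBatchComponents(x, batch, n_examine = 2, n_remove = 3),
               "n_remove")
})

test_that("strong batch structure is identified and reduced", {
  # simulation: the removed components carry more batch R2 than any
  # retained examined component, and correction lowers the max batch R2
  ok_rank <- ok_drop <- logical(20)
  for (s in seq_len(20)) {
    set.seed(300 + s)
    p <- 100; n <- 60
    batch <- sample(rep(1:5, each = 12))
    x <- matrix(rnorm(p * n), p, n,
                dimnames = list(sprintf("f%03d", 1:p),
                                sprintf("s%02d", 1:n)))
    off <- matrix(rnorm(p * 5, sd = 3), p, 5)
    x <- x + off[, batch]
    pre <- maxBatchR2(x, batch)
    bc <- removeBatchComponents(x, batch)
    post <- maxBatchR2(bc@corrected, batch)
    ok_rank[s] <- min(bc@batchR2[bc@removedPCs]) >
      max(bc@batchR2[-bc@removedPCs])
    ok_drop[s] <- post < pre
  }
  expect_true(all(ok_rank))
  expect_true(all(ok_drop))
})

test_that("without batch effects no component associates with batch", {
  set.seed(17)
  p <- 100; n <- 60
  batch <- sample(rep(1:5, each = 12))
  x <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("f%03d", 1:p), sprintf("s%02d", 1:n)))
  bc <- removeBatchComponents(x, batch)
  expect_lt(max(bc@batchR2), 0.35)
  # corrected matrix stays close to the input (only 2 near-noise PCs gone)
  expect_gt(cor(as.vector(x), as.vector(bc@corrected)), 0.95)
})

test_that("case-control signal survives correction when batch is independent", {
  atten <- numeric(5)
  for (s in seq_len(5)) {
    cfg <- smallSimConfig(seed = 700 + s, batch_sd = 2, effect_size = 1)
    coh <- simulateCohort(cfg)
    y <- isCase(coh)
    inf <- featureInfo(coh)$is_informative
    x0 <- exprValues(coh)
    d0 <- mean(abs(rowMeans(x0[inf, y]) - rowMeans(x0[inf, !y])))
    x1 <- exprValues(applyBatchCorrection(coh))
    d1 <- mean(abs(rowMeans(x1[inf, y]) - rowMeans(x1[inf, !y])))
    atten[s] <- 1 - d1 / d0
  }
  expect_true(all(atten < 0.20))
})
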