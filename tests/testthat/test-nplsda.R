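# NPLS-DA: oracle equivalence on single-timepoint data, invariants,
# null behaviour, prediction, cross-validation.

test_that("single-timepoint NPLS matches the two-way PLS oracle", {
  set.seed(1)
  n <- 30; J <- 12
  Xm <- matrix(rnorm(n * J), n)
  y <- rep(c("a", "b"), each = n / 2)
  X3 <- array(Xm, c(n, J, 1),
              dimnames = list(paste0("s", 1:n), paste0("f", 1:J), "1"))
  m <- fitNPLSDA(X3, y, H = 2)
  o <- oraclePLS2(Xm, y, H = 2)
  expect_lt(max(abs(abs(m@featureWeights) - abs(o$weights))), 1e-8)
  expect_lt(max(abs(abs(m@scores) - abs(o$scores))), 1e-8)
})

test_that("the first component agrees with an external PLS implementation", {
  set.seed(2)
  n <- 24; J <- 10
  Xm <- matrix(rnorm(n * J), n)
  y <- rep(c("a", "b"), each = n / 2)
  Y <- stats::model.matrix(~ 0 + factor(y))
  ext <- mixOmics::pls(Xm, Y, ncomp = 1, scale = FALSE, mode = "regression")
  w <- ext$loadings$X[, 1L]
  m <- fitNPLSDA(array(Xm, c(n, J, 1)), y, H = 1)
  expect_lt(max(abs(abs(m@featureWeights[, 1L]) - abs(w))), 1e-8)
})

test_that("mode-1 scores equal the contraction with the weight pair", {
  set.seed(3)
  X <- array(rnorm(20 * 8 * 5), c(20, 8, 5))
  y <- rep(c("case", "control"), 10)
  m <- fitNPLSDA(X, y, H = 3)
  Xc <- sweep(X, c(2, 3), m@xMean)
  for (h in 1:3) {
    tc <- tritime:::contractModes23(Xc, m@featureWeights[, h],
                                    m@timeWeights[, h])
    expect_lt(max(abs(tc - m@scores[, h])), 1e-10)
  }
  # unit-norm weights and sign convention
  expect_equal(colSums(m@featureWeights^2), rep(1, 3), tolerance = 1e-10)
  expect_equal(colSums(m@timeWeights^2), rep(1, 3), tolerance = 1e-10)
  for (h in 1:3)
    expect_gt(m@featureWeights[which.max(abs(m@featureWeights[, h])), h], 0)
})

test_that("training R2Y never decreases with more components", {
  set.seed(4)
  X <- array(rnorm(20 * 10 * 4), c(20, 10, 4))
  y <- rep(c("a", "b"), 10)
  r2 <- vapply(1:4, function(h) fitNPLSDA(X, y, H = h)@R2Y, numeric(1))
  expect_true(all(diff(r2) >= -1e-10))
})

test_that("pure-noise labels give weak fits and no predictive power", {
  r2s <- numeric(10); q2s <- numeric(10)
  for (s in 1:10) {
    set.seed(400 + s)
    X <- array(rnorm(100 * 8 * 3), c(100, 8, 3))
    y <- rep(c("a", "b"), 50)
    r2s[s] <- fitNPLSDA(X, y, H = 2)@R2Y
    q2s[s] <- crossValidate(X, y, H = 2, scheme = "kfold5", seed = s)$q2
  }
  expect_lt(mean(r2s), 0.3)
  expect_lt(mean(q2s), 0.1)
})

test_that("a strong planted signal is classified perfectly in training", {
  prep <- preparedTensor(smallCohortConfig(seed = 5, nPairs = 15L,
                                           nFeatures = 60L, effectSize = 2))
  m <- fitNPLSDA(prep$tensor, prep$labels, H = 2)
  p <- predictNPLSDA(m, prep$tensor)
  expect_equal(mean(p$class == prep$labels), 1.0)
})

test_that("held-out subjects with a strong signal are classified well", {
  cfg <- smallCohortConfig(seed = 6, nPairs = 24L, nFeatures = 60L,
                           effectSize = 2, missingRate = 0)
  prep <- preparedTensor(cfg)
  n <- length(prep$labels)
  test <- seq(1, n, by = 3)
  train <- setdiff(seq_len(n), test)
  m <- fitNPLSDA(prep$tensor@values[train, , , drop = FALSE],
                 prep$labels[train], H = 2)
  p <- predictNPLSDA(m, prep$tensor@values[test, , , drop = FALSE])
  expect_gte(mean(p$class == prep$labels[test]), 0.9)
})

test_that("prediction is deterministic and degenerate slices get the first class", {
  set.seed(7)
  X <- array(rnorm(10 * 6 * 3), c(10, 6, 3))
  y <- rep(c("a", "b"), 5)
  m <- fitNPLSDA(X, y, H = 2)
  z <- array(0, c(1, 6, 3))
  p1 <- predictNPLSDA(m, z)
  p2 <- predictNPLSDA(m, z)
  expect_identical(p1$class, p2$class)
  expect_true(p1$class %in% c("a", "b"))
})

test_that("mode mismatches raise errors naming the mode", {
  set.seed(8)
  X <- array(rnorm(10 * 6 * 3), c(10, 6, 3))
  y <- rep(c("a", "b"), 5)
  m <- fitNPLSDA(X, y, H = 1)
  expect_error(predictNPLSDA(m, array(0, c(2, 5, 3))), "feature mode")
  expect_error(predictNPLSDA(m, array(0, c(2, 6, 4))), "timepoint mode")
  expect_error(fitNPLSDA(X, rep("a", 10), H = 1), "single class")
  expect_error(fitNPLSDA(X, y, H = 10), "smaller than the number of subjects")
})

test_that("leave-one-out performs exactly n fits, one per subject", {
  set.seed(9)
  X <- array(rnorm(12 * 8 * 3), c(12, 8, 3))
  y <- rep(c("a", "b"), 6)
  cv <- crossValidate(X, y, H = 1, scheme = "loo")
  expect_identical(nrow(cv$predictions), 12L)
  expect_setequal(cv$predictions$subject, 1:12)
  expect_true(all(table(cv$predictions$subject) == 1L))
})

test_that("label permutation destroys Q2", {
  prep <- preparedTensor(smallCohortConfig(seed = 10, nPairs = 12L,
                                           nFeatures = 40L, effectSize = 2))
  q2s <- vapply(1:10, function(s) {
    set.seed(500 + s)
    crossValidate(prep$tensor@values, sample(prep$labels), H = 2,
                  scheme = "kfold5", seed = s)$q2
  }, numeric(1))
  expect_lt(mean(q2s), 0.05)
})

test_that("CV schemes agree on a strong-signal cohort", {
  prep <- preparedTensor(smallCohortConfig(seed = 11, nPairs = 20L,
                                           nFeatures = 50L, effectSize = 2))
  X <- prep$tensor@values; y <- prep$labels
  loo <- crossValidate(X, y, H = 2, scheme = "loo")$q2
  k5 <- crossValidate(X, y, H = 2, scheme = "kfold5", nRepeats = 3,
                      seed = 1)$q2
  k10 <- crossValidate(X, y, H = 2, scheme = "kfold10", nRepeats = 3,
                       seed = 1)$q2
  expect_lt(abs(k5 - k10), 0.1)
  expect_lt(abs(k5 - loo), 0.1)
  expect_lt(abs(k10 - loo), 0.1)
  # Q2 <= R2 on training data, with small tolerance for estimation noise
  r2 <- fitNPLSDA(X, y, H = 2)@R2Y
  for (q in c(loo, k5, k10)) expect_lt(q, r2 + 0.02)
})

test_that("block concatenation balances blocks to unit total SS", {
  prep1 <- preparedTensor(smallCohortConfig(seed = 12, nPairs = 6L,
                                            nFeatures = 30L))
  prep2 <- preparedTensor(smallCohortConfig(seed = 12, nPairs = 6L,
                                            nFeatures = 10L,
                                            block = "metabolomics"))
  joint <- joinBlocks(list(gene_expression = prep1$tensor,
                           metabolomics = prep2$tensor))
  v <- tensorValues(joint)
  geneCols <- grep("^gene_expression:", featureIds(joint))
  metCols <- grep("^metabolomics:", featureIds(joint))
  expect_equal(sum(v[, geneCols, ]^2), 1, tolerance = 1e-8)
  expect_equal(sum(v[, metCols, ]^2), 1, tolerance = 1e-8)
})
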