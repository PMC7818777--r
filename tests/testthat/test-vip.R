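# VIP computation, percentile thresholding, union/intersection search.

test_that("two-way VIP satisfies the normalization identity sum VIP^2 = p", {
  set.seed(1)
  n <- 30; J <- 15
  Xm <- matrix(rnorm(n * J), n)
  y <- rep(c("a", "b"), each = n / 2)
  X3 <- array(Xm, c(n, J, 1),
              dimnames = list(paste0("s", 1:n), paste0("f", 1:J), "1"))
  for (H in 1:2) {
    sel <- computeVIP(tensor = X3, labels = y, strategy = "vip2d", H = H)
    expect_equal(sum(sel@vipValues^2), J, tolerance = 1e-8)
    # against the independent oracle VIP
    o <- oracleVIP(oraclePLS2(Xm, y, H = H))
    expect_equal(unname(sel@vipValues), o, tolerance = 1e-8)
  }
})

test_that("exchangeable variables all get VIP 1", {
  set.seed(2)
  n <- 20; J <- 6
  base <- rnorm(n)                             # same signal in every feature
  X1 <- array(rep(base, J), c(n, J, 1))        # single timepoint
  y <- rep(c("a", "b"), n / 2)
  sel <- computeVIP(tensor = X1, labels = y, strategy = "vip2d", H = 1)
  expect_equal(unname(sel@vipValues), rep(1, J), tolerance = 1e-8)
  # with several timepoints, exchangeability across features still forces
  # identical scores within each timepoint and strategy
  K <- 3
  baseK <- matrix(rnorm(n * K), n)
  X <- array(0, c(n, J, K))
  for (j in 1:J) X[, j, ] <- baseK
  sel2 <- computeVIP(tensor = X, labels = y, strategy = "vip2d", H = 1)
  byTp <- split(sel2@detail$vip, sel2@detail$timepoint)
  for (v in byTp) expect_lt(max(v) - min(v), 1e-8)
  m <- fitNPLSDA(X, y, H = 1)
  s1 <- computeVIP(model = m, strategy = "vip3d_model1")
  expect_equal(max(s1@vipValues) - min(s1@vipValues), 0, tolerance = 1e-8)
})

test_that("planted features dominate the top VIP ranks", {
  hits <- vapply(1:5, function(s) {
    prep <- preparedTensor(smallCohortConfig(seed = 40 + s, nPairs = 20L,
                                             nFeatures = 100L,
                                             nInformative = 5L,
                                             effectSize = 2))
    sel <- computeVIP(tensor = prep$tensor@values, labels = prep$labels,
                      strategy = "vip2d", H = 2)
    planted <- prep$truth$informative$gene_expression
    top <- names(sort(sel@vipValues, decreasing = TRUE))[seq_along(planted)]
    mean(planted %in% top)
  }, numeric(1))
  expect_gte(mean(hits), 0.8)
})

test_that("percentile selection follows the strict-inequality order statistics", {
  v <- stats::setNames(seq_len(100) / 100, paste0("f", 1:100))
  sel <- selectByPercentile(v, 95)
  expect_length(sel, 5L)
  expect_setequal(sel, paste0("f", 96:100))
  # all equal -> nothing strictly larger
  ve <- stats::setNames(rep(1, 10), paste0("f", 1:10))
  expect_length(selectByPercentile(ve, 95), 0L)
  # monotone in threshold
  s90 <- selectByPercentile(v, 90)
  expect_true(all(sel %in% s90))
  expect_error(selectByPercentile(v, 0), "strictly between")
  expect_error(selectByPercentile(numeric(0), 95), "empty")
})

test_that("the candidate search enumerates unions and intersections", {
  prep <- preparedTensor(smallCohortConfig(seed = 3, nPairs = 15L,
                                           nFeatures = 80L, nInformative = 4L,
                                           effectSize = 2))
  labs <- prep$labels
  m <- fitNPLSDA(prep$tensor, labs, H = 2)
  sels <- list(
    computeVIP(tensor = prep$tensor@values, labels = labs, strategy = "vip2d"),
    computeVIP(model = m, strategy = "vip3d_model1"),
    computeVIP(model = m, strategy = "vip3d_model2"))
  sels <- lapply(sels, selectByPercentile, percentile = 90)
  best <- searchBestSet(sels, prep$tensor, labs, seed = 1)
  log <- attr(best, "candidates")
  expect_gte(nrow(log), 3L)          # 3 base sets at minimum
  expect_true(all(c("provenance", "size", "r2", "q2") %in% names(log)))
  # winner has the maximum Q2 among candidates
  expect_equal(best@q2, max(log$q2))
  expect_true(best@provenance %in% log$provenance)
})

test_that("identical per-strategy selections win trivially", {
  prep <- preparedTensor(smallCohortConfig(seed = 4, nPairs = 10L,
                                           nFeatures = 30L, nInformative = 3L,
                                           effectSize = 2))
  ids <- prep$truth$informative$gene_expression
  mk <- function(strategy) {
    v <- stats::setNames(rep(0, 30), featureIds(prep$tensor))
    v[ids] <- 1
    new("VIPSelection", strategy = strategy, vipValues = v,
        detail = data.frame(), percentile = 90, selectedIds = ids,
        provenance = strategy, r2 = NA_real_, q2 = NA_real_)
  }
  best <- searchBestSet(list(mk("vip2d"), mk("vip3d_model1"),
                             mk("vip3d_model2")),
                        prep$tensor, prep$labels, seed = 1)
  expect_setequal(best@selectedIds, ids)
  expect_identical(nrow(attr(best, "candidates")), 1L)  # all sets identical
})

test_that("the winning set beats size-matched random selections", {
  wins <- vapply(1:5, function(s) {
    prep <- preparedTensor(smallCohortConfig(seed = 60 + s, nPairs = 15L,
                                             nFeatures = 60L,
                                             nInformative = 3L,
                                             effectSize = 2))
    labs <- prep$labels
    sel <- computeVIP(tensor = prep$tensor@values, labels = labs,
                      strategy = "vip2d")
    sel <- selectByPercentile(sel, 90)
    best <- searchBestSet(list(sel), prep$tensor, labs, seed = s)
    set.seed(1000 + s)
    rnd <- sample(featureIds(prep$tensor), length(best@selectedIds))
    idx <- match(rnd, featureIds(prep$tensor))
    q2rnd <- crossValidate(prep$tensor@values[, idx, , drop = FALSE], labs,
                           H = min(2L, length(idx)), scheme = "kfold5",
                           seed = s)$q2
    best@q2 - q2rnd
  }, numeric(1))
  expect_gt(mean(wins), 0)
})

test_that("empty candidate lists are rejected", {
  emptySel <- new("VIPSelection", strategy = "vip2d",
                  vipValues = c(f1 = 1, f2 = 1), detail = data.frame(),
                  percentile = 99, selectedIds = character(0),
                  provenance = "vip2d", r2 = NA_real_, q2 = NA_real_)
  expect_error(searchBestSet(list(emptySel), array(0, c(4, 2, 2)),
                             c("a", "b", "a", "b")), "empty")
})
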