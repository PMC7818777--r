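# GSEA by VIP ranking, Fisher's-method combination, signed scores, and
# metabolite-class enrichment.

test_that("a set occupying the top ranks hits the permutation floor", {
  v <- matrix(seq(2, 0.01, length.out = 100), 100, 1,
              dimnames = list(paste0("g", 1:100), "12"))
  g <- gseaByVIP(v, list(top = paste0("g", 1:8)), nPerm = 500, seed = 1)
  expect_equal(g$p, 1 / 501)
  expect_identical(g$n_members, 8L)
})

test_that("the whole-universe set is never enriched", {
  set.seed(2)
  v <- matrix(rnorm(50, 1, .2), 50, 1,
              dimnames = list(paste0("g", 1:50), "9"))
  g <- gseaByVIP(v, list(all = paste0("g", 1:50)), nPerm = 200, seed = 1)
  expect_gte(g$p, 0.99)   # statistic equals its null exactly
})

test_that("no-overlap sets yield NA with a warning", {
  v <- matrix(1:10, 10, 1, dimnames = list(paste0("g", 1:10), "6"))
  expect_warning(g <- gseaByVIP(v, list(none = c("x1", "x2")), nPerm = 100,
                                seed = 1), "no overlap")
  expect_true(is.na(g$p))
  expect_error(gseaByVIP(v, list(a = "g1"), nPerm = 10), "at least 100")
})

test_that("null GSEA p-values are approximately uniform", {
  set.seed(3)
  v <- matrix(rnorm(200), 200, 1, dimnames = list(paste0("g", 1:200), "3"))
  sets <- lapply(1:300, function(i) paste0("g", sample(200, 10)))
  names(sets) <- paste0("s", 1:300)
  g <- gseaByVIP(v, sets, nPerm = 200, seed = 7)
  frac <- mean(g$p <= 0.05)
  expect_lt(abs(frac - 0.05), 0.03)
})

test_that("Fisher combination matches the chi-square closed form", {
  e <- data.frame(set = "s", timepoint = c("12", "9"), p = c(0.5, 0.5))
  fc <- fisherCombine(e)
  both <- fc$combinations[fc$combinations$combination == "12+9", ]
  expect_equal(both$fisher_p, stats::pchisq(-2 * 2 * log(0.5), df = 4,
                                            lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(both$fisher_p, 0.5965736, tolerance = 1e-6)
  expect_identical(both$df, 4L)
  # k = 1 identity
  single <- fc$combinations[fc$combinations$combination == "12", ]
  expect_equal(single$fisher_p, 0.5)
})

test_that("degenerate p-values are handled and BH never shrinks below raw", {
  e <- data.frame(set = rep(paste0("s", 1:5), each = 2),
                  timepoint = rep(c("12", "9"), 5),
                  p = c(1, 1, 0.01, 0.2, 0.5, 0.5, 0.9, 0.8, 0.05, 0.3))
  fc <- fisherCombine(e)
  allOne <- fc$combinations[fc$combinations$set == "s1", ]
  expect_true(all(allOne$fisher_p == 1))
  ok <- !is.na(fc$combinations$adj_p)
  expect_true(all(fc$combinations$adj_p[ok] >= fc$combinations$fisher_p[ok] - 1e-12))
  expect_warning(fisherCombine(data.frame(set = "s", timepoint = "12", p = 0)),
                 "clipped")
  expect_error(fisherCombine(data.frame(set = "s", timepoint = "12", p = 1.5)),
               "lie in")
})

test_that("combined p is monotone in each input p", {
  base <- data.frame(set = "s", timepoint = c("12", "9"), p = c(0.3, 0.4))
  worse <- data.frame(set = "s", timepoint = c("12", "9"), p = c(0.3, 0.6))
  f1 <- fisherCombine(base)$combinations
  f2 <- fisherCombine(worse)$combinations
  expect_lt(f1$fisher_p[f1$combination == "12+9"],
            f2$fisher_p[f2$combination == "12+9"])
})

test_that("signed scores follow (1 - p) times the sign of the mean", {
  expect_equal(signedScore(0.05, c(1, 2)), 0.95)
  expect_equal(signedScore(0.05, c(-1)), -0.95)
  expect_equal(signedScore(1, 5), 0)
  expect_equal(signedScore(0.3, numeric(0)), 0)
  expect_equal(abs(signedScore(0.17, -4)), 1 - 0.17)
  expect_error(signedScore(0, 1), "lie in")
})

test_that("metabolite class enrichment matches the hypergeometric oracle", {
  # 2x2 table: in-class significant = 8, in-class not = 2,
  # out significant = 12, out not = 78
  set.seed(4)
  nPairs <- 20
  nFeat <- 100
  v <- array(rnorm(2 * nPairs * nFeat, sd = 0.05), c(2 * nPairs, nFeat, 1))
  sigIdx <- c(1:8, 11:22)              # 20 significant metabolites
  for (j in sigIdx) v[seq(1, 2 * nPairs, 2), j, ] <-
      v[seq(1, 2 * nPairs, 2), j, ] + 3   # strong case shift
  tens <- makeTensor(array(rep(v, 5), c(2 * nPairs, nFeat, 5)),
                     block = "metabolomics")
  cm <- data.frame(metabolite_id = featureIds(tens),
                   class = c(rep("classA", 10), rep("other", 90)))
  # alpha far below the noise floor keeps the table counts deterministic
  res <- suppressWarnings(metaboliteClassEnrichment(tens, cm, alpha = 1e-6,
                                                    fdr = 0.2))
  row <- res[res$class == "classA" & res$timepoint == 12, ]
  expect_identical(row$n_significant, 8L)
  expect_equal(row$odds_ratio, (8 * 78) / (2 * 12))
  # exact one-sided hypergeometric tail
  expect_equal(row$fisher_p, stats::phyper(7, 20, 80, 10, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_true(row$enriched)
  expect_identical(row$direction, "up")
})

test_that("no significant metabolites means no enriched classes", {
  set.seed(5)
  v <- array(rnorm(20 * 30 * 5, sd = 1), c(20, 30, 5))
  tens <- makeTensor(v, block = "metabolomics")
  cm <- data.frame(metabolite_id = featureIds(tens),
                   class = rep(c("a", "b", "c"), each = 10))
  res <- suppressWarnings(metaboliteClassEnrichment(tens, cm, alpha = 1e-6))
  expect_true(all(res$n_significant == 0L))
  expect_false(any(res$enriched, na.rm = TRUE))
})

test_that("degenerate class maps are rejected or skipped", {
  set.seed(6)
  v <- array(rnorm(8 * 10 * 5), c(8, 10, 5))
  tens <- makeTensor(v, block = "metabolomics")
  dup <- data.frame(metabolite_id = c(featureIds(tens), featureIds(tens)[1]),
                    class = "a")
  expect_error(metaboliteClassEnrichment(tens, dup), "at most one class")
  oneClass <- data.frame(metabolite_id = featureIds(tens), class = "a")
  expect_warning(res <- metaboliteClassEnrichment(tens, oneClass),
                 "whole universe")
  expect_identical(nrow(res), 0L)
})

test_that("GMT files round-trip", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g4", "g5"))
  d <- withr::local_tempdir()
  p <- file.path(d, "sets.gmt")
  writeGMT(sets, p)
  expect_identical(readGMT(p), sets)
  expect_error(readGMT(file.path(d, "missing.gmt")), "missing GMT")
})
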