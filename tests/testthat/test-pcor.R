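# Delta profiles, elastic-net stability selection, partial correlations,
# network construction, and window comparison.

test_that("delta profiles difference consecutive timepoints, later minus earlier", {
  v <- array(0, c(2, 1, 5))
  v[1, 1, ] <- c(2, 5, 1, 1, 1)   # 2.0 at 12 MBSC, 5.0 at 9 MBSC
  tens <- makeTensor(v, tp = c(12, 9, 6, 3, 0))
  d <- deltaProfiles(tens, subjects = "all")
  expect_length(d, 4L)
  expect_named(d, c("12to9", "9to6", "6to3", "3to0"))
  expect_equal(unname(d[["12to9"]]$delta[1, 1]), 3.0)
  # constant profile -> all zero
  expect_true(all(vapply(d, function(w) w$delta[2, 1], numeric(1)) == 0))
  expect_error(deltaProfiles(makeTensor(array(0, c(2, 1, 3)))), "5-timepoint")
})

test_that("case-only profiles keep only case subjects", {
  set.seed(1)
  v <- array(rnorm(6 * 4 * 5), c(6, 4, 5))
  tens <- makeTensor(v)
  d <- deltaProfiles(tens, subjects = "cases")
  expect_identical(rownames(d[["12to9"]]$delta),
                   subjectIds(tens)[tensorDesign(tens)$role == "case"])
})

test_that("the precision route matches the 3-variable recursive formula", {
  set.seed(2)
  n <- 200
  Z <- matrix(rnorm(n * 3), n)
  X <- cbind(Z[, 1], 0.6 * Z[, 1] + Z[, 2], 0.3 * Z[, 2] + Z[, 3])
  R <- partialCorrelations(X, shrink = FALSE)
  cc <- stats::cor(X)
  expect_equal(R[1, 2], pcorRecursive3(cc, 1, 2, 3), tolerance = 1e-10)
  expect_equal(R[1, 3], pcorRecursive3(cc, 1, 3, 2), tolerance = 1e-10)
  expect_equal(R[2, 3], pcorRecursive3(cc, 2, 3, 1), tolerance = 1e-10)
})

test_that("the precision route matches double regression on random instances", {
  set.seed(3)
  for (rep in 1:20) {
    p <- sample(3:6, 1)
    n <- 60
    X <- matrix(rnorm(n * p), n) %*%
      matrix(rnorm(p * p, sd = 0.4) + diag(p), p)
    R <- partialCorrelations(X, shrink = FALSE)
    i <- 1; j <- 2
    expect_equal(R[i, j], pcorRegression(X, i, j), tolerance = 1e-8)
  }
})

test_that("partial correlations are symmetric with unit diagonal", {
  set.seed(4)
  X <- matrix(rnorm(50 * 6), 50)
  R <- partialCorrelations(X)
  expect_lt(max(abs(R - t(R))), 1e-12)
  expect_equal(unname(diag(R)), rep(1, 6), tolerance = 1e-12)
})

test_that("independent features give near-zero partial correlations", {
  set.seed(5)
  R <- partialCorrelations(matrix(rnorm(500 * 5), 500), shrink = FALSE)
  diag(R) <- 0
  expect_lt(max(abs(R)), 0.2)
})

test_that("zero cross-block covariance is recovered as near-zero pcor", {
  set.seed(6)
  n <- 1000
  A <- matrix(rnorm(n * 3), n) %*% matrix(c(1, .5, .2, .5, 1, .3, .2, .3, 1), 3)
  B <- matrix(rnorm(n * 3), n) %*% matrix(c(1, .4, .1, .4, 1, .2, .1, .2, 1), 3)
  R <- partialCorrelations(cbind(A, B), shrink = FALSE)
  # cross-block entries sit at sampling-noise scale, far below the
  # within-block partial correlations
  expect_lt(mean(abs(R[1:3, 4:6])), 0.05)
  expect_lt(max(abs(R[1:3, 4:6])), 0.15)
  expect_gt(max(abs(R[1:3, 1:3][upper.tri(diag(3))])), 0.2)
})

test_that("perfect collinearity raises an error naming the pair", {
  set.seed(7)
  x <- rnorm(30)
  X <- cbind(a = x, b = 2 * x, c = rnorm(30))
  err <- tryCatch(partialCorrelations(X), error = identity)
  expect_match(conditionMessage(err), "perfectly collinear")
  expect_match(conditionMessage(err), "a")
  expect_match(conditionMessage(err), "b")
  expect_error(partialCorrelations(matrix(rnorm(20), 10, 2)), "at least 3")
})

test_that("network construction follows the |pcor| > threshold rule", {
  R <- diag(4)
  dimnames(R) <- list(letters[1:4], letters[1:4])
  R["a", "b"] <- R["b", "a"] <- 0.71
  R["c", "d"] <- R["d", "c"] <- -0.8
  R["a", "c"] <- R["c", "a"] <- 0.65
  net <- buildNetwork(R, threshold = 0.7, window = "12to9")
  expect_identical(nrow(net@edges), 2L)
  ab <- net@edges[net@edges$from == "a", ]
  expect_equal(ab$pcor, 0.71)
  expect_identical(ab$sign, "positive")
  cd <- net@edges[net@edges$from == "c", ]
  expect_identical(cd$sign, "negative")
  # all below threshold -> empty network is valid
  net0 <- buildNetwork(diag(3), threshold = 0.7)
  expect_identical(nrow(net0@edges), 0L)
  expect_true(all(net0@nodes$isolated))
})

test_that("raising the threshold never adds edges", {
  set.seed(8)
  X <- matrix(rnorm(40 * 6), 40) %*% matrix(rnorm(36, sd = .5) + diag(6), 6)
  R <- partialCorrelations(X, shrink = FALSE)
  lo <- buildNetwork(R, threshold = 0.3)
  hi <- buildNetwork(R, threshold = 0.5)
  key <- function(n) paste(n@edges$from, n@edges$to)
  expect_true(all(key(hi) %in% key(lo)))
})

test_that("node direction annotation reflects mean case values", {
  R <- diag(3); dimnames(R) <- list(c("x", "y", "z"), c("x", "y", "z"))
  meta <- data.frame(feature_id = c("x", "y", "z"), kind = "gene",
                     mean_case = c(0.5, -0.2, 0))
  net <- buildNetwork(R, meta, threshold = 0.7)
  expect_identical(net@nodes$direction, c("up", "down", "up"))
  expect_identical(net@nodes$kind, rep("gene", 3))
})

test_that("elastic-net selection is deterministic and recovers planted drivers", {
  set.seed(9)
  n <- 60; p <- 25
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("f", 1:p)))
  beta <- c(rep(2, 4), rep(0, p - 4))
  y <- as.integer(stats::runif(n) < stats::plogis(X %*% beta))
  labels <- c("control", "case")[y + 1L]
  win <- list(delta = X, labels = labels, label = "12to9", from = 12, to = 9)
  a <- elasticNetSelect(win, nTune = 10L, nFinal = 40L, seed = 5)
  b <- elasticNetSelect(win, nTune = 10L, nFinal = 40L, seed = 5)
  expect_identical(a$selected, b$selected)
  expect_gte(mean(paste0("f", 1:4) %in% a$selected), 0.8)
  expect_true(a$alpha %in% seq(0, 1, by = 0.1))
})

test_that("all-constant features are dropped with a warning", {
  set.seed(10)
  X <- cbind(matrix(rnorm(40 * 3), 40), 1)
  colnames(X) <- paste0("f", 1:4)
  win <- list(delta = X, labels = rep(c("case", "control"), 20),
              label = "9to6", from = 9, to = 6)
  expect_warning(r <- elasticNetSelect(win, nTune = 5L, nFinal = 10L, seed = 1),
                 "all-constant")
  expect_false("f4" %in% r$selected)
})

test_that("kurtosis and KS comparisons behave on known distributions", {
  set.seed(11)
  z <- rnorm(1e5)
  cmp <- compareWindows(list(a = z, b = z))
  expect_lt(abs(cmp$kurtosis$excess_kurtosis[1]), 0.2)
  expect_equal(cmp$ks$ks_stat, 0)
  expect_equal(cmp$ks$ks_p, 1)
  # uniform vs tight normal separate decisively
  u <- stats::runif(500, -1, 1); g <- rnorm(500, 0, 0.3)
  cmp2 <- compareWindows(list(w1 = u, w2 = g))
  expect_lt(cmp2$ks$ks_p, 1e-6)
  # platykurtic/leptokurtic labels follow the sign of excess kurtosis
  expect_identical(cmp2$kurtosis$shape[1], "platykurtic")   # uniform: -1.2
  lep <- stats::rt(5000, df = 5)
  cmp3 <- compareWindows(list(a = lep, b = rnorm(5000)))
  expect_identical(cmp3$kurtosis$shape[1], "leptokurtic")
  expect_error(compareWindows(list(a = rnorm(30))), "at least 2 windows")
  expect_error(compareWindows(list(a = rnorm(5), b = rnorm(5))), "at least 20")
})

test_that("networks export to GraphML, SIF, and a node table", {
  R <- diag(3); dimnames(R) <- list(c("x", "y", "z"), c("x", "y", "z"))
  R["x", "y"] <- R["y", "x"] <- 0.9
  net <- buildNetwork(R, threshold = 0.7, window = "6to3")
  d <- withr::local_tempdir()
  paths <- exportNetwork(net, d)
  expect_true(all(file.exists(paths)))
  g <- igraph::read_graph(paths[["graphml"]], format = "graphml")
  expect_equal(igraph::gorder(g), 3)
  expect_equal(igraph::gsize(g), 1)
})
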