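# Fixture builders and independent oracles used across the suite.
# Everything is generated in code under fixed seeds; no stored data.

# small matched cohort; single 1:1 block unless specified
smallCohortConfig <- function(seed = 1, nPairs = 20L, nFeatures = 100L,
                              controlsPerCase = 1L, nInformative = 5L,
                              effectSize = 2, missingRate = 0.1,
                              nIncompletePairs = 0L, block = "gene_expression",
                              ...) {
  cohortConfig(nPairs = nPairs,
               blockSpecs = data.frame(block = block,
                                       n_features = as.integer(nFeatures),
                                       controls_per_case = as.integer(controlsPerCase)),
               nInformativePerBlock = as.integer(nInformative),
               effectSize = effectSize, missingRate = missingRate,
               nIncompletePairs = as.integer(nIncompletePairs),
               seed = seed, ...)
}

# cohort -> normalized complete analysis tensor (+ truth), one block
preparedTensor <- function(cfg, imputeRanks = c(2L, 2L, 2L)) {
  coh <- generateCohort(cfg)
  block <- cfg$blockSpecs$block[1L]
  tens <- binToTensor(coh$measurements, block)
  sp <- filterAndSplit(tens)
  imp <- imputeMissing(sp$analysis, ranks = imputeRanks)
  nrm <- suppressWarnings(withinNormalize(imp$tensor))
  nrm@mask[] <- TRUE
  list(tensor = nrm, labels = tensorDesign(nrm)$role,
       truth = coh$truth, validation = sp$validation, cohort = coh)
}

# bare OmicsTensor from an array, with a 1:1 pairing design
makeTensor <- function(values, block = "test",
                       tp = rev(seq_len(dim(values)[3L])) * 3 - 3,
                       roles = NULL, pairs = NULL, mask = NULL) {
  d <- dim(values)
  subj <- sprintf("s%02d", seq_len(d[1L]))
  feat <- sprintf("f%03d", seq_len(d[2L]))
  dimnames(values) <- list(subj, feat, format(tp))
  if (is.null(mask)) mask <- !is.na(values)
  dimnames(mask) <- dimnames(values)
  if (is.null(roles)) roles <- rep(c("case", "control"), length.out = d[1L])
  if (is.null(pairs)) pairs <- sprintf("p%02d", rep(seq_len(ceiling(d[1L] / 2)),
                                                    each = 2L)[seq_len(d[1L])])
  new("OmicsTensor", values = values, mask = mask, block = block,
      timePoints = tp,
      design = data.frame(subject_id = subj, pair_id = pairs, role = roles))
}

# random tensor generated from a known Tucker3 model with orthonormal
# loadings; the core is redrawn until every mode unfolding is well
# conditioned, so each of the generating components carries real signal
tuckerTensor <- function(dims, ranks, seed = 1, noiseSd = 0) {
  set.seed(seed)
  A <- qr.Q(qr(matrix(rnorm(dims[1] * ranks[1]), dims[1])))
  B <- qr.Q(qr(matrix(rnorm(dims[2] * ranks[2]), dims[2])))
  C <- qr.Q(qr(matrix(rnorm(dims[3] * ranks[3]), dims[3])))
  repeat {
    G <- array(rnorm(prod(ranks), sd = 3), ranks)
    cond <- vapply(1:3, function(m) {
      d <- svd(tritime:::unfoldTensor(G, m), nu = 0, nv = 0)$d
      min(d) / max(d)
    }, numeric(1))
    if (min(cond) > 0.3) break
  }
  X <- tritime:::ttm(tritime:::ttm(tritime:::ttm(G, A, 1L), B, 2L), C, 3L)
  if (noiseSd > 0) X <- X + array(rnorm(prod(dims), sd = noiseSd), dims)
  X
}

# independent two-way PLS oracle: NIPALS with response deflation only,
# dummy-coded Y, the same construction the tensor engine generalizes.
# Written directly from the matrix algorithm; shares no code with the
# package's tensor path.
oraclePLS2 <- function(X, labels, H = 2L) {
  classes <- sort(unique(labels))
  Y <- stats::model.matrix(~ 0 + factor(labels, levels = classes))
  Yc <- scale(Y, scale = FALSE)
  Xc <- scale(X, scale = FALSE)
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, H); Tm <- matrix(0, n, H)
  FY <- Yc
  ssy <- numeric(H)
  for (h in seq_len(H)) {
    u <- FY[, which.max(colSums(FY^2))]
    repeat {
      w <- crossprod(Xc, u); w <- w / sqrt(sum(w^2))
      tt <- Xc %*% w
      q <- crossprod(FY, tt); q <- q / sqrt(sum(q^2))
      uNew <- FY %*% q
      if (sum((uNew - u)^2) < 1e-26) { u <- uNew; break }
      u <- uNew
    }
    if (w[which.max(abs(w))] < 0) w <- -w
    tt <- Xc %*% w
    W[, h] <- w; Tm[, h] <- tt
    b <- crossprod(FY, tt) / sum(tt^2)
    before <- sum(FY^2)
    FY <- FY - tt %*% t(b)
    ssy[h] <- before - sum(FY^2)
  }
  list(weights = W, scores = Tm, ssy = ssy)
}

# Wold VIP from the two-way oracle fit
oracleVIP <- function(oracle) {
  p <- nrow(oracle$weights)
  sqrt(p * as.vector(oracle$weights^2 %*% oracle$ssy) / sum(oracle$ssy))
}

# first-order partial correlation by the textbook recursive formula
pcorRecursive3 <- function(cc, i, j, k) {
  (cc[i, j] - cc[i, k] * cc[j, k]) /
    sqrt((1 - cc[i, k]^2) * (1 - cc[j, k]^2))
}

# full-order partial correlation by explicit double regression: residualize
# variables i and j on all others with lm, then correlate the residuals
pcorRegression <- function(X, i, j) {
  others <- setdiff(seq_len(ncol(X)), c(i, j))
  ri <- stats::resid(stats::lm(X[, i] ~ X[, others]))
  rj <- stats::resid(stats::lm(X[, j] ~ X[, others]))
  stats::cor(ri, rj)
}
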