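#' Fit an N-way PLS discriminant model on a three-way array
#'
#' Trilinear PLS (tri-PLS2) with a dummy-coded class response. Per
#' component the feature-mode and time-mode weight vectors are the
#' dominant singular pair of the J x K covariance unfolding
#' \code{Z = X_(1)' u} between the centered tensor and the current
#' response score, which maximizes the squared covariance between the
#' tensor projection and the response. The subject score is the tensor
#' contracted with the (feature x time) rank-1 weight; only the response
#' is deflated, so scores of any component are always the plain
#' contraction of the centered data with that component's weights.
#' Classification uses linear discriminant analysis on the subject
#' scores (default) or the inner regression with a midpoint cutoff.
#'
#' @param tensor an \linkS4class{OmicsTensor} (complete, post-imputation)
#'   or a plain I x J x K array with dimnames.
#' @param labels class labels, length I, exactly two classes.
#' @param H number of components (>= 1, < number of subjects).
#' @param discriminant \code{"lda"} (default) or \code{"inner"}.
#' @return an \linkS4class{NPLSDAModel}.
#' @seealso [predictNPLSDA()], [crossValidate()], [computeVIP()]
#' @export
fitNPLSDA <- function(tensor, labels, H = 2L, discriminant = c("lda", "inner")) {
  discriminant <- match.arg(discriminant)
  X <- if (methods::is(tensor, "OmicsTensor")) tensor@values else tensor
  d <- dim(X)
  if (length(d) != 3L) stop("predictor must be a 3-way array")
  if (anyNA(X)) stop("predictor tensor contains missing values; impute first")
  labels <- as.character(labels)
  if (length(labels) != d[1L]) stop("labels must have one entry per subject")
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("labels contain a single class; nothing to discriminate")
  if (length(classes) > 2L) stop("only two-class problems are supported")
  H <- as.integer(H)
  if (H < 1L) stop("H must be >= 1")
  if (H >= d[1L]) stop("H must be smaller than the number of subjects")

  Y <- stats::model.matrix(~ 0 + factor(labels, levels = classes))
  colnames(Y) <- classes
  yMean <- colMeans(Y)
  Yc <- sweep(Y, 2L, yMean)
  xMean <- apply(X, c(2L, 3L), mean)
  Xc <- sweep(X, c(2L, 3L), xMean)
  X1 <- unfoldTensor(Xc, 1L)

  J <- d[2L]; K <- d[3L]
  WJ <- matrix(0, J, H); WK <- matrix(0, K, H)
  V <- matrix(0, ncol(Y), H)
  Tm <- matrix(0, d[1L], H)
  ssy <- numeric(H)
  FY <- Yc
  totSSY <- sumsq(Yc)
  for (h in seq_len(H)) {
    u <- FY[, which.max(colSums(FY^2))]
    tOld <- rep(Inf, d[1L])
    for (iter in 1:500) {
      Z <- matrix(crossprod(X1, u), J, K)
      sv <- svd(Z, nu = 1L, nv = 1L)
      wj <- sv$u[, 1L]; wk <- sv$v[, 1L]
      tt <- as.vector(X1 %*% as.vector(outer(wj, wk)))
      q <- crossprod(FY, tt)
      qn <- sqrt(sum(q^2))
      if (qn < .Machine$double.eps) break
      q <- q / qn
      u <- as.vector(FY %*% q)
      if (sqrt(sumsq(tt - tOld)) < 1e-12 * max(1, sqrt(sumsq(tt)))) break
      tOld <- tt
    }
    # sign convention: largest-magnitude feature weight entry positive
    if (wj[which.max(abs(wj))] < 0) { wj <- -wj; wk <- -wk }
    tt <- as.vector(X1 %*% as.vector(outer(wj, wk)))
    WJ[, h] <- wj; WK[, h] <- wk; Tm[, h] <- tt
    V[, h] <- as.vector(q)
    b <- crossprod(FY, tt) / max(sumsq(tt), .Machine$double.eps)
    before <- sumsq(FY)
    FY <- FY - tt %*% t(b)
    ssy[h] <- before - sumsq(FY)
  }

  G <- crossprod(Tm)
  B <- solve(G + diag(1e-12 * max(diag(G)), H), crossprod(Tm, Yc))
  R2Y <- 1 - sumsq(Yc - Tm %*% B) / totSSY
  Xhat1 <- Tm %*% solve(G + diag(1e-12 * max(diag(G)), H), crossprod(Tm, X1))
  R2X <- 1 - sumsq(X1 - Xhat1) / max(sumsq(X1), .Machine$double.eps)

  elem <- data.frame(
    component = seq_len(H),
    ssy_explained = ssy / totSSY,
    ssx_explained = vapply(seq_len(H), function(h) {
      tt <- Tm[, h]
      sumsq(tt %*% crossprod(tt, X1) / max(sumsq(tt), .Machine$double.eps)) /
        max(sumsq(X1), .Machine$double.eps)
    }, numeric(1))
  )

  disc <- .fitScoreDiscriminant(Tm, labels, classes, discriminant)

  dn <- dimnames(X)
  new("NPLSDAModel",
      nComponents = H, scores = Tm, featureWeights = WJ, timeWeights = WK,
      responseWeights = V, coef = B, xMean = xMean, yMean = yMean,
      classes = classes, labels = labels,
      R2X = max(0, min(1, R2X)), R2Y = max(0, min(1, R2Y)),
      ssyExplained = ssy, elementTable = elem, discriminant = disc,
      featureIds = dn[[2L]] %||% as.character(seq_len(J)),
      timePoints = if (is.null(dn[[3L]])) rep(NA_real_, K) else
        suppressWarnings(as.numeric(dn[[3L]])))
}

.fitScoreDiscriminant <- function(Tm, labels, classes, type) {
  mu <- lapply(classes, function(cl) colMeans(Tm[labels == cl, , drop = FALSE]))
  pooled <- Reduce(`+`, lapply(classes, function(cl) {
    Z <- scale(Tm[labels == cl, , drop = FALSE], center = TRUE, scale = FALSE)
    crossprod(Z)
  })) / max(nrow(Tm) - length(classes), 1L)
  ridge <- 1e-8 * max(diag(pooled), 1)
  pooledInv <- solve(pooled + diag(ridge, ncol(Tm)))
  priors <- as.vector(table(factor(labels, levels = classes))) / length(labels)
  list(type = type, means = mu, pooledInv = pooledInv, priors = priors)
}

#' Predict class membership for new subjects
#'
#' Projects new subject slices onto the trained components (centering with
#' the training means) and applies the trained discriminant rule. Fully
#' deterministic; posterior ties are broken toward the first class in
#' sorted label order.
#'
#' @param model an \linkS4class{NPLSDAModel}.
#' @param tensor new data, I' x J x K, with feature and timepoint modes
#'   matching training (checked by name when dimnames are present).
#' @return list with \code{class}, \code{scores} (I' x H), and
#'   \code{posterior} (I' x 2), plus \code{yhat} (inner-regression
#'   prediction of the dummy response).
#' @export
predictNPLSDA <- function(model, tensor) {
  X <- if (methods::is(tensor, "OmicsTensor")) tensor@values else tensor
  d <- dim(X)
  if (length(d) != 3L) stop("new data must be a 3-way array")
  if (d[2L] != nrow(model@featureWeights))
    stop("mode mismatch: feature mode has ", d[2L], " entries, model expects ",
         nrow(model@featureWeights))
  if (d[3L] != nrow(model@timeWeights))
    stop("mode mismatch: timepoint mode has ", d[3L], " entries, model expects ",
         nrow(model@timeWeights))
  dn <- dimnames(X)
  if (!is.null(dn[[2L]]) && length(model@featureIds) &&
      !identical(dn[[2L]], model@featureIds))
    stop("mode mismatch: feature ids differ from the training feature mode")

  Xc <- sweep(X, c(2L, 3L), model@xMean)
  X1 <- unfoldTensor(Xc, 1L)
  H <- model@nComponents
  Tn <- vapply(seq_len(H), function(h)
    as.vector(X1 %*% as.vector(outer(model@featureWeights[, h],
                                     model@timeWeights[, h]))),
    numeric(d[1L]))
  Tn <- matrix(Tn, nrow = d[1L])
  yhat <- sweep(Tn %*% model@coef, 2L, -model@yMean)

  disc <- model@discriminant
  if (disc$type == "inner") {
    cls <- model@classes[max.col(yhat, ties.method = "first")]
    post <- yhat
  } else {
    ll <- vapply(seq_along(model@classes), function(g) {
      dev <- sweep(Tn, 2L, disc$means[[g]])
      -0.5 * rowSums((dev %*% disc$pooledInv) * dev) + log(disc$priors[g])
    }, numeric(d[1L]))
    ll <- matrix(ll, nrow = d[1L])
    post <- exp(ll - apply(ll, 1L, max))
    post <- post / rowSums(post)
    cls <- model@classes[max.col(post, ties.method = "first")]
  }
  list(class = cls, scores = Tn, posterior = post, yhat = yhat)
}

#' Cross-validate an NPLS-DA model
#'
#' Leave-one-out or k-fold cross-validation of goodness of fit (R2) and
#' predictive ability (Q2 = 1 - PRESS/TSS on the dummy-coded response).
#' k-fold schemes are repeated over random fold assignments (stratified
#' by class) and averaged; leave-one-out is deterministic and performs
#' exactly n fits.
#'
#' Within-normalized case-control data require group-aware folds: after
#' normalization a case's values mirror its matched controls', so
#' splitting a set across folds leaks the held-out subject's profile
#' into training and inflates Q2. When \code{groups} is supplied (or
#' the input is an \linkS4class{OmicsTensor}, whose design provides the
#' pairing), whole groups are held out together and \code{"loo"} means
#' leave-one-group-out.
#'
#' @param tensor complete 3-way array or \linkS4class{OmicsTensor}.
#' @param labels two-class labels.
#' @param H number of components.
#' @param scheme \code{"loo"}, \code{"kfold5"}, or \code{"kfold10"}.
#' @param nRepeats repeats for the k-fold schemes (ignored for LOO).
#' @param seed integer seed for fold assignment.
#' @param groups optional grouping vector (e.g. case-control set ids);
#'   defaults to the tensor's pair ids for an \linkS4class{OmicsTensor}
#'   and to subject-level folds otherwise.
#' @return list with \code{scheme}, \code{n_repeats}, \code{r2} (mean
#'   training R2Y over folds), \code{q2}, \code{q2_sd} (across repeats),
#'   \code{accuracy} (held-out classification rate), and
#'   \code{predictions} (data.frame subject/repeat/fold/truth/predicted).
#' @export
crossValidate <- function(tensor, labels, H = 2L,
                          scheme = c("loo", "kfold5", "kfold10"),
                          nRepeats = 1L, seed = 1L, groups = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(groups) && methods::is(tensor, "OmicsTensor"))
    groups <- tensor@design$pair_id
  X <- if (methods::is(tensor, "OmicsTensor")) tensor@values else tensor
  labels <- as.character(labels)
  n <- dim(X)[1L]
  if (is.null(groups)) groups <- as.character(seq_len(n))
  groups <- as.character(groups)
  gids <- unique(groups)
  classes <- sort(unique(labels))
  k <- switch(scheme, loo = length(gids), kfold5 = 5L, kfold10 = 10L)
  if (scheme != "loo" && k > length(gids))
    stop("fold count exceeds the number of groups")
  if (scheme != "loo" && length(gids) == n && k > min(table(labels)))
    stop("fold count exceeds the size of the smallest class")
  if (scheme == "loo") nRepeats <- 1L

  Yfull <- stats::model.matrix(~ 0 + factor(labels, levels = classes))
  ybar <- colMeans(Yfull)

  rng <- .seedStream(seed)
  q2rep <- numeric(nRepeats); r2rep <- numeric(nRepeats)
  accrep <- numeric(nRepeats)
  preds <- vector("list", nRepeats)
  for (r in seq_len(nRepeats)) {
    gfolds <- if (scheme == "loo") stats::setNames(seq_along(gids), gids) else
      .groupFolds(gids, groups, labels, k, rng())
    folds <- unname(gfolds[groups])
    press <- 0; tss <- 0; r2sum <- 0; hit <- 0L
    rows <- vector("list", k)
    for (f in seq_len(k)) {
      test <- which(folds == f)
      train <- setdiff(seq_len(n), test)
      m <- fitNPLSDA(X[train, , , drop = FALSE], labels[train], H)
      p <- predictNPLSDA(m, X[test, , , drop = FALSE])
      Yt <- Yfull[test, , drop = FALSE]
      press <- press + sumsq(Yt - p$yhat)
      tss <- tss + sumsq(sweep(Yt, 2L, ybar))
      r2sum <- r2sum + m@R2Y
      hit <- hit + sum(p$class == labels[test])
      rows[[f]] <- data.frame(subject = test, rep = r, fold = f,
                              truth = labels[test], predicted = p$class)
    }
    q2rep[r] <- 1 - press / tss
    r2rep[r] <- r2sum / k
    accrep[r] <- hit / n
    preds[[r]] <- do.call(rbind, rows)
  }
  list(scheme = scheme, n_repeats = nRepeats,
       r2 = mean(r2rep), q2 = mean(q2rep),
       q2_sd = if (nRepeats > 1L) stats::sd(q2rep) else NA_real_,
       accuracy = mean(accrep),
       predictions = do.call(rbind, preds))
}

# fold assignment at the group level; for subject-level groups this is
# plain class-stratified assignment, otherwise groups (case-control sets)
# are distributed evenly so no set is ever split across folds
.groupFolds <- function(gids, groups, labels, k, seed) {
  set.seed(seed)
  if (length(gids) == length(groups)) {        # subject-level: stratify
    folds <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
    return(stats::setNames(folds[match(gids, groups)], gids))
  }
  stats::setNames(rep_len(seq_len(k), length(gids))[sample(length(gids))],
                  gids)
}

# deterministic stream of sub-seeds derived from one integer seed
.seedStream <- function(seed) {
  counter <- 0
  base <- as.numeric(seed) %% 2147480000
  function() {
    counter <<- counter + 1
    as.integer((base * 69069 + counter * 362437) %% 2147483647)
  }
}

#' Concatenate omics blocks into one integrated tensor
#'
#' Feature-wise concatenation of several blocks over their common
#' subjects, each block scaled to unit total sum of squares first so that
#' no single (large) block dominates the covariance structure of the
#' joint model.
#'
#' @param tensors named list of \linkS4class{OmicsTensor} objects sharing
#'   the timepoint grid.
#' @param features optional named list restricting each block to a subset
#'   of feature ids before concatenation.
#' @return an \linkS4class{OmicsTensor} with block name
#'   \code{"integrated"}; feature ids are prefixed with their block.
#' @export
joinBlocks <- function(tensors, features = NULL) {
  stopifnot(length(tensors) >= 1L)
  tp <- timePoints(tensors[[1L]])
  for (tn in tensors) stopifnot(identical(timePoints(tn), tp))
  common <- Reduce(intersect, lapply(tensors, subjectIds))
  if (length(common) < 4L) stop("fewer than 4 subjects shared across blocks")
  slabs <- list(); fids <- character(0)
  for (bn in names(tensors)) {
    tn <- tensors[[bn]]
    keep <- featureIds(tn)
    if (!is.null(features) && !is.null(features[[bn]]))
      keep <- intersect(keep, features[[bn]])
    if (!length(keep)) next
    V <- tn@values[match(common, subjectIds(tn)), keep, , drop = FALSE]
    ss <- sumsq(V)
    if (ss > 0) V <- V / sqrt(ss)
    dimnames(V)[[2L]] <- paste(bn, keep, sep = ":")
    slabs[[bn]] <- V
    fids <- c(fids, dimnames(V)[[2L]])
  }
  if (!length(slabs)) stop("no features left after restriction")
  J <- length(fids)
  vals <- array(NA_real_, c(length(common), J, length(tp)),
                dimnames = list(common, fids, as.character(tp)))
  at <- 0L
  for (V in slabs) {
    vals[, at + seq_len(dim(V)[2L]), ] <- V
    at <- at + dim(V)[2L]
  }
  des <- tensorDesign(tensors[[1L]])
  des <- des[match(common, des$subject_id), , drop = FALSE]
  rownames(des) <- NULL
  new("OmicsTensor", values = vals,
      mask = array(TRUE, dim(vals), dimnames = dimnames(vals)),
      block = "integrated", timePoints = tp, design = des)
}
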