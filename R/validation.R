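#' Permutation significance of a selected feature set
#'
#' Two complementary null models. \code{mode = "random_features"} draws,
#' per permutation, a random feature set of the same size as the
#' selection, refits the NPLS-DA model, and records its R2 and
#' cross-validated Q2 — testing whether the VIP-selected set outperforms
#' size-matched random signatures. \code{mode = "permuted_labels"}
#' shuffles the outcome labels (by default swapping case/control roles
#' within matched sets, the exchangeable unit under pairing) and refits
#' on the selected set — testing whether the labels carry signal at all.
#' One-sided p-values use the conservative (1 + more-extreme) /
#' (nPermutations + 1) estimator.
#'
#' @param tensor complete 3-way array or \linkS4class{OmicsTensor} (the
#'   pairing structure for paired label swaps comes from its design).
#' @param labels two-class labels.
#' @param selectedIds non-empty feature id set to test.
#' @param mode \code{"random_features"} or \code{"permuted_labels"}.
#' @param nPermutations number of null draws (>= 1; default 100).
#' @param H components for the refits.
#' @param cvScheme scheme used for the Q2 of each refit.
#' @param paired for \code{"permuted_labels"}: swap roles within pairs
#'   (default TRUE) or shuffle labels freely.
#' @param seed integer seed; identical seeds give identical null
#'   distributions.
#' @return list with \code{mode}, \code{n_permutations}, \code{observed}
#'   (r2, q2), \code{null} (data.frame r2/q2 per permutation), and
#'   \code{p_value} (named: r2, q2).
#' @export
permutationTest <- function(tensor, labels, selectedIds,
                            mode = c("random_features", "permuted_labels"),
                            nPermutations = 100L, H = 2L,
                            cvScheme = "kfold5", paired = TRUE, seed = 1L) {
  mode <- match.arg(mode)
  if (!length(selectedIds)) stop("selectedIds must be non-empty")
  if (nPermutations < 1L) stop("nPermutations must be >= 1")
  X <- if (methods::is(tensor, "OmicsTensor")) tensor@values else tensor
  des <- if (methods::is(tensor, "OmicsTensor")) tensor@design else NULL
  labels <- as.character(labels)
  fids <- dimnames(X)[[2L]]
  idx <- match(selectedIds, fids)
  if (anyNA(idx)) stop("selectedIds contain unknown features")
  if (mode == "random_features" && length(idx) >= length(fids))
    stop("selection covers the whole feature universe; nothing to randomize")

  groups <- if (!is.null(des)) des$pair_id
  scoreSet <- function(cols, labs, foldSeed) {
    Xi <- X[, cols, , drop = FALSE]
    Hi <- min(H, length(cols))
    cv <- crossValidate(Xi, labs, H = Hi, scheme = cvScheme, seed = foldSeed,
                        groups = groups)
    c(r2 = cv$r2, q2 = cv$q2)
  }

  rng <- .seedStream(seed)
  obs <- scoreSet(idx, labels, rng())
  null <- matrix(NA_real_, nPermutations, 2L,
                 dimnames = list(NULL, c("r2", "q2")))
  for (b in seq_len(nPermutations)) {
    s <- rng()
    set.seed(s)
    if (mode == "random_features") {
      cols <- sample(seq_along(fids), length(idx))
      null[b, ] <- scoreSet(cols, labels, rng())
    } else {
      labs <- .permuteLabels(labels, des, paired)
      null[b, ] <- scoreSet(idx, labs, rng())
    }
  }
  p <- vapply(c("r2", "q2"), function(st)
    (1 + sum(null[, st] >= obs[[st]])) / (nPermutations + 1), numeric(1))
  list(mode = mode, n_permutations = nPermutations,
       observed = as.list(obs), null = as.data.frame(null), p_value = p)
}

.permuteLabels <- function(labels, design, paired) {
  if (paired && !is.null(design)) {
    out <- labels
    cls <- sort(unique(labels))
    for (pid in unique(design$pair_id)) {
      if (stats::runif(1) < 0.5) {     # flip the whole set's roles
        rows <- which(design$pair_id == pid)
        out[rows] <- ifelse(labels[rows] == cls[1L], cls[2L], cls[1L])
      }
    }
    out
  } else {
    sample(labels)
  }
}

#' Per-timepoint discriminant validation on held-out subjects
#'
#' Held-out subjects (those failing the 3-of-5 completeness filter)
#' cannot enter the tensor model, so the selected signature is validated
#' per timepoint: for every timepoint a linear discriminant model is
#' trained on the analysis subjects' selected-feature slice and applied
#' to the validation subjects observed at that timepoint. When the
#' feature count exceeds the (tiny) per-timepoint sample size, the
#' pooled covariance is shrunk toward its diagonal before inversion.
#' Cross-timepoint prediction (train on timepoint a, predict at b) is
#' available through \code{trainTimepoint}.
#'
#' @param trainTensor analysis-set \linkS4class{OmicsTensor} (complete).
#' @param trainLabels labels for the analysis subjects.
#' @param validTensor validation \linkS4class{OmicsTensor} (may contain
#'   missing cells; subjects enter only at observed timepoints).
#' @param validLabels labels for the validation subjects.
#' @param selectedIds feature ids of the signature.
#' @param trainTimepoint optional MBSC label: train every rule on this
#'   timepoint's slice instead of the matching one.
#' @return data.frame with one row per timepoint: \code{timepoint},
#'   \code{n}, \code{accuracy} (NA when fewer than 2 subjects or a
#'   single class at that timepoint), plus the per-subject predictions
#'   as \code{attr(, "predictions")}.
#' @export
timepointValidate <- function(trainTensor, trainLabels, validTensor,
                              validLabels, selectedIds,
                              trainTimepoint = NULL) {
  tp <- timePoints(trainTensor)
  fTr <- featureIds(trainTensor)
  idx <- match(selectedIds, fTr)
  if (anyNA(idx)) stop("selectedIds missing from the training tensor")
  if (is.null(validTensor)) {
    out <- data.frame(timepoint = tp, n = 0L, accuracy = NA_real_)
    attr(out, "predictions") <- data.frame()
    return(out)
  }
  idxV <- match(selectedIds, featureIds(validTensor))
  if (anyNA(idxV)) stop("selectedIds missing from the validation tensor")
  validLabels <- as.character(validLabels)
  trainLabels <- as.character(trainLabels)

  rows <- list(); preds <- list()
  for (k in seq_along(tp)) {
    kTrain <- if (is.null(trainTimepoint)) k else match(trainTimepoint, tp)
    Xtr <- trainTensor@values[, idx, kTrain, drop = TRUE]
    Xtr <- matrix(Xtr, ncol = length(idx))
    obsK <- apply(validTensor@mask[, idxV, k, drop = FALSE], 1L, all)
    vs <- which(obsK)
    n <- length(vs)
    acc <- NA_real_
    if (n >= 2L && length(unique(validLabels[vs])) == 2L) {
      Xv <- matrix(validTensor@values[vs, idxV, k, drop = TRUE], ncol = length(idx))
      pred <- .ldaPredict(Xtr, trainLabels, Xv)
      acc <- mean(pred == validLabels[vs])
      preds[[length(preds) + 1L]] <- data.frame(
        timepoint = tp[k], subject_id = subjectIds(validTensor)[vs],
        truth = validLabels[vs], predicted = pred)
    } else if (n >= 1L) {
      Xv <- matrix(validTensor@values[vs, idxV, k, drop = TRUE], ncol = length(idx))
      pred <- .ldaPredict(Xtr, trainLabels, Xv)
      preds[[length(preds) + 1L]] <- data.frame(
        timepoint = tp[k], subject_id = subjectIds(validTensor)[vs],
        truth = validLabels[vs], predicted = pred)
    }
    rows[[k]] <- data.frame(timepoint = tp[k], n = n, accuracy = acc)
  }
  out <- do.call(rbind, rows)
  attr(out, "predictions") <- if (length(preds)) do.call(rbind, preds)
                              else data.frame()
  out
}

# pooled-covariance LDA with diagonal shrinkage when p is large relative
# to n; deterministic, equal treatment of both classes
.ldaPredict <- function(Xtr, labels, Xnew) {
  classes <- sort(unique(labels))
  p <- ncol(Xtr); n <- nrow(Xtr)
  if (p < n - length(classes) - 5L) {
    # collinear-variable warnings are routine on within-normalized data
    # (case and control values mirror each other); lda drops them itself
    fit <- suppressWarnings(MASS::lda(Xtr, grouping = factor(labels,
                                                             levels = classes)))
    return(as.character(stats::predict(fit, Xnew)$class))
  }
  mu <- lapply(classes, function(cl) colMeans(Xtr[labels == cl, , drop = FALSE]))
  Z <- Xtr
  for (g in seq_along(classes))
    Z[labels == classes[g], ] <- sweep(Xtr[labels == classes[g], , drop = FALSE],
                                       2L, mu[[g]])
  Sig <- shrinkCovariance(Z)
  Sinv <- solve(Sig + diag(1e-8 * max(diag(Sig)), p))
  priors <- as.vector(table(factor(labels, levels = classes))) / n
  ll <- vapply(seq_along(classes), function(g) {
    dev <- sweep(Xnew, 2L, mu[[g]])
    -0.5 * rowSums((dev %*% Sinv) * dev) + log(priors[g])
  }, numeric(nrow(Xnew)))
  ll <- matrix(ll, nrow = nrow(Xnew))
  classes[max.col(ll, ties.method = "first")]
}
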