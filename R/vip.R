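# Variable importance for projection (VIP) under the three data
# arrangements, percentile thresholding, and the union/intersection
# candidate search.
#
# VIP formula (Wold): VIP_j = sqrt(p * sum_h[SSY_h * a_jh] / sum_h SSY_h)
# where a_jh is the squared (unit-norm) weight of variable j on component
# h and SSY_h the response sum of squares explained by component h. For
# the three-way model the per-(feature, timepoint) weight element is the
# Kronecker product entry w_jh * w_kh, whose squares sum to 1 over (j, k)
# because both mode weights are unit norm — so the identity
# sum_jk VIP_jk^2 = J*K carries over.

#' Compute VIP scores under one of three data arrangements
#'
#' \describe{
#'   \item{vip2d}{unfolds the tensor to a subjects x (features x
#'     timepoints) wide matrix, fits a standard two-way PLS-DA on it, and
#'     computes one VIP value per feature per timepoint; the per-feature
#'     score aggregates over timepoints (max by default).}
#'   \item{vip3d_model1}{uses the three-way model's Kronecker weights,
#'     averages the per-timepoint VIP over time per feature and
#'     component (constraining the time mode), then averages over
#'     components.}
#'   \item{vip3d_model2}{computes the VIP per feature per timepoint per
#'     component, sums over timepoints within each component, and
#'     averages the summed values over components.}
#' }
#'
#' @param model fitted \linkS4class{NPLSDAModel}, or NULL to fit
#'   internally from \code{tensor} and \code{labels}.
#' @param tensor complete 3-way array or \linkS4class{OmicsTensor}.
#' @param labels two-class labels (needed when fitting internally or for
#'   vip2d, which always fits its own two-way model).
#' @param strategy one of \code{"vip2d"}, \code{"vip3d_model1"},
#'   \code{"vip3d_model2"}.
#' @param H components used when a model must be fitted.
#' @param aggregate2d collapse rule over timepoints for vip2d
#'   (\code{"max"} default, or \code{"mean"}).
#' @return a \linkS4class{VIPSelection} with values only (no threshold
#'   applied yet).
#' @export
computeVIP <- function(model = NULL, tensor = NULL, labels = NULL,
                       strategy = c("vip2d", "vip3d_model1", "vip3d_model2"),
                       H = 2L, aggregate2d = c("max", "mean")) {
  strategy <- match.arg(strategy)
  aggregate2d <- match.arg(aggregate2d)
  X <- if (methods::is(tensor, "OmicsTensor")) tensor@values else tensor
  if (is.null(model) && is.null(X))
    stop("either a fitted model or (tensor, labels) is required")

  if (strategy == "vip2d") {
    if (is.null(X) || is.null(labels))
      stop("vip2d needs the tensor and labels to fit the unfolded model")
    res <- .vip2d(X, labels, H, aggregate2d)
  } else {
    if (is.null(model)) model <- fitNPLSDA(X, labels, H)
    res <- .vip3d(model, strategy)
  }

  new("VIPSelection", strategy = strategy, vipValues = res$score,
      detail = res$detail, percentile = NA_real_,
      selectedIds = character(0), provenance = strategy,
      r2 = NA_real_, q2 = NA_real_)
}

# two-way VIP on the subjects x (features * timepoints) unfolding
.vip2d <- function(X, labels, H, aggregate2d) {
  d <- dim(X)
  J <- d[2L]; K <- d[3L]
  wide <- unfoldTensor(X, 1L)                       # columns (j,k), j fastest
  fids <- dimnames(X)[[2L]] %||% as.character(seq_len(J))
  # fit as a K=1 tensor: identical to a two-way PLS with Y-deflation only
  m <- fitNPLSDA(array(wide, c(d[1L], J * K, 1L),
                       dimnames = list(dimnames(X)[[1L]],
                                       paste(rep(fids, K),
                                             rep(seq_len(K), each = J),
                                             sep = "@"),
                                       "1")),
                 labels, H)
  W <- m@featureWeights                              # (J*K) x H, unit columns
  ssy <- m@ssyExplained
  vip2 <- (J * K) * (W^2 %*% ssy) / sum(ssy)
  vipJK <- matrix(sqrt(pmax(vip2, 0)), J, K,
                  dimnames = list(fids,
                                  dimnames(X)[[3L]] %||% as.character(seq_len(K))))
  score <- if (aggregate2d == "max") apply(vipJK, 1L, max) else rowMeans(vipJK)
  detail <- data.frame(feature_id = rep(fids, K),
                       timepoint = rep(dimnames(X)[[3L]] %||%
                                         as.character(seq_len(K)), each = J),
                       vip = as.vector(vipJK))
  list(score = score, detail = detail)
}

.vip3d <- function(model, strategy) {
  WJ <- model@featureWeights; WK <- model@timeWeights
  J <- nrow(WJ); K <- nrow(WK); H <- model@nComponents
  ssy <- model@ssyExplained
  ssyFrac <- ssy / sum(ssy)
  fids <- model@featureIds
  # per-component per-(j,k) VIP: sqrt(J*K * a_jkh) scaled by that
  # component's share of the explained response SS
  perComp <- lapply(seq_len(H), function(h) {
    a <- outer(WJ[, h]^2, WK[, h]^2)                # sums to 1 over (j,k)
    sqrt(J * K * a)
  })
  if (strategy == "vip3d_model1") {
    # mean VIP per variable over time, per component; then weighted mean
    # over components by explained response SS
    perVar <- vapply(seq_len(H), function(h) rowMeans(perComp[[h]]),
                     numeric(J))
    perVar <- matrix(perVar, nrow = J)
    score <- as.vector(perVar %*% ssyFrac)
    detail <- data.frame(feature_id = rep(fids, H),
                         component = rep(seq_len(H), each = J),
                         vip = as.vector(perVar))
  } else {
    # sum over timepoints within component, then component-weighted mean
    perVar <- vapply(seq_len(H), function(h) rowSums(perComp[[h]]),
                     numeric(J))
    perVar <- matrix(perVar, nrow = J)
    score <- as.vector(perVar %*% ssyFrac)
    detail <- data.frame(feature_id = rep(fids, H),
                         component = rep(seq_len(H), each = J),
                         vip = as.vector(perVar))
  }
  names(score) <- fids
  list(score = score, detail = detail)
}

#' Threshold VIP scores at a percentile
#'
#' Selects the features whose VIP score is strictly larger than the
#' given percentile of the block's VIP distribution (computed with
#' linear interpolation, \code{stats::quantile} type 7). Ties at the
#' threshold are excluded. The conventional defaults are the 99th
#' percentile for gene-expression blocks and the 95th for metabolomics.
#'
#' @param vipValues named numeric vector of VIP scores (or a
#'   \linkS4class{VIPSelection}).
#' @param percentile percentile in (0, 100).
#' @return for a numeric input, the selected feature ids; for a
#'   \linkS4class{VIPSelection}, the object with \code{selectedIds} and
#'   \code{percentile} filled in.
#' @export
selectByPercentile <- function(vipValues, percentile = 95) {
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must lie strictly between 0 and 100")
  sel <- NULL
  if (methods::is(vipValues, "VIPSelection")) sel <- vipValues
  v <- if (is.null(sel)) vipValues else sel@vipValues
  if (!length(v)) stop("empty VIP value vector")
  thr <- stats::quantile(v, percentile / 100, type = 7, names = FALSE)
  ids <- names(v)[v > thr]
  if (is.null(sel)) return(ids)
  sel@selectedIds <- ids
  sel@percentile <- percentile
  sel
}

#' Search unions and intersections of per-strategy selections
#'
#' Candidate feature sets are the per-strategy selections plus all their
#' pairwise and three-way unions and intersections (duplicates and empty
#' sets dropped). Each candidate is refitted with NPLS-DA on the reduced
#' tensor and cross-validated; the winner has the highest Q2, ties going
#' to the higher R2 and then to the smaller set.
#'
#' @param selections list of \linkS4class{VIPSelection} objects with
#'   \code{selectedIds} filled (from [selectByPercentile()]).
#' @param tensor complete 3-way array or \linkS4class{OmicsTensor}.
#' @param labels two-class labels.
#' @param H components for the refits.
#' @param cvScheme cross-validation scheme for scoring candidates.
#' @param seed fold-assignment seed.
#' @return a \linkS4class{VIPSelection} with strategy \code{"search"};
#'   \code{attr(, "candidates")} holds the full search log (set,
#'   provenance, size, r2, q2).
#' @export
searchBestSet <- function(selections, tensor, labels, H = 2L,
                          cvScheme = "kfold5", seed = 1L) {
  groups <- if (methods::is(tensor, "OmicsTensor")) tensor@design$pair_id
  X <- if (methods::is(tensor, "OmicsTensor")) tensor@values else tensor
  sets <- lapply(selections, function(s) s@selectedIds)
  names(sets) <- vapply(selections, function(s) s@strategy, character(1))
  sets <- sets[lengths(sets) > 0L]
  if (!length(sets)) stop("all candidate selections are empty")

  cand <- sets
  nm <- names(sets)
  if (length(sets) >= 2L) {
    combos <- c(utils::combn(seq_along(sets), 2L, simplify = FALSE),
                if (length(sets) >= 3L)
                  utils::combn(seq_along(sets), 3L, simplify = FALSE))
    for (cb in combos) {
      u <- sort(Reduce(union, sets[cb]))
      i <- sort(Reduce(intersect, sets[cb]))
      cand[[paste(nm[cb], collapse = " | ")]] <- u
      if (length(i)) cand[[paste(nm[cb], collapse = " & ")]] <- i
    }
  }
  # deduplicate identical sets, keep first provenance
  keys <- vapply(cand, function(s) paste(sort(s), collapse = ","), character(1))
  cand <- cand[!duplicated(keys)]
  cand <- cand[lengths(cand) > 0L]

  fids <- dimnames(X)[[2L]]
  log <- data.frame(provenance = names(cand), size = lengths(cand),
                    r2 = NA_real_, q2 = NA_real_)
  for (i in seq_along(cand)) {
    idx <- match(cand[[i]], fids)
    Xi <- X[, idx, , drop = FALSE]
    Hi <- min(H, length(idx))
    cv <- crossValidate(Xi, labels, H = Hi, scheme = cvScheme, seed = seed,
                        groups = groups)
    log$r2[i] <- cv$r2; log$q2[i] <- cv$q2
  }
  o <- order(-log$q2, -log$r2, log$size)
  best <- o[1L]

  vals <- stats::setNames(rep(NA_real_, length(cand[[best]])), cand[[best]])
  out <- new("VIPSelection", strategy = "search",
             vipValues = numeric(0), detail = data.frame(),
             percentile = NA_real_, selectedIds = cand[[best]],
             provenance = log$provenance[best],
             r2 = log$r2[best], q2 = log$q2[best])
  attr(out, "candidates") <- log
  out
}
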