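#' Fit a Tucker3 model by alternating least squares
#'
#' Decomposes a complete three-way array into a P x Q x R core and three
#' column-orthonormal loading matrices, maximizing the explained sum of
#' squares. The algorithm is higher-order orthogonal iteration: loadings
#' are initialized from the truncated SVD of each unfolding (HOSVD), then
#' each mode's loading is updated in turn as the leading singular vectors
#' of the data projected on the other two modes. The fit (fraction of
#' total SS captured by the core) is non-decreasing across sweeps; the
#' HOSVD start makes the result deterministic.
#'
#' @param X numeric three-way array with no missing values.
#' @param ranks integer vector (P, Q, R); each must not exceed the
#'   corresponding mode dimension, and each must not exceed the product of
#'   the other two (larger cores are not identifiable).
#' @param tol relative fit-change convergence threshold.
#' @param maxIter maximum number of ALS sweeps.
#' @return a \linkS4class{Tucker3Model}.
#' @examples
#' X <- array(rnorm(10 * 8 * 5), c(10, 8, 5))
#' m <- tucker3Fit(X, c(2, 2, 2))
#' m@fit
#' @export
tucker3Fit <- function(X, ranks, tol = 1e-8, maxIter = 200L) {
  d <- dim(X)
  if (length(d) != 3L) stop("X must be a 3-way array")
  if (anyNA(X)) stop("X must not contain missing values; impute first")
  ranks <- as.integer(ranks)
  if (length(ranks) != 3L || any(ranks < 1L)) stop("ranks must be 3 positive integers")
  if (any(ranks > d))
    stop(sprintf("rank (%s) exceeds a mode dimension (%s)",
                 paste(ranks, collapse = ","), paste(d, collapse = ",")))
  for (m in 1:3) if (ranks[m] > prod(ranks[-m]))
    stop("each rank must not exceed the product of the other two")
  totSS <- sumsq(X)
  if (totSS == 0) stop("zero tensor: fit undefined")

  A <- vector("list", 3L)
  for (m in 1:3) A[[m]] <- svd(unfoldTensor(X, m), nu = ranks[m], nv = 0)$u

  fit <- -Inf; it <- 0L; converged <- FALSE
  fitTrace <- numeric(0)
  repeat {
    it <- it + 1L
    for (m in 1:3) {
      others <- setdiff(1:3, m)
      W <- X
      for (o in others) W <- ttm(W, t(A[[o]]), o)
      A[[m]] <- svd(unfoldTensor(W, m), nu = ranks[m], nv = 0)$u
    }
    core <- ttm(ttm(ttm(X, t(A[[1L]]), 1L), t(A[[2L]]), 2L), t(A[[3L]]), 3L)
    newFit <- sumsq(core) / totSS
    fitTrace <- c(fitTrace, newFit)
    if (is.finite(fit) && newFit < fit - 1e-12)
      stop("internal error: ALS fit decreased")  # monotonicity guard
    if (is.finite(fit) && abs(newFit - fit) < tol * max(fit, .Machine$double.eps)) {
      converged <- TRUE; fit <- newFit; break
    }
    fit <- newFit
    if (it >= maxIter) break
  }

  out <- new("Tucker3Model", core = core, loadings = A, ranks = ranks,
             fit = min(fit, 1), nIterations = it, converged = converged)
  attr(out@fit, "trace") <- NULL
  attr(out, "fitTrace") <- fitTrace
  out
}

#' Reconstruct the fitted approximation of a Tucker3 model
#'
#' @param model a \linkS4class{Tucker3Model}.
#' @return the I x J x K array \code{core x1 A x2 B x3 C}.
#' @export
tucker3Reconstruct <- function(model) {
  ttm(ttm(ttm(model@core, model@loadings[[1L]], 1L),
          model@loadings[[2L]], 2L),
      model@loadings[[3L]], 3L)
}

#' Choose Tucker3 mode ranks by the DIFFIT procedure
#'
#' Fits Tucker3 models for every feasible rank triple (P, Q, R) with total
#' rank P+Q+R up to \code{maxTotalRank}, keeps the best fit per total rank
#' s, and computes the fit gains dif(s) = fit(s) - fit(s-1). The selected
#' total rank maximizes the gain ratio dif(s)/dif(s+1), i.e. the point
#' where adding components stops paying off; the returned triple is the
#' best-fitting one at that total rank. When every gain is below 1% of the
#' total SS the data support no structure beyond one component per mode
#' and (1, 1, 1) is returned; ties break toward the smaller total rank.
#'
#' @param X complete three-way array.
#' @param maxTotalRank largest P+Q+R explored (>= 3).
#' @param flatGain gains below this fraction of total SS count as flat.
#' @return list with \code{ranks} (the chosen triple), and the exploration
#'   \code{table} (P, Q, R, total, fit).
#' @export
diffitSelect <- function(X, maxTotalRank = 12L, flatGain = 0.01) {
  if (maxTotalRank < 3L) stop("maxTotalRank must be at least 3")
  d <- dim(X)
  triples <- expand.grid(P = seq_len(min(d[1], maxTotalRank)),
                         Q = seq_len(min(d[2], maxTotalRank)),
                         R = seq_len(min(d[3], maxTotalRank)))
  triples <- triples[rowSums(triples) <= maxTotalRank, , drop = FALSE]
  ok <- with(triples, P <= Q * R & Q <= P * R & R <= P * Q)
  triples <- triples[ok, , drop = FALSE]
  fits <- vapply(seq_len(nrow(triples)), function(i) {
    tucker3Fit(X, unlist(triples[i, ]))@fit
  }, numeric(1))
  tab <- cbind(triples, total = rowSums(triples), fit = fits)

  totals <- sort(unique(tab$total))
  best <- vapply(totals, function(s) max(tab$fit[tab$total == s]), numeric(1))
  # monotone envelope: a larger budget can always do at least as well
  best <- cummax(best)
  if (length(totals) < 2L) return(list(ranks = c(1L, 1L, 1L), table = tab))

  dif <- diff(best)                      # dif[i] = gain going to totals[i+1]
  if (all(dif < flatGain)) {
    sel <- totals[1L]
  } else {
    # ratio dif(s)/dif(s+1) for interior totals; guard zero denominators
    ratio <- dif[-length(dif)] / pmax(dif[-1L], .Machine$double.eps)
    ratio[dif[-length(dif)] < flatGain] <- -Inf  # flat gains never win
    if (all(!is.finite(ratio)) || length(ratio) == 0L) {
      sel <- totals[1L + which(dif >= flatGain)[1L]]
    } else {
      sel <- totals[1L + which.max(ratio)]       # ties -> smaller total
    }
  }
  sub <- tab[tab$total == sel, , drop = FALSE]
  w <- which.max(sub$fit)
  list(ranks = as.integer(unlist(sub[w, c("P", "Q", "R")])), table = tab)
}

#' Impute missing tensor cells with an iterative Tucker3 model
#'
#' Missing cells are first filled with the mean of the observed values.
#' A Tucker3 model is then fitted to the completed array and the filled
#' cells are replaced by the model's reconstruction; the fill-fit-replace
#' cycle repeats until the relative change in the sum of squared
#' differences of the imputed cells between successive iterations drops
#' below \code{tol} (default 1e-7). Observed cells are never altered, and
#' the returned mask marks imputed cells as unobserved.
#'
#' @param tensor an \linkS4class{OmicsTensor} whose mask flags missing
#'   cells, or a plain array paired with \code{mask}.
#' @param ranks Tucker3 ranks; \code{"diffit"} (default) selects them by
#'   [diffitSelect()] on the mean-filled array.
#' @param tol convergence threshold on the relative movement of imputed
#'   values.
#' @param maxIter maximum fill-fit-replace cycles.
#' @param mask logical array when \code{tensor} is a plain array.
#' @param criterion \code{"imputed"} (default) tracks the movement of the
#'   imputed cells; \code{"observed"} tracks the relative change in
#'   reconstruction error on observed cells instead.
#' @return list with \code{tensor} (filled; same class as the input) and
#'   \code{report} (n_imputed_cells, fraction_imputed, iterations,
#'   final_change, converged, ranks).
#' @export
imputeMissing <- function(tensor, ranks = "diffit", tol = 1e-7,
                          maxIter = 100L, mask = NULL,
                          criterion = c("imputed", "observed")) {
  criterion <- match.arg(criterion)
  isOT <- methods::is(tensor, "OmicsTensor")
  X <- if (isOT) tensor@values else tensor
  M <- if (isOT) tensor@mask else mask
  if (is.null(M)) stop("a mask is required")
  miss <- !M | is.na(X)
  nMiss <- sum(miss)
  report <- list(n_imputed_cells = nMiss,
                 fraction_imputed = nMiss / length(X),
                 iterations = 0L, final_change = 0, converged = TRUE,
                 ranks = NA)
  if (nMiss == 0L) {
    return(list(tensor = tensor, report = report))
  }
  if (nMiss == length(X)) stop("all cells missing: nothing to anchor imputation")

  Xf <- X
  Xf[miss] <- mean(X[!miss])
  if (identical(ranks, "diffit")) ranks <- diffitSelect(Xf)$ranks
  report$ranks <- as.integer(ranks)

  prevImp <- Xf[miss]
  prevObsErr <- NULL
  converged <- FALSE; it <- 0L; change <- Inf
  while (it < maxIter) {
    it <- it + 1L
    fitm <- tucker3Fit(Xf, ranks)
    Xhat <- tucker3Reconstruct(fitm)
    Xf[miss] <- Xhat[miss]
    if (criterion == "imputed") {
      num <- sumsq(Xf[miss] - prevImp)
      den <- max(sumsq(prevImp), .Machine$double.eps)
      change <- num / den
      prevImp <- Xf[miss]
    } else {
      obsErr <- sumsq(Xhat[!miss] - X[!miss])
      change <- if (is.null(prevObsErr)) Inf else
        abs(obsErr - prevObsErr) / max(prevObsErr, .Machine$double.eps)
      prevObsErr <- obsErr
    }
    if (change < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("imputation did not converge in %d iterations (last change %.3g)",
                    maxIter, change))
  report$iterations <- it
  report$final_change <- change
  report$converged <- converged

  stopifnot(identical(Xf[!miss], X[!miss]))  # observed cells untouched
  if (isOT) {
    out <- tensor
    out@values <- Xf
    out@mask <- M & !is.na(X)   # imputed cells stay flagged unobserved
    list(tensor = out, report = report)
  } else {
    list(tensor = Xf, report = report)
  }
}
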