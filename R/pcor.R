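#' Consecutive-timepoint difference profiles
#'
#' Disease-progression profiles: per subject and feature, the value at
#' the later timepoint (closer to the event) minus the value at the
#' earlier one, for each of the four windows a five-timepoint grid
#' yields (12to9, 9to6, 6to3, 3to0 MBSC). By default only case
#' subjects' normalized values enter, since the within-normalization
#' makes case values the signed case-control divergence.
#'
#' @param tensor normalized, imputed \linkS4class{OmicsTensor}.
#' @param subjects \code{"cases"} (default), \code{"controls"}, or
#'   \code{"all"}.
#' @param featureIds signature to restrict to (default: all features).
#' @return named list of windows; each has \code{label}, \code{delta}
#'   (subjects x features matrix), \code{from}/\code{to} (MBSC labels),
#'   and \code{labels} (case/control of the retained subjects).
#' @export
deltaProfiles <- function(tensor, subjects = c("cases", "controls", "all"),
                          featureIds = NULL) {
  subjects <- match.arg(subjects)
  tp <- timePoints(tensor)
  if (length(tp) < 5L) stop("delta profiles need the full 5-timepoint grid")
  des <- tensorDesign(tensor)
  keep <- switch(subjects,
                 cases = which(des$role == "case"),
                 controls = which(des$role == "control"),
                 all = seq_len(nrow(des)))
  fids <- featureIds %||% dimnames(tensor@values)[[2L]]
  idx <- match(fids, dimnames(tensor@values)[[2L]])
  if (anyNA(idx)) stop("unknown feature ids in the requested signature")

  out <- list()
  for (k in seq_len(length(tp) - 1L)) {
    lab <- sprintf("%gto%g", tp[k], tp[k + 1L])
    later <- tensor@values[keep, idx, k + 1L, drop = FALSE]  # closer to event
    earlier <- tensor@values[keep, idx, k, drop = FALSE]
    delta <- matrix(later - earlier, nrow = length(keep),
                    dimnames = list(subjectIds(tensor)[keep], fids))
    flagged <- !(tensor@mask[keep, idx, k, drop = FALSE] &
                   tensor@mask[keep, idx, k + 1L, drop = FALSE])
    out[[lab]] <- list(label = lab, delta = delta,
                       from = tp[k], to = tp[k + 1L],
                       labels = des$role[keep],
                       imputed_flag = matrix(flagged, nrow = length(keep)))
  }
  out
}

#' Elastic-net stability selection of high-variability features
#'
#' Two-stage bootstrap procedure per time window: first, for each alpha
#' on the ridge-to-lasso grid, \code{nTune} bootstrap fits are scored by
#' out-of-bag deviance and the alpha with the best mean deviance wins;
#' second, \code{nFinal} bootstrap fits at the winning alpha collect
#' every feature whose coefficient is nonzero in at least one fit. The
#' response is the case/control outcome (logistic loss) by default, or
#' the window's first principal component (linear loss) in unsupervised
#' mode.
#'
#' @param window one window from [deltaProfiles()] (needs both classes
#'   present for the outcome response, so build the profiles with
#'   \code{subjects = "all"}).
#' @param response \code{"outcome"} (default) or \code{"pc1"}.
#' @param alphaGrid elastic-net mixing values to scan.
#' @param nTune bootstrap fits per alpha in the tuning stage.
#' @param nFinal bootstrap fits at the winning alpha.
#' @param seed integer seed; identical seeds give identical selections.
#' @return list with \code{selected} (feature ids), \code{alpha} (the
#'   winning mixing value), and \code{n_appearances} (per-feature count
#'   of nonzero coefficients over the final fits).
#' @export
elasticNetSelect <- function(window, response = c("outcome", "pc1"),
                             alphaGrid = seq(0, 1, by = 0.1),
                             nTune = 100L, nFinal = 1000L, seed = 1L) {
  response <- match.arg(response)
  X <- window$delta
  keepF <- apply(X, 2L, function(x) stats::sd(x) > 0)
  if (!all(keepF)) {
    warning(sprintf("dropping %d all-constant feature(s) before fitting",
                    sum(!keepF)))
    X <- X[, keepF, drop = FALSE]
  }
  if (ncol(X) < 2L) stop("need at least 2 variable features")
  n <- nrow(X)

  if (response == "outcome") {
    y <- factor(window$labels, levels = sort(unique(window$labels)))
    if (nlevels(y) < 2L)
      stop("outcome response needs both classes in the window; ",
           "build delta profiles with subjects = 'all'")
    family <- "binomial"
    yNum <- as.integer(y) - 1L
  } else {
    y <- stats::prcomp(X, center = TRUE, scale. = FALSE)$x[, 1L]
    family <- "gaussian"
    yNum <- y
  }

  rng <- .seedStream(seed)
  oob <- function(alpha, nBoot) {
    devs <- numeric(nBoot)
    for (b in seq_len(nBoot)) {
      set.seed(rng())
      idx <- sample(n, n, replace = TRUE)
      out <- setdiff(seq_len(n), unique(idx))
      if (length(out) < 2L ||
          (family == "binomial" && length(unique(yNum[idx])) < 2L)) {
        devs[b] <- NA_real_; next
      }
      fit <- glmnet::glmnet(X[idx, , drop = FALSE], yNum[idx],
                            family = family, alpha = alpha, nlambda = 30)
      eta <- stats::predict(fit, X[out, , drop = FALSE])
      devPath <- if (family == "binomial") {
        p <- 1 / (1 + exp(-eta))
        p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
        -2 * colMeans(yNum[out] * log(p) + (1 - yNum[out]) * log(1 - p))
      } else colMeans((yNum[out] - eta)^2)
      devs[b] <- min(devPath)   # each alpha judged at its best penalty
    }
    mean(devs, na.rm = TRUE)
  }

  tuneDev <- vapply(alphaGrid, oob, numeric(1), nBoot = nTune)
  alphaWin <- alphaGrid[which.min(tuneDev)]

  # fix the penalty for the final stage by cross-validation on the full
  # window at the winning alpha (lasso alpha 0 excluded from zero checks
  # is irrelevant here: ridge never zeroes, so alpha 0 selects everything)
  set.seed(rng())
  lamFinal <- tryCatch(
    glmnet::cv.glmnet(X, yNum, family = family, alpha = alphaWin,
                      nfolds = 5)$lambda.min,
    error = function(e) NULL)
  counts <- stats::setNames(integer(ncol(X)), colnames(X))
  for (b in seq_len(nFinal)) {
    set.seed(rng())
    idx <- sample(n, n, replace = TRUE)
    if (family == "binomial" && length(unique(yNum[idx])) < 2L) next
    fit <- glmnet::glmnet(X[idx, , drop = FALSE], yNum[idx],
                          family = family, alpha = alphaWin, nlambda = 30)
    lam <- lamFinal %||% fit$lambda[max(1L, floor(length(fit$lambda) / 2))]
    cf <- stats::coef(fit, s = lam)
    nz <- rownames(cf)[as.vector(cf != 0)]
    nz <- setdiff(nz, "(Intercept)")
    counts[nz] <- counts[nz] + 1L
  }
  list(selected = names(counts)[counts > 0L], alpha = alphaWin,
       n_appearances = counts)
}

#' Full-order partial correlations
#'
#' The partial correlation between every pair of variables controlling
#' for all others, computed from the precision matrix:
#' \code{pcor(i, j) = -P[i, j] / sqrt(P[i, i] * P[j, j])} with unit
#' diagonal. When the sample size does not comfortably exceed the
#' variable count (n <= p + 10) the covariance is first shrunk toward
#' its diagonal with an analytic intensity, otherwise the sample
#' covariance is inverted directly.
#'
#' @param X subjects x features matrix (>= 4 rows, >= 3 columns).
#' @param shrink force shrinkage on (\code{TRUE}) or off (\code{FALSE});
#'   default \code{NULL} applies the n vs p rule above.
#' @return symmetric features x features matrix with unit diagonal;
#'   \code{attr(, "lambda")} records the shrinkage intensity used (0 for
#'   the unregularized route).
#' @export
partialCorrelations <- function(X, shrink = NULL) {
  n <- nrow(X); p <- ncol(X)
  if (p < 3L) stop("need at least 3 features")
  if (n < 4L) stop("need at least 4 subjects")
  cc <- suppressWarnings(stats::cor(X))
  diag(cc) <- 0
  if (any(abs(cc) > 1 - 1e-12, na.rm = TRUE)) {
    w <- which(abs(cc) > 1 - 1e-12, arr.ind = TRUE)[1L, ]
    stop(sprintf("features '%s' and '%s' are perfectly collinear",
                 colnames(X)[w[1L]] %||% w[1L], colnames(X)[w[2L]] %||% w[2L]))
  }
  useShrink <- shrink %||% (n <= p + 10L)
  if (useShrink) {
    Sig <- shrinkCovariance(X)
    lambda <- attr(Sig, "lambda")
  } else {
    Xc <- scale(X, center = TRUE, scale = FALSE)
    Sig <- crossprod(Xc) / (n - 1)
    lambda <- 0
  }
  P <- tryCatch(solve(Sig), error = function(e)
    stop("covariance inversion failed: ", conditionMessage(e)))
  D <- sqrt(diag(P))
  R <- -P / tcrossprod(D)
  diag(R) <- 1
  R <- (R + t(R)) / 2
  dimnames(R) <- list(colnames(X), colnames(X))
  attr(R, "lambda") <- lambda
  R
}

#' Threshold a partial-correlation matrix into a network
#'
#' Keeps edges whose absolute partial correlation exceeds the threshold
#' (0.7 by convention). Nodes are annotated with their molecule kind
#' (gene / metabolite / vitamin — drawn as circles, triangles, and
#' squares downstream), the mean normalized case value at the window's
#' first timepoint, and a direction flag (up in cases when positive).
#' Isolated nodes are retained and flagged.
#'
#' @param pcor symmetric partial-correlation matrix.
#' @param nodeMeta data.frame with \code{feature_id}, \code{kind}, and
#'   \code{mean_case} (mean normalized case value at the window's first
#'   timepoint); defaults fill in \code{"unknown"} kinds and NA means.
#' @param threshold absolute partial-correlation cut (default 0.7).
#' @param window window label carried through to the result.
#' @return a \linkS4class{PcorNetwork}.
#' @export
buildNetwork <- function(pcor, nodeMeta = NULL, threshold = 0.7,
                         window = "window") {
  stopifnot(is.matrix(pcor), nrow(pcor) == ncol(pcor))
  if (max(abs(pcor - t(pcor))) > 1e-8) stop("pcor must be symmetric")
  ids <- colnames(pcor) %||% as.character(seq_len(ncol(pcor)))
  if (is.null(nodeMeta))
    nodeMeta <- data.frame(feature_id = ids, kind = "unknown",
                           mean_case = NA_real_)
  nodeMeta <- nodeMeta[match(ids, nodeMeta$feature_id), , drop = FALSE]
  nodeMeta$feature_id <- ids

  ut <- which(upper.tri(pcor) & abs(pcor) > threshold, arr.ind = TRUE)
  edges <- data.frame(from = ids[ut[, 1L]], to = ids[ut[, 2L]],
                      pcor = pcor[ut],
                      sign = ifelse(pcor[ut] >= 0, "positive", "negative"))
  connected <- unique(c(edges$from, edges$to))
  nodes <- data.frame(feature_id = ids,
                      kind = nodeMeta$kind,
                      mean_case = nodeMeta$mean_case,
                      direction = ifelse(is.na(nodeMeta$mean_case), NA,
                                         ifelse(nodeMeta$mean_case >= 0,
                                                "up", "down")),
                      isolated = !(ids %in% connected))
  new("PcorNetwork", window = window, nodes = nodes, edges = edges,
      threshold = threshold, pcor = pcor)
}

#' Compare window-wise partial-correlation distributions
#'
#' Excess kurtosis (normal = 0; negative = platykurtic, positive =
#' leptokurtic) of each window's off-diagonal partial-correlation
#' values, and a two-sample Kolmogorov-Smirnov test between each pair
#' of consecutive windows.
#'
#' @param pcorValues named list (one entry per window, chronological
#'   order) of numeric vectors — typically the upper-triangle values of
#'   each window's partial-correlation matrix.
#' @return list with \code{kurtosis} (data.frame window / n /
#'   excess_kurtosis / shape) and \code{ks} (data.frame window_a /
#'   window_b / ks_stat / ks_p).
#' @export
compareWindows <- function(pcorValues) {
  if (length(pcorValues) < 2L) stop("need at least 2 windows to compare")
  if (any(lengths(pcorValues) < 20L))
    stop("each window needs at least 20 correlation values")
  kurt <- function(x) {
    x <- x - mean(x)
    length(x) * sum(x^4) / sum(x^2)^2 - 3
  }
  kt <- data.frame(window = names(pcorValues),
                   n = lengths(pcorValues),
                   excess_kurtosis = vapply(pcorValues, kurt, numeric(1)))
  kt$shape <- ifelse(kt$excess_kurtosis < 0, "platykurtic", "leptokurtic")
  ks <- list()
  for (i in seq_len(length(pcorValues) - 1L)) {
    tst <- suppressWarnings(stats::ks.test(pcorValues[[i]],
                                           pcorValues[[i + 1L]]))
    ks[[i]] <- data.frame(window_a = names(pcorValues)[i],
                          window_b = names(pcorValues)[i + 1L],
                          ks_stat = unname(tst$statistic),
                          ks_p = tst$p.value)
  }
  list(kurtosis = kt, ks = do.call(rbind, ks))
}

#' Export a network as GraphML and SIF with node attributes
#'
#' @param network a \linkS4class{PcorNetwork}.
#' @param dir output directory.
#' @return named paths of the written \code{.graphml}, \code{.sif}, and
#'   node-attribute \code{.tsv} files.
#' @export
exportNetwork <- function(network, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, paste0("network_", network@window))
  paths <- c(graphml = paste0(base, ".graphml"),
             sif = paste0(base, ".sif"),
             nodes = paste0(base, "_nodes.tsv"))
  g <- igraph::graph_from_data_frame(
    network@edges[, c("from", "to", "pcor", "sign")],
    directed = FALSE,
    vertices = network@nodes[, c("feature_id", "kind", "mean_case",
                                 "direction", "isolated")])
  igraph::write_graph(g, paths[["graphml"]], format = "graphml")
  sif <- if (nrow(network@edges))
    data.frame(a = network@edges$from, rel = network@edges$sign,
               b = network@edges$to)
  else data.frame(a = character(0), rel = character(0), b = character(0))
  data.table::fwrite(sif, paths[["sif"]], sep = "\t", col.names = FALSE)
  data.table::fwrite(network@nodes, paths[["nodes"]], sep = "\t")
  paths
}
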