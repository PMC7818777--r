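#' Read gene sets from a GMT file
#'
#' Standard tab-delimited gene-set format: one set per line, first field
#' the set name, second a description, remaining fields the member ids.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("missing GMT file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    unique(f[-(1:2)][nzchar(f[-(1:2)])])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1))
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeGMT <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Gene-set enrichment from per-timepoint VIP rankings
#'
#' Competitive enrichment by gene-label permutation: per gene set and
#' timepoint the observed statistic is the sum (and the mean) of the
#' member genes' VIP-derived ranking values; the null redraws member
#' labels uniformly from the ranked universe \code{nPerm} times. The
#' permutation p-value uses the conservative (1 + more-extreme) /
#' (nPerm + 1) estimator, and the retained p per set/timepoint is the
#' smaller of the sum-statistic and mean-statistic p-values.
#'
#' @param vipByTimepoint numeric matrix, genes x timepoints, of VIP (or
#'   other ranking) values with gene row names.
#' @param geneSets named list of member id vectors (see [readGMT()]).
#' @param nPerm permutations (>= 100).
#' @param seed integer seed.
#' @return data.frame: set, timepoint, n_members (overlap with the
#'   universe), p (NA for sets with no overlap, with a warning).
#' @export
gseaByVIP <- function(vipByTimepoint, geneSets, nPerm = 10000L, seed = 1L) {
  if (nPerm < 100L) stop("nPerm must be at least 100")
  genes <- rownames(vipByTimepoint)
  if (is.null(genes)) stop("vipByTimepoint needs gene row names")
  tps <- colnames(vipByTimepoint) %||% as.character(seq_len(ncol(vipByTimepoint)))

  rows <- list()
  noOverlap <- character(0)
  for (sn in names(geneSets)) {
    members <- intersect(geneSets[[sn]], genes)
    m <- length(members)
    if (m == 0L) {
      noOverlap <- c(noOverlap, sn)
      for (k in seq_along(tps))
        rows[[length(rows) + 1L]] <- data.frame(
          set = sn, timepoint = tps[k], n_members = 0L, p = NA_real_)
      next
    }
    for (k in seq_along(tps)) {
      v <- vipByTimepoint[, k]
      obsSum <- sum(v[members])
      set.seed((seed + match(sn, names(geneSets)) * 131L + k) %% 2147483647L)
      nullSum <- vapply(seq_len(nPerm), function(i) sum(v[sample(length(v), m)]),
                        numeric(1))
      pSum <- (1 + sum(nullSum >= obsSum)) / (nPerm + 1)
      # mean statistic shares the null draws: mean = sum / m on both sides
      pMean <- (1 + sum(nullSum / m >= obsSum / m)) / (nPerm + 1)
      rows[[length(rows) + 1L]] <- data.frame(
        set = sn, timepoint = tps[k], n_members = m,
        p = min(pSum, pMean))
    }
  }
  if (length(noOverlap))
    warning("gene set(s) with no overlap with the universe: ",
            paste(noOverlap, collapse = ", "))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Combine per-timepoint p-values with Fisher's method
#'
#' For every non-empty subset of timepoints, the combined statistic is
#' \code{X2 = -2 * sum(log(p))} with \code{2 * |subset|} degrees of
#' freedom; the combined p is the chi-square upper tail. Benjamini-
#' Hochberg correction is applied across sets within each combination,
#' and a set is flagged selected when its adjusted p is <= 0.05 in at
#' least one combination. A single-timepoint "combination" reproduces
#' the input p exactly.
#'
#' @param enrichment data.frame from [gseaByVIP()] (columns set,
#'   timepoint, p) or any per-set per-timepoint p table.
#' @param alpha selection level on the adjusted p (default 0.05).
#' @param maxComboSize optional cap on the subset size for large grids.
#' @param pFloor values of exactly 0 are clipped here, with a warning.
#' @return list with \code{combinations} (data.frame set / combination /
#'   df / fisher_p / adj_p) and \code{selected} (data.frame set /
#'   selected flag / best adjusted p).
#' @export
fisherCombine <- function(enrichment, alpha = 0.05, maxComboSize = Inf,
                          pFloor = 1e-16) {
  stopifnot(all(c("set", "timepoint", "p") %in% names(enrichment)))
  enr <- enrichment[!is.na(enrichment$p), , drop = FALSE]
  if (any(enr$p <= 0)) {
    warning("p values of 0 clipped to the floor ", pFloor)
    enr$p[enr$p <= 0] <- pFloor
  }
  if (any(enr$p > 1)) stop("p values must lie in (0, 1]")
  tps <- unique(enr$timepoint)
  combos <- list()
  for (sz in seq_len(min(length(tps), maxComboSize)))
    combos <- c(combos, utils::combn(tps, sz, simplify = FALSE))

  rows <- list()
  for (cb in combos) {
    lab <- paste(cb, collapse = "+")
    sub <- enr[enr$timepoint %in% cb, , drop = FALSE]
    agg <- tapply(sub$p, sub$set, function(p) {
      if (length(p) < length(cb)) return(NA_real_)
      stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
    })
    rows[[lab]] <- data.frame(set = names(agg), combination = lab,
                              df = 2L * length(cb),
                              fisher_p = as.vector(agg))
  }
  comb <- do.call(rbind, rows)
  rownames(comb) <- NULL
  comb$adj_p <- NA_real_
  for (lab in unique(comb$combination)) {
    i <- comb$combination == lab & !is.na(comb$fisher_p)
    comb$adj_p[i] <- stats::p.adjust(comb$fisher_p[i], method = "BH")
  }
  best <- tapply(comb$adj_p, comb$set, function(x)
    if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))
  selected <- data.frame(set = names(best),
                         best_adj_p = as.vector(best),
                         selected = !is.na(best) & best <= alpha)
  rownames(selected) <- NULL
  list(combinations = comb, selected = selected)
}

#' Signed pathway score
#'
#' \code{(1 - p)} signed by the mean value of the significant member
#' genes: positive when the pathway's significant genes are on average
#' up in cases, negative when down, and 0 when no member is significant.
#'
#' @param p enrichment p-value in (0, 1].
#' @param memberValues values (e.g. mean normalized case expression) of
#'   the set's significant member genes; empty vector means none were
#'   significant.
#' @return a number in [-1, 1].
#' @export
signedScore <- function(p, memberValues) {
  if (is.na(p) || p <= 0 || p > 1) stop("p must lie in (0, 1]")
  if (!length(memberValues)) return(0)
  (1 - p) * sign(mean(memberValues))
}

#' Metabolite-class enrichment from per-metabolite t-tests
#'
#' Per timepoint, each metabolite is tested for case-control
#' differential abundance (paired t-test within case-control sets when
#' the pairing is complete, Welch otherwise) and flagged significant at
#' p < \code{alpha}. Per class, a 2x2 Fisher exact test (in-class vs
#' out-of-class by significant vs not) measures over-representation of
#' significant metabolites; BH correction runs across classes within
#' each timepoint and classes are kept at adjusted p <= \code{fdr} with
#' a direction annotation (sign of the mean case-control difference
#' among the class's significant members).
#'
#' @param tensor \linkS4class{OmicsTensor} of the metabolomics block
#'   (raw or normalized values; cases and controls are compared
#'   directly).
#' @param classMap data.frame with \code{metabolite_id}, \code{class};
#'   each metabolite maps to at most one class.
#' @param alpha per-metabolite significance level (default 0.05).
#' @param fdr class-level adjusted-p cut (default 0.2).
#' @return data.frame: timepoint, class, n_class, n_significant,
#'   odds_ratio, fisher_p, adj_p, direction, enriched.
#' @export
metaboliteClassEnrichment <- function(tensor, classMap, alpha = 0.05,
                                      fdr = 0.2) {
  if (anyDuplicated(classMap$metabolite_id))
    stop("each metabolite must map to at most one class")
  des <- tensorDesign(tensor)
  fids <- featureIds(tensor)
  tp <- timePoints(tensor)
  caseRows <- which(des$role == "case")
  ctlRows <- which(des$role == "control")
  if (length(caseRows) < 2L || length(ctlRows) < 2L)
    stop("need at least 2 subjects per group")
  cls <- classMap$class[match(fids, classMap$metabolite_id)]

  rows <- list()
  for (k in seq_along(tp)) {
    V <- tensor@values[, , k]
    # per-set case and mean-control values for the paired test
    pairIds <- unique(des$pair_id)
    caseV <- matrix(NA_real_, length(pairIds), length(fids))
    ctlV <- matrix(NA_real_, length(pairIds), length(fids))
    for (i in seq_along(pairIds)) {
      r <- which(des$pair_id == pairIds[i])
      cr <- r[des$role[r] == "case"]
      kr <- r[des$role[r] == "control"]
      if (length(cr) == 1L) caseV[i, ] <- V[cr, ]
      if (length(kr) >= 1L)
        ctlV[i, ] <- colMeans(V[kr, , drop = FALSE], na.rm = TRUE)
    }
    paired <- !apply(is.na(caseV) | is.na(ctlV), 1L, any)
    pvals <- numeric(length(fids)); delta <- numeric(length(fids))
    for (j in seq_along(fids)) {
      if (sum(paired) >= 3L) {
        tt <- stats::t.test(caseV[paired, j], ctlV[paired, j], paired = TRUE)
      } else {
        tt <- stats::t.test(V[caseRows, j], V[ctlRows, j])
      }
      pvals[j] <- tt$p.value
      delta[j] <- mean(caseV[paired, j] - ctlV[paired, j], na.rm = TRUE)
    }
    sig <- pvals < alpha

    for (cl in unique(stats::na.omit(cls))) {
      inClass <- !is.na(cls) & cls == cl
      nClass <- sum(inClass)
      if (nClass < 2L) {
        warning("class '", cl, "' has fewer than 2 members; skipped")
        next
      }
      if (nClass == length(fids)) {
        warning("class '", cl, "' spans the whole universe; skipped")
        next
      }
      tab <- matrix(c(sum(inClass & sig), sum(inClass & !sig),
                      sum(!inClass & sig), sum(!inClass & !sig)), 2L, 2L)
      ft <- stats::fisher.test(tab, alternative = "greater")
      orNum <- tab[1, 1] * tab[2, 2]
      orDen <- tab[2, 1] * tab[1, 2]
      direction <- if (sum(inClass & sig))
        ifelse(mean(delta[inClass & sig]) >= 0, "up", "down") else NA_character_
      rows[[length(rows) + 1L]] <- data.frame(
        timepoint = tp[k], class = cl, n_class = nClass,
        n_significant = sum(inClass & sig),
        odds_ratio = if (orDen > 0) orNum / orDen else Inf,
        fisher_p = ft$p.value, direction = direction)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out$adj_p <- NA_real_
  for (k in unique(out$timepoint)) {
    i <- out$timepoint == k
    out$adj_p[i] <- stats::p.adjust(out$fisher_p[i], method = "BH")
  }
  out$enriched <- out$adj_p <= fdr
  rownames(out) <- NULL
  out[, c("timepoint", "class", "n_class", "n_significant", "odds_ratio",
          "fisher_p", "adj_p", "direction", "enriched")]
}
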