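#' Default 3-month bin specification
#'
#' Maps months-before-seroconversion (MBSC) onto the five visit bins
#' labelled 0, 3, 6, 9, 12: the intervals are [1, 1.5), [1.5, 4.5),
#' [4.5, 7.5), [7.5, 10.5), and [10.5, 13.5], closed on the left and
#' open on the right except for the last bin, which keeps its upper
#' boundary so 13.5 is retained. Measurements below 1 MBSC or above 13.5
#' fall outside every bin and are dropped.
#'
#' @return data.frame with columns \code{label} (MBSC bin label,
#'   descending 12..0), \code{lower}, \code{upper}.
#' @export
defaultBinSpec <- function() {
  data.frame(label = c(12, 9, 6, 3, 0),
             lower = c(10.5, 7.5, 4.5, 1.5, 1.0),
             upper = c(13.5, 10.5, 7.5, 4.5, 1.5))
}

.checkBinSpec <- function(binSpec) {
  stopifnot(all(c("label", "lower", "upper") %in% names(binSpec)))
  o <- order(binSpec$lower)
  lo <- binSpec$lower[o]; up <- binSpec$upper[o]
  if (any(up <= lo)) stop("bin intervals must have upper > lower")
  if (any(lo[-1L] < up[-length(up)])) stop("bin intervals overlap")
  invisible(binSpec)
}

#' Bin long-format measurements into a three-way tensor
#'
#' Assigns each measurement of one omics block to the unique MBSC bin
#' containing it, averages multiple values from the same subject and
#' feature inside a bin, and arranges the result as a subjects x
#' features x timepoints \linkS4class{OmicsTensor}. Cells with no
#' measurement are NA with mask FALSE. Out-of-range measurements are
#' dropped and counted (see \code{attr(, "n_excluded")}).
#'
#' @param measurements long data.frame (columns subject_id, pair_id,
#'   role, block, feature_id, months_before_sc, value), restricted to or
#'   filtered by \code{block}.
#' @param block block name to extract.
#' @param binSpec bin table as from [defaultBinSpec()].
#' @return an \linkS4class{OmicsTensor}; attribute \code{n_excluded}
#'   counts dropped out-of-range measurements.
#' @export
binToTensor <- function(measurements, block, binSpec = defaultBinSpec()) {
  .checkBinSpec(binSpec)
  m <- measurements[measurements$block == block, , drop = FALSE]
  if (nrow(m) == 0L) stop("no measurements for block '", block, "'")

  lastBin <- which.max(binSpec$upper)
  assign <- rep(NA_integer_, nrow(m))
  for (b in seq_len(nrow(binSpec))) {
    inb <- m$months_before_sc >= binSpec$lower[b] &
      (m$months_before_sc < binSpec$upper[b] |
         (b == lastBin & m$months_before_sc == binSpec$upper[b]))
    assign[inb] <- b
  }
  nExcluded <- sum(is.na(assign))
  if (nExcluded == nrow(m))
    stop("all measurements fall outside the bin specification: empty tensor")
  if (nExcluded > 0L)
    message(sprintf("binToTensor: excluded %d out-of-range measurement(s)", nExcluded))
  m <- m[!is.na(assign), , drop = FALSE]
  assign <- assign[!is.na(assign)]

  tpOrder <- order(-binSpec$label)
  tp <- binSpec$label[tpOrder]
  binPos <- match(assign, tpOrder)    # column in descending-MBSC order

  subjects <- unique(m$subject_id)
  features <- sort(unique(m$feature_id))
  dt <- data.table::data.table(
    i = match(m$subject_id, subjects),
    j = match(m$feature_id, features),
    k = binPos, value = m$value)
  agg <- dt[, list(value = mean(value), n = .N), by = c("i", "j", "k")]

  vals <- array(NA_real_, c(length(subjects), length(features), length(tp)),
                dimnames = list(subjects, features, as.character(tp)))
  vals[cbind(agg$i, agg$j, agg$k)] <- agg$value
  mask <- !is.na(vals)

  des <- unique(m[, c("subject_id", "pair_id", "role")])
  des <- des[match(subjects, des$subject_id), , drop = FALSE]
  rownames(des) <- NULL

  out <- new("OmicsTensor", values = vals, mask = mask, block = block,
             timePoints = tp, design = des)
  attr(out, "n_excluded") <- nExcluded
  out
}

#' Split subjects into analysis and validation sets by completeness
#'
#' A subject counts as observed at a timepoint when any feature is
#' observed there. Subjects with at least \code{minObserved} observed
#' timepoints are eligible for analysis; the rest go to the validation
#' pool. Filtering is pair-joint: when a case or any of its matched
#' controls fails the filter, the whole case-control set moves to
#' validation, so the analysis tensor always holds complete sets.
#'
#' @param tensor an \linkS4class{OmicsTensor}.
#' @param minObserved minimum observed timepoints (default 3 of 5).
#' @return list with \code{analysis} and \code{validation} tensors
#'   (\code{validation} is NULL when empty).
#' @export
filterAndSplit <- function(tensor, minObserved = 3L) {
  m <- tensor@mask
  obsTp <- apply(m, c(1L, 3L), any)
  nObs <- rowSums(obsTp)
  pass <- nObs >= minObserved
  des <- tensor@design
  badPairs <- unique(des$pair_id[!pass])
  keep <- !(des$pair_id %in% badPairs)
  if (!any(keep)) stop("no complete case-control sets pass the completeness filter")
  list(analysis = .subsetSubjects(tensor, which(keep)),
       validation = if (all(keep)) NULL else
         .subsetSubjects(tensor, which(!keep)))
}

.subsetSubjects <- function(tensor, idx) {
  v <- tensor@values[idx, , , drop = FALSE]
  m <- tensor@mask[idx, , , drop = FALSE]
  des <- tensor@design[idx, , drop = FALSE]
  rownames(des) <- NULL
  new("OmicsTensor", values = v, mask = m, block = tensor@block,
      timePoints = tensor@timePoints, design = des)
}

#' Case-control within-normalization
#'
#' For each case-control set, feature, and timepoint the set mean is
#' subtracted from every member's value. With one control the set mean
#' is (case + control) / 2; with several controls the mean control value
#' is computed first and then averaged with the case value, so the case
#' and the control pool weigh equally. Large absolute values therefore
#' flag cases diverging from their controls, while near-zero values mean
#' the set agrees. When some members are unobserved the mean uses the
#' available members of each side; a cell whose set has only one
#' observed member (or is missing a whole side) is set missing, to be
#' imputed, and a warning is raised.
#'
#' @param tensor an \linkS4class{OmicsTensor} (usually post-imputation,
#'   in which case no cell is missing).
#' @return the normalized \linkS4class{OmicsTensor}.
#' @export
withinNormalize <- function(tensor) {
  v <- tensor@values
  # availability = a value is present (observed or imputed); the mask
  # keeps tracking provenance and is intersected back in at the end
  m <- !is.na(v)
  des <- tensor@design
  out <- v
  dropped <- 0L
  for (pid in unique(des$pair_id)) {
    rows <- which(des$pair_id == pid)
    caseRow <- rows[des$role[rows] == "case"]
    ctlRows <- rows[des$role[rows] == "control"]
    if (length(caseRow) != 1L)
      stop("set '", pid, "' must contain exactly one case")
    vc <- v[caseRow, , , drop = FALSE][1, , ]          # J x K
    obsC <- m[caseRow, , , drop = FALSE][1, , ]
    vk <- v[ctlRows, , , drop = FALSE]                 # nc x J x K
    obsK <- m[ctlRows, , , drop = FALSE]
    nCtlObs <- apply(obsK, c(2L, 3L), sum)
    ctlSum <- apply(ifelse(obsK, vk, 0), c(2L, 3L), sum)
    ctlMean <- ifelse(nCtlObs > 0, ctlSum / pmax(nCtlObs, 1L), NA_real_)
    haveCase <- obsC
    haveCtl <- nCtlObs > 0
    setMean <- ifelse(haveCase & haveCtl, (vc + ctlMean) / 2, NA_real_)
    # cells where only one side of the set is observed become missing
    lone <- xor(haveCase, haveCtl)
    dropped <- dropped + sum(lone)
    out[caseRow, , ] <- ifelse(haveCase & haveCtl, vc - setMean, NA_real_)
    for (r in seq_along(ctlRows)) {
      vo <- vk[r, , ]; oo <- obsK[r, , ]
      out[ctlRows[r], , ] <- ifelse(oo & haveCase & haveCtl, vo - setMean,
                                    NA_real_)
    }
  }
  if (dropped > 0L)
    warning(sprintf("withinNormalize: %d cell group(s) had only one observed side; left missing", dropped))
  res <- tensor
  res@values <- out
  res@mask <- !is.na(out) & tensor@mask
  res
}
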