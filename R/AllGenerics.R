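#' @rdname OmicsTensor-accessors
#' @export
setGeneric("tensorValues", function(x) standardGeneric("tensorValues"))
#' @rdname OmicsTensor-accessors
#' @export
setGeneric("tensorMask", function(x) standardGeneric("tensorMask"))
#' @rdname OmicsTensor-accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))
#' @rdname OmicsTensor-accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))
#' @rdname OmicsTensor-accessors
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))
#' @rdname OmicsTensor-accessors
#' @export
setGeneric("blockName", function(x) standardGeneric("blockName"))
#' @rdname OmicsTensor-accessors
#' @export
setGeneric("tensorDesign", function(x) standardGeneric("tensorDesign"))

#' Accessors for OmicsTensor
#'
#' @param x an \linkS4class{OmicsTensor}.
#' @return \code{tensorValues}/\code{tensorMask} return the 3-way arrays,
#'   \code{subjectIds}/\code{featureIds} the mode labels, \code{timePoints}
#'   the MBSC labels, \code{blockName} the block, \code{tensorDesign} the
#'   per-subject pairing table.
#' @name OmicsTensor-accessors
NULL

#' @rdname OmicsTensor-accessors
setMethod("tensorValues", "OmicsTensor", function(x) x@values)
#' @rdname OmicsTensor-accessors
setMethod("tensorMask", "OmicsTensor", function(x) x@mask)
#' @rdname OmicsTensor-accessors
setMethod("subjectIds", "OmicsTensor", function(x) dimnames(x@values)[[1L]])
#' @rdname OmicsTensor-accessors
setMethod("featureIds", "OmicsTensor", function(x) dimnames(x@values)[[2L]])
#' @rdname OmicsTensor-accessors
setMethod("timePoints", "OmicsTensor", function(x) x@timePoints)
#' @rdname OmicsTensor-accessors
setMethod("blockName", "OmicsTensor", function(x) x@block)
#' @rdname OmicsTensor-accessors
setMethod("tensorDesign", "OmicsTensor", function(x) x@design)

setMethod("show", "OmicsTensor", function(object) {
  d <- dim(object@values)
  cat(sprintf("OmicsTensor '%s': %d subjects x %d features x %d timepoints\n",
              object@block, d[1], d[2], d[3]))
  cat(sprintf("  timepoints (MBSC): %s\n",
              paste(object@timePoints, collapse = ", ")))
  cat(sprintf("  observed cells: %.1f%% (%d of %d)\n",
              100 * mean(object@mask), sum(object@mask), length(object@mask)))
  nc <- sum(object@design$role == "case")
  cat(sprintf("  design: %d cases, %d controls in %d sets\n",
              nc, d[1] - nc, length(unique(object@design$pair_id))))
})

setMethod("show", "Tucker3Model", function(object) {
  cat(sprintf("Tucker3Model ranks (%s): fit = %.4f, %d iterations%s\n",
              paste(object@ranks, collapse = ","), object@fit,
              object@nIterations,
              if (object@converged) "" else " (not converged)"))
})

setMethod("show", "NPLSDAModel", function(object) {
  cat(sprintf("NPLSDAModel: %d component(s), %d subjects, %d features, %d timepoints\n",
              object@nComponents, nrow(object@scores),
              nrow(object@featureWeights), nrow(object@timeWeights)))
  cat(sprintf("  R2X = %.4f, R2Y = %.4f; classes: %s\n",
              object@R2X, object@R2Y, paste(object@classes, collapse = " vs ")))
})

setMethod("show", "VIPSelection", function(object) {
  cat(sprintf("VIPSelection [%s]: %d features scored, %d selected",
              object@strategy, length(object@vipValues),
              length(object@selectedIds)))
  if (!is.na(object@percentile))
    cat(sprintf(" (> %gth percentile)", object@percentile))
  cat("\n")
  if (!is.na(object@q2))
    cat(sprintf("  refit performance: R2 = %.3f, Q2 = %.3f\n",
                object@r2, object@q2))
  if (length(object@provenance))
    cat(sprintf("  provenance: %s\n", object@provenance))
})

setMethod("show", "PcorNetwork", function(object) {
  cat(sprintf("PcorNetwork window %s: %d nodes, %d edges (|pcor| > %g)\n",
              object@window, nrow(object@nodes), nrow(object@edges),
              object@threshold))
})
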