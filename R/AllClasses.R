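#' @import methods
NULL

#' Three-way omics tensor with observation mask
#'
#' Container for one omics block arranged as a subjects x features x
#' timepoints array, the element \code{x[i, j, k]} holding the value for
#' subject i at feature j and timepoint k. The logical \code{mask} records
#' which cells were actually measured: \code{TRUE} means the value came from
#' data, \code{FALSE} marks a cell that is missing or was filled by
#' imputation. Timepoints are labelled in months before the clinical event
#' (months before seroconversion, MBSC) and are stored in strictly
#' decreasing order (12, 9, 6, 3, 0 by default) so that mode 3 always reads
#' chronologically left to right.
#'
#' @slot values numeric three-way array, subjects x features x timepoints.
#' @slot mask logical array of the same shape; \code{TRUE} = observed.
#' @slot block single block name, e.g. \code{"gene_expression"}.
#' @slot timePoints numeric MBSC labels, strictly decreasing.
#' @slot design \code{data.frame} with columns \code{subject_id},
#'   \code{pair_id}, \code{role} (\code{"case"} or \code{"control"}), one
#'   row per subject in mode 1, same order.
#'
#' @seealso [binToTensor()], [imputeMissing()], [withinNormalize()]
#' @export
setClass("OmicsTensor",
  slots = c(
    values = "array",
    mask = "array",
    block = "character",
    timePoints = "numeric",
    design = "data.frame"
  )
)

setValidity("OmicsTensor", function(object) {
  v <- object@values; m <- object@mask
  if (length(dim(v)) != 3L) return("values must be a 3-way array")
  if (!identical(dim(v), dim(m))) return("values and mask shapes differ")
  if (!is.logical(m)) return("mask must be logical")
  if (length(object@timePoints) != dim(v)[3L])
    return("timePoints length must equal the third mode dimension")
  if (is.unsorted(rev(object@timePoints), strictly = TRUE))
    return("timePoints must be strictly decreasing in MBSC")
  if (nrow(object@design) != dim(v)[1L])
    return("design must have one row per subject")
  need <- c("subject_id", "pair_id", "role")
  if (!all(need %in% names(object@design)))
    return("design must have subject_id, pair_id, role columns")
  if (!all(object@design$role %in% c("case", "control")))
    return("design role must be 'case' or 'control'")
  if (is.null(dimnames(v)) || any(vapply(dimnames(v), is.null, logical(1))))
    return("values must carry full dimnames (subjects, features, timepoints)")
  TRUE
})

#' Tucker3 decomposition of a three-way array
#'
#' Result of fitting a Tucker3 model by alternating least squares: a small
#' core array of size P x Q x R and three column-orthonormal loading
#' matrices for the subject, feature, and time modes. \code{fit} is the
#' fraction of the total sum of squares of the data explained by the model.
#'
#' @slot core numeric P x Q x R array.
#' @slot loadings list of three column-orthonormal matrices
#'   (subjects x P, features x Q, timepoints x R).
#' @slot ranks integer vector (P, Q, R).
#' @slot fit fraction of total SS explained, in [0, 1].
#' @slot nIterations number of ALS sweeps performed.
#' @slot converged logical.
#'
#' @seealso [tucker3Fit()], [diffitSelect()], [imputeMissing()]
#' @export
setClass("Tucker3Model",
  slots = c(
    core = "array",
    loadings = "list",
    ranks = "integer",
    fit = "numeric",
    nIterations = "integer",
    converged = "logical"
  )
)

setValidity("Tucker3Model", function(object) {
  if (length(object@ranks) != 3L) return("ranks must have length 3")
  if (length(object@loadings) != 3L) return("loadings must be a list of 3")
  for (m in 1:3) {
    A <- object@loadings[[m]]
    if (ncol(A) != object@ranks[m]) return("loading/rank mismatch")
    g <- crossprod(A)
    if (max(abs(g - diag(ncol(A)))) > 1e-8)
      return(sprintf("mode-%d loadings are not column-orthonormal", m))
  }
  if (object@fit < -1e-10 || object@fit > 1 + 1e-10)
    return("fit must lie in [0, 1]")
  TRUE
})

#' N-way PLS discriminant model
#'
#' Trilinear PLS (tri-PLS2) on a subjects x features x timepoints tensor
#' with a dummy-coded class response and a linear-discriminant layer on the
#' subject scores. Per component h the feature weight \code{featureWeights[, h]}
#' and time weight \code{timeWeights[, h]} are the dominant singular pair of
#' the covariance unfolding between the tensor and the (deflated) response;
#' both are unit norm, and the subject score is the tensor contracted with
#' their Kronecker product. Only the response is deflated.
#'
#' @slot nComponents number of components H.
#' @slot scores subjects x H matrix of mode-1 scores T.
#' @slot featureWeights features x H matrix W_J, unit-norm columns.
#' @slot timeWeights timepoints x H matrix W_K, unit-norm columns.
#' @slot responseWeights response-columns x H matrix V, unit-norm columns.
#' @slot coef H x nClasses inner regression coefficients of the centered
#'   dummy response on the scores.
#' @slot xMean features x timepoints matrix of training means.
#' @slot yMean response column means.
#' @slot classes class labels in sorted order.
#' @slot labels training labels (factor levels of \code{classes}).
#' @slot R2X,R2Y fractions of predictor / response SS explained.
#' @slot ssyExplained response SS explained per component (drives VIP).
#' @slot elementTable per-component data.frame of explained variance.
#' @slot discriminant list with the fitted rule on the scores
#'   (\code{type}, class means, pooled covariance inverse, priors).
#' @slot featureIds,timePoints mode labels captured at training time.
#'
#' @seealso [fitNPLSDA()], [predictNPLSDA()], [crossValidate()], [computeVIP()]
#' @export
setClass("NPLSDAModel",
  slots = c(
    nComponents = "integer",
    scores = "matrix",
    featureWeights = "matrix",
    timeWeights = "matrix",
    responseWeights = "matrix",
    coef = "matrix",
    xMean = "matrix",
    yMean = "numeric",
    classes = "character",
    labels = "character",
    R2X = "numeric",
    R2Y = "numeric",
    ssyExplained = "numeric",
    elementTable = "data.frame",
    discriminant = "list",
    featureIds = "character",
    timePoints = "numeric"
  )
)

setValidity("NPLSDAModel", function(object) {
  H <- object@nComponents
  if (ncol(object@featureWeights) != H || ncol(object@timeWeights) != H)
    return("weight matrices must have H columns")
  wn <- apply(object@featureWeights, 2, function(x) sqrt(sum(x^2)))
  kn <- apply(object@timeWeights, 2, function(x) sqrt(sum(x^2)))
  if (max(abs(c(wn, kn) - 1)) > 1e-10)
    return("feature/time weight columns must be unit norm")
  if (object@R2X < -1e-10 || object@R2X > 1 + 1e-10) return("R2X out of [0,1]")
  if (object@R2Y < -1e-10 || object@R2Y > 1 + 1e-10) return("R2Y out of [0,1]")
  TRUE
})

#' VIP-based feature selection result
#'
#' Per-variable importance-for-projection values under one of the three
#' arrangements (\code{"vip2d"}, \code{"vip3d_model1"}, \code{"vip3d_model2"})
#' or for the winning candidate of the union/intersection search, together
#' with the selected feature set and the cross-validated performance of the
#' model refitted on it.
#'
#' @slot strategy one of \code{"vip2d"}, \code{"vip3d_model1"},
#'   \code{"vip3d_model2"}, or \code{"search"}.
#' @slot vipValues named numeric vector, one aggregated score per feature.
#' @slot detail data.frame with per-timepoint / per-component values where
#'   the strategy produces them.
#' @slot percentile percentile threshold applied (NA before thresholding).
#' @slot selectedIds character vector of selected feature ids.
#' @slot provenance how the final set was formed (e.g.
#'   \code{"vip2d ∪ vip3d_model1"}).
#' @slot r2,q2 performance of the model refitted on \code{selectedIds}
#'   (NA until the search stage evaluates it).
#'
#' @seealso [computeVIP()], [selectByPercentile()], [searchBestSet()]
#' @export
setClass("VIPSelection",
  slots = c(
    strategy = "character",
    vipValues = "numeric",
    detail = "data.frame",
    percentile = "numeric",
    selectedIds = "character",
    provenance = "character",
    r2 = "numeric",
    q2 = "numeric"
  )
)

setValidity("VIPSelection", function(object) {
  if (any(object@vipValues < -1e-12)) return("VIP values must be >= 0")
  if (length(object@selectedIds) &&
      !all(object@selectedIds %in% names(object@vipValues)) &&
      object@strategy != "search")
    return("selected ids must come from the scored feature universe")
  TRUE
})

#' Time-window partial-correlation network
#'
#' Nodes are features of the selected signature annotated with their
#' molecule kind (gene / metabolite / vitamin) and the mean normalized case
#' value at the window's first timepoint (positive = up-regulated in cases).
#' Edges connect feature pairs whose full-order partial correlation exceeds
#' the threshold in absolute value, signed by the correlation's sign.
#'
#' @slot window window label, e.g. \code{"12to9"}.
#' @slot nodes data.frame: \code{feature_id}, \code{kind}, \code{mean_case},
#'   \code{direction}, \code{isolated}.
#' @slot edges data.frame: \code{from}, \code{to}, \code{pcor}, \code{sign}.
#' @slot threshold absolute partial-correlation cut applied.
#' @slot pcor the full symmetric partial-correlation matrix.
#'
#' @seealso [buildNetwork()], [partialCorrelations()], [compareWindows()]
#' @export
setClass("PcorNetwork",
  slots = c(
    window = "character",
    nodes = "data.frame",
    edges = "data.frame",
    threshold = "numeric",
    pcor = "matrix"
  )
)

setValidity("PcorNetwork", function(object) {
  if (nrow(object@edges)) {
    if (any(abs(object@edges$pcor) <= object@threshold))
      return("every edge must exceed the threshold in |pcor|")
    if (any(abs(object@edges$pcor) > 1 + 1e-12))
      return("partial correlations must lie in [-1, 1]")
  }
  TRUE
})
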