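#' Configuration for the synthetic matched case-control cohort
#'
#' Describes a longitudinal multi-omics case-control cohort emulating a
#' prospective autoimmunity study design: cases matched to 1 control
#' (gene expression) or 3 controls (metabolomics / dietary biomarkers),
#' five 3-month visit bins labelled by months before seroconversion
#' (MBSC: 12, 9, 6, 3, 0), block sizes of a few hundred features, a
#' planted case-control mean shift concentrated at the early timepoints,
#' and visit-level missingness constrained so every analysis subject
#' keeps at least 3 of 5 timepoints.
#'
#' @param nPairs number of case-control sets.
#' @param blockSpecs data.frame with columns \code{block},
#'   \code{n_features}, \code{controls_per_case} (1 or 3). The default
#'   mirrors a transcriptomics block (1:1) plus metabolomics and dietary
#'   blocks (1:3).
#' @param timepointLabels MBSC bin labels, strictly decreasing.
#' @param nInformativePerBlock planted discriminative features per block.
#' @param effectSize standardized case-control mean difference at
#'   informative features (units of \code{noiseSd}).
#' @param effectTimeProfile per-timepoint multiplier of the effect, same
#'   length as \code{timepointLabels}; the default loads the signal on
#'   the earliest visits (12 and 9 MBSC).
#' @param missingRate expected fraction of missing subject x timepoint x
#'   block cells, must be < 0.4 so the 3-of-5 constraint stays feasible.
#' @param noiseSd residual SD of the measurement noise.
#' @param nIncompletePairs extra pairs whose members have fewer than 3
#'   observed timepoints; they feed the held-out validation route.
#' @param seed integer RNG seed; identical seeds give byte-identical
#'   output.
#' @return a validated list of class \code{CohortConfig}.
#' @export
cohortConfig <- function(nPairs = 40L,
                         blockSpecs = data.frame(
                           block = c("gene_expression", "metabolomics", "dietary"),
                           n_features = c(400L, 150L, 30L),
                           controls_per_case = c(1L, 3L, 3L)),
                         timepointLabels = c(12, 9, 6, 3, 0),
                         nInformativePerBlock = 20L,
                         effectSize = 1.5,
                         effectTimeProfile = c(1.0, 1.0, 0.6, 0.4, 0.4),
                         missingRate = 0.1,
                         noiseSd = 1.0,
                         nIncompletePairs = 5L,
                         seed = 1L) {
  cfg <- list(nPairs = as.integer(nPairs), blockSpecs = blockSpecs,
              timepointLabels = timepointLabels,
              nInformativePerBlock = as.integer(nInformativePerBlock),
              effectSize = effectSize, effectTimeProfile = effectTimeProfile,
              missingRate = missingRate, noiseSd = noiseSd,
              nIncompletePairs = as.integer(nIncompletePairs),
              seed = as.integer(seed))
  class(cfg) <- "CohortConfig"
  .validateCohortConfig(cfg)
  cfg
}

.validateCohortConfig <- function(cfg) {
  bs <- cfg$blockSpecs
  if (!all(c("block", "n_features", "controls_per_case") %in% names(bs)))
    stop("blockSpecs needs block, n_features, controls_per_case columns")
  if (cfg$nPairs < 1L) stop("nPairs must be positive")
  if (any(bs$n_features < 1L)) stop("all block sizes must be positive")
  if (!all(bs$controls_per_case %in% c(1L, 3L)))
    stop("controls_per_case must be 1 or 3")
  if (any(cfg$nInformativePerBlock > bs$n_features))
    stop("nInformativePerBlock exceeds a block's feature count")
  if (cfg$missingRate < 0 || cfg$missingRate >= 0.4)
    stop("infeasible missingness: missingRate must lie in [0, 0.4) so every ",
         "subject can keep at least 3 of 5 timepoints")
  if (length(cfg$effectTimeProfile) != length(cfg$timepointLabels))
    stop("effectTimeProfile must match timepointLabels in length")
  if (cfg$noiseSd <= 0) stop("noiseSd must be positive")
  invisible(cfg)
}

#' Generate a synthetic multi-omics case-control cohort
#'
#' Emits raw long-format measurements with known ground truth. Feature
#' values are i.i.d. Gaussian noise plus a subject-level random intercept
#' (SD = 0.5 x noiseSd) emulating repeated measures; informative features
#' receive an additive mean shift of
#' \code{effectSize * effectTimeProfile[k] * noiseSd} in cases only.
#' Observation times are jittered uniformly inside the 3-month bin
#' boundaries. Missingness is applied completely at random at the
#' subject x timepoint x block level (whole visit vectors drop out, as
#' missed study visits do), capped so every regular subject keeps at
#' least 3 of 5 timepoints; an extra group of incomplete pairs with only
#' 1-2 observed timepoints is generated for the validation route.
#'
#' @param config a \code{CohortConfig} from [cohortConfig()].
#' @return list with \code{measurements} (long data.frame: subject_id,
#'   pair_id, role, block, feature_id, months_before_sc, value),
#'   \code{design} (pair_id, subject_id, role, blocks, sex, country), and
#'   \code{truth} (informative feature ids per block, the per-feature
#'   per-timepoint true effect, and subject outcome labels).
#' @export
generateCohort <- function(config) {
  .validateCohortConfig(config)
  set.seed(config$seed)
  tp <- config$timepointLabels
  nT <- length(tp)
  # bin boundaries matching the 3-month binning grid (MBSC)
  bounds <- .defaultBinBounds(tp)

  sexes <- c("female", "male")
  countries <- c("SWE", "FIN", "GER", "USA")

  allPairs <- config$nPairs + config$nIncompletePairs
  maxCtl <- max(config$blockSpecs$controls_per_case)

  design <- list(); meas <- list(); truthLabels <- list()
  truth <- list(informative = list(), effects = list())

  # informative feature choice is shared across pairs, per block
  for (b in seq_len(nrow(config$blockSpecs))) {
    bs <- config$blockSpecs[b, ]
    fids <- sprintf("%s_f%04d", bs$block, seq_len(bs$n_features))
    inf <- sort(sample(fids, config$nInformativePerBlock))
    truth$informative[[bs$block]] <- inf
    eff <- matrix(0, bs$n_features, nT, dimnames = list(fids, as.character(tp)))
    eff[inf, ] <- rep(config$effectSize * config$effectTimeProfile *
                        config$noiseSd, each = length(inf))
    truth$effects[[bs$block]] <- eff
  }

  for (p in seq_len(allPairs)) {
    pid <- sprintf("pair%03d", p)
    incomplete <- p > config$nPairs
    members <- c(case = sprintf("%s_case", pid),
                 stats::setNames(sprintf("%s_ctl%d", pid, seq_len(maxCtl)),
                                 paste0("ctl", seq_len(maxCtl))))
    sex <- sample(sexes, 1L); country <- sample(countries, 1L)

    for (b in seq_len(nrow(config$blockSpecs))) {
      bs <- config$blockSpecs[b, ]
      fids <- rownames(truth$effects[[bs$block]])
      eff <- truth$effects[[bs$block]]
      who <- members[seq_len(1L + bs$controls_per_case)]
      roles <- c("case", rep("control", bs$controls_per_case))
      for (s in seq_along(who)) {
        sid <- who[[s]]
        # observed timepoints for this subject x block
        if (incomplete) {
          nObs <- sample(1:2, 1L)
          obs <- sort(sample(seq_len(nT), nObs))
        } else {
          missTp <- which(stats::runif(nT) < config$missingRate)
          if (length(missTp) > nT - 3L)
            missTp <- sample(missTp, nT - 3L)
          obs <- setdiff(seq_len(nT), missTp)
        }
        intercept <- stats::rnorm(length(fids), 0, 0.5 * config$noiseSd)
        for (k in obs) {
          mbsc <- stats::runif(1L, bounds$lower[k], bounds$upper[k])
          vals <- intercept + stats::rnorm(length(fids), 0, config$noiseSd)
          if (roles[s] == "case") vals <- vals + eff[, k]
          meas[[length(meas) + 1L]] <- data.frame(
            subject_id = sid, pair_id = pid, role = roles[s],
            block = bs$block, feature_id = fids,
            months_before_sc = mbsc, value = vals)
        }
        design[[length(design) + 1L]] <- data.frame(
          pair_id = pid, subject_id = sid, role = roles[s],
          block = bs$block, sex = sex, country = country)
      }
    }
    truthLabels[[pid]] <- stats::setNames(
      c("case", rep("control", maxCtl)), members)
  }

  measurements <- as.data.frame(data.table::rbindlist(meas))
  rownames(measurements) <- NULL
  designTab <- unique(as.data.frame(data.table::rbindlist(design)))
  rownames(designTab) <- NULL
  truth$labels <- unlist(unname(truthLabels))
  list(measurements = measurements, design = designTab, truth = truth)
}

.defaultBinBounds <- function(tp) {
  # 3-month bins: 0 -> [1, 1.5), 3 -> [1.5, 4.5), 6 -> [4.5, 7.5),
  # 9 -> [7.5, 10.5), 12 -> [10.5, 13.5]
  centers <- sort(tp)
  lower <- c(1.0, centers[-1L] - 1.5)
  upper <- c(1.5, centers[-1L] + 1.5)
  i <- match(tp, centers)
  list(lower = lower[i], upper = upper[i])
}

#' Write a generated cohort to TSV/JSON fixtures
#'
#' Writes \code{measurements.tsv}, \code{design.tsv}, and
#' \code{truth.json} into \code{dir}. Values round-trip losslessly
#' through [readMeasurements()].
#'
#' @param cohort output of [generateCohort()].
#' @param dir target directory (created if absent).
#' @return named character vector of the written paths.
#' @export
writeCohort <- function(cohort, dir) {
  if (is.null(cohort$measurements) || nrow(cohort$measurements) == 0L)
    stop("empty measurement table: refusing to write fixtures")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(measurements = file.path(dir, "measurements.tsv"),
             design = file.path(dir, "design.tsv"),
             truth = file.path(dir, "truth.json"))
  data.table::fwrite(cohort$measurements, paths[["measurements"]],
                     sep = "\t", quote = FALSE)
  data.table::fwrite(cohort$design, paths[["design"]], sep = "\t",
                     quote = FALSE)
  jsonlite::write_json(cohort$truth, paths[["truth"]], digits = NA,
                       auto_unbox = TRUE)
  paths
}

#' Read long-format measurement and design tables
#'
#' @param dir directory containing \code{measurements.tsv} and
#'   \code{design.tsv} as written by [writeCohort()].
#' @return list with \code{measurements} and \code{design} data.frames.
#' @export
readMeasurements <- function(dir) {
  mp <- file.path(dir, "measurements.tsv")
  dp <- file.path(dir, "design.tsv")
  for (f in c(mp, dp)) if (!file.exists(f)) stop("missing input file: ", f)
  list(measurements = as.data.frame(data.table::fread(mp, sep = "\t")),
       design = as.data.frame(data.table::fread(dp, sep = "\t")))
}
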