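# End-to-end workflow: simulate/read -> bin -> filter/split -> impute ->
# normalize -> per-block NPLS-DA -> VIP selection -> integrated model ->
# permutation + per-timepoint validation -> time-window networks ->
# enrichment. Every stage writes plain-text artifacts (TSV/JSON/GraphML)
# and the run ends with a manifest listing all outputs with MD5 hashes.

#' Write / read an OmicsTensor bundle
#'
#' The bundle is plain text: \code{<name>_values.tsv} in long form
#' (subject_id, feature_id, timepoint, value, observed), a
#' \code{<name>_design.tsv}, and a \code{<name>_meta.json} sidecar with
#' the mode labels.
#'
#' @param tensor an \linkS4class{OmicsTensor}.
#' @param dir directory; \code{name} the file prefix.
#' @return named vector of paths (\code{writeTensorBundle}); the tensor
#'   (\code{readTensorBundle}).
#' @export
writeTensorBundle <- function(tensor, dir, name = blockName(tensor)) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  v <- tensor@values; m <- tensor@mask
  dn <- dimnames(v)
  long <- data.frame(
    subject_id = rep(dn[[1L]], times = length(dn[[2L]]) * length(dn[[3L]])),
    feature_id = rep(rep(dn[[2L]], each = length(dn[[1L]])),
                     times = length(dn[[3L]])),
    timepoint = rep(tensor@timePoints, each = length(dn[[1L]]) * length(dn[[2L]])),
    value = as.vector(v), observed = as.vector(m))
  paths <- c(values = file.path(dir, paste0(name, "_values.tsv")),
             design = file.path(dir, paste0(name, "_design.tsv")),
             meta = file.path(dir, paste0(name, "_meta.json")))
  data.table::fwrite(long, paths[["values"]], sep = "\t")
  data.table::fwrite(tensor@design, paths[["design"]], sep = "\t")
  jsonlite::write_json(
    list(block = tensor@block, subjects = dn[[1L]], features = dn[[2L]],
         timepoints = tensor@timePoints), paths[["meta"]],
    digits = NA, auto_unbox = TRUE)
  paths
}

#' @rdname writeTensorBundle
#' @param name file prefix of the bundle.
#' @export
readTensorBundle <- function(dir, name) {
  meta <- jsonlite::read_json(file.path(dir, paste0(name, "_meta.json")),
                              simplifyVector = TRUE)
  long <- as.data.frame(data.table::fread(
    file.path(dir, paste0(name, "_values.tsv")), sep = "\t"))
  des <- as.data.frame(data.table::fread(
    file.path(dir, paste0(name, "_design.tsv")), sep = "\t"))
  dn <- list(meta$subjects, meta$features, as.character(meta$timepoints))
  vals <- array(NA_real_, lengths(dn), dimnames = dn)
  mask <- array(FALSE, lengths(dn), dimnames = dn)
  i <- cbind(match(long$subject_id, meta$subjects),
             match(long$feature_id, meta$features),
             match(long$timepoint, meta$timepoints))
  vals[i] <- long$value
  mask[i] <- long$observed
  new("OmicsTensor", values = vals, mask = mask, block = meta$block,
      timePoints = as.numeric(meta$timepoints), design = des)
}

#' Assemble a pipeline configuration
#'
#' Either pass a YAML file path or override the defaults directly.
#' Every stochastic stage derives its own seed deterministically from
#' the single global seed, so any stage can be rerun reproducibly.
#'
#' @param path optional YAML config file; fields override the defaults.
#' @param ... named overrides applied after the file.
#' @return a validated config list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(path = NULL, ...) {
  cfg <- list(
    input_dir = NULL,           # directory with measurements/design TSVs
    simulate = NULL,            # a CohortConfig to generate inputs instead
    blocks = NULL,              # block names (default: all in the data)
    gene_blocks = "gene_expression",  # blocks using the 99th percentile
    bin_spec = defaultBinSpec(),
    min_observed_timepoints = 3L,
    impute_ranks = "diffit",
    impute_tol = 1e-7,
    diffit_max_total_rank = 9L,
    n_components = 2L,
    cv_scheme = "kfold5",
    cv_repeats = 1L,
    percentile_gene = 99,
    percentile_metab = 95,
    n_permutations = 100L,
    network_threshold = 0.7,
    alpha_grid = seq(0, 1, by = 0.1),
    en_n_tune = 100L,
    en_n_final = 1000L,
    en_response = "outcome",
    gmt = NULL,                 # optional gene-set file
    gsea_n_perm = 1000L,
    metabolite_class_map = NULL, # optional TSV: metabolite_id, class
    fdr = 0.2,
    seed = 1L)
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    over <- yaml::read_yaml(path)
    cfg[names(over)] <- over
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  if (is.null(cfg$seed)) stop("a seed is required; no silent nondeterminism")
  for (f in c("gmt", "metabolite_class_map"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("configured file does not exist: ", cfg[[f]])
  if (is.null(cfg$input_dir) && is.null(cfg$simulate))
    stop("either input_dir or a simulate config is required")
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order, writing each stage's artifact under
#' \code{outDir} and finishing with \code{manifest.json} that lists all
#' outputs with MD5 content hashes. Identical config and seed give
#' identical hashes for every deterministic stage.
#'
#' @param config a \code{PipelineConfig} from [pipelineConfig()].
#' @param outDir output directory (created).
#' @return the manifest, invisibly (list with \code{artifacts} and the
#'   per-stage summary \code{summary}).
#' @export
runPipeline <- function(config, outDir) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  rng <- .seedStream(config$seed)
  logLine <- function(stage, ...) {
    msg <- sprintf("[%s] %s", stage, sprintf(...))
    message(msg)
    cat(msg, "\n", file = file.path(outDir, "run.log"), append = TRUE)
  }
  summary <- list()

  # --- input stage --------------------------------------------------
  if (!is.null(config$simulate)) {
    simCfg <- config$simulate
    simCfg$seed <- rng()
    cohort <- generateCohort(do.call(cohortConfig, simCfg))
    writeCohort(cohort, file.path(outDir, "input"))
    inputDir <- file.path(outDir, "input")
    logLine("simulate", "generated cohort with seed %d", simCfg$seed)
  } else {
    inputDir <- config$input_dir
  }
  inp <- readMeasurements(inputDir)
  blocks <- config$blocks %||% unique(inp$measurements$block)

  # --- prep: bin, filter/split, impute, normalize -------------------
  analysis <- list(); validation <- list(); reports <- list()
  for (b in blocks) {
    tens <- binToTensor(inp$measurements, b, config$bin_spec)
    sp <- filterAndSplit(tens, config$min_observed_timepoints)
    ranks <- config$impute_ranks
    if (identical(ranks, "diffit")) {
      Xf <- sp$analysis@values
      Xf[!sp$analysis@mask] <- mean(Xf[sp$analysis@mask])
      ranks <- diffitSelect(Xf, maxTotalRank = config$diffit_max_total_rank)$ranks
    }
    imp <- imputeMissing(sp$analysis, ranks = ranks, tol = config$impute_tol)
    norm <- withinNormalize(imp$tensor)
    norm@mask[] <- TRUE          # complete after impute + normalize
    analysis[[b]] <- norm
    validation[[b]] <- if (is.null(sp$validation)) NULL else
      suppressWarnings(withinNormalize(sp$validation))
    reports[[b]] <- imp$report
    writeTensorBundle(norm, file.path(outDir, "tensors"), paste0(b, "_analysis"))
    if (!is.null(validation[[b]]))
      writeTensorBundle(validation[[b]], file.path(outDir, "tensors"),
                        paste0(b, "_validation"))
    logLine("prep", "block %s: %d analysis / %d validation subjects, %.1f%% imputed",
            b, dim(norm@values)[1L],
            if (is.null(sp$validation)) 0L else dim(sp$validation@values)[1L],
            100 * imp$report$fraction_imputed)
  }
  jsonlite::write_json(reports, file.path(outDir, "imputation_reports.json"),
                       digits = NA, auto_unbox = TRUE)

  # --- per-block NPLS-DA + VIP selection ----------------------------
  selections <- list(); blockModels <- list()
  vipByTimepoint <- list()
  for (b in blocks) {
    tens <- analysis[[b]]
    labels <- tensorDesign(tens)$role
    model <- fitNPLSDA(tens, labels, H = config$n_components)
    blockModels[[b]] <- model
    pct <- if (b %in% config$gene_blocks) config$percentile_gene else
      config$percentile_metab
    sels <- list(
      computeVIP(tensor = tens@values, labels = labels, strategy = "vip2d",
                 H = config$n_components),
      computeVIP(model = model, strategy = "vip3d_model1"),
      computeVIP(model = model, strategy = "vip3d_model2"))
    sels <- lapply(sels, selectByPercentile, percentile = pct)
    best <- searchBestSet(sels, tens, labels, H = config$n_components,
                          cvScheme = config$cv_scheme, seed = rng())
    selections[[b]] <- best
    # per-timepoint VIP table for enrichment (vip2d detail)
    d2 <- sels[[1L]]@detail
    vipByTimepoint[[b]] <- stats::reshape(
      d2, idvar = "feature_id", timevar = "timepoint", direction = "wide")
    selTab <- data.frame(feature_id = best@selectedIds, block = b)
    data.table::fwrite(selTab,
                       file.path(outDir, paste0("selected_", b, ".tsv")),
                       sep = "\t")
    data.table::fwrite(attr(best, "candidates"),
                       file.path(outDir, paste0("vip_search_", b, ".tsv")),
                       sep = "\t")
    logLine("select", "block %s: winner '%s' (%d features, Q2 = %.3f)",
            b, best@provenance, length(best@selectedIds), best@q2)
  }

  # --- integrated model ---------------------------------------------
  joint <- joinBlocks(analysis, features = lapply(selections, methods::slot,
                                                  "selectedIds"))
  jointLabels <- tensorDesign(joint)$role
  jointModel <- fitNPLSDA(joint, jointLabels, H = config$n_components)
  jointCV <- crossValidate(joint, jointLabels, H = config$n_components,
                           scheme = "loo")
  trainPred <- predictNPLSDA(jointModel, joint)
  trainAcc <- mean(trainPred$class == jointLabels)
  jsonlite::write_json(
    list(r2x = jointModel@R2X, r2y = jointModel@R2Y,
         q2_loo = jointCV$q2, cv_accuracy = jointCV$accuracy,
         training_accuracy = trainAcc,
         n_features = length(featureIds(joint)),
         scores = as.data.frame(jointModel@scores),
         element_table = jointModel@elementTable),
    file.path(outDir, "integrated_model.json"), digits = NA,
    auto_unbox = TRUE)
  logLine("fit", "integrated model: R2Y = %.3f, LOO Q2 = %.3f, accuracy = %.3f",
          jointModel@R2Y, jointCV$q2, jointCV$accuracy)

  # --- validation: permutations + per-timepoint LDA ------------------
  # random-feature null draws size-matched sets from the full feature
  # universe, so it runs on the unrestricted joint tensor
  jointFull <- joinBlocks(analysis)
  perm <- permutationTest(jointFull, tensorDesign(jointFull)$role,
                          featureIds(joint),
                          mode = "random_features",
                          nPermutations = config$n_permutations,
                          H = config$n_components,
                          cvScheme = config$cv_scheme, seed = rng())
  permLab <- permutationTest(joint, jointLabels, featureIds(joint),
                             mode = "permuted_labels",
                             nPermutations = config$n_permutations,
                             H = config$n_components,
                             cvScheme = config$cv_scheme, seed = rng())
  # named vectors serialize as bare arrays; keep the p-value names
  perm$p_value <- as.list(perm$p_value)
  permLab$p_value <- as.list(permLab$p_value)
  jsonlite::write_json(list(random_features = perm, permuted_labels = permLab),
                       file.path(outDir, "permutation_result.json"),
                       digits = NA, auto_unbox = TRUE)
  logLine("validate", "permutation p (random features): q2 = %.4f, r2 = %.4f",
          perm$p_value[["q2"]], perm$p_value[["r2"]])

  tpv <- list()
  for (b in blocks) {
    if (is.null(validation[[b]])) next
    tv <- timepointValidate(analysis[[b]], tensorDesign(analysis[[b]])$role,
                            validation[[b]],
                            tensorDesign(validation[[b]])$role,
                            selections[[b]]@selectedIds)
    tv$block <- b
    tpv[[b]] <- tv
  }
  if (length(tpv)) {
    tpvAll <- do.call(rbind, tpv)
    data.table::fwrite(tpvAll, file.path(outDir, "timepoint_validation.tsv"),
                       sep = "\t")
  }

  # --- time-window networks -----------------------------------------
  netDir <- file.path(outDir, "networks")
  deltasAll <- deltaProfiles(joint, subjects = "all")
  deltasCase <- deltaProfiles(joint, subjects = "cases")
  winStats <- list(); pcorVals <- list()
  for (w in names(deltasCase)) {
    en <- elasticNetSelect(deltasAll[[w]], response = config$en_response,
                           alphaGrid = config$alpha_grid,
                           nTune = config$en_n_tune,
                           nFinal = config$en_n_final, seed = rng())
    feats <- en$selected
    if (length(feats) < 3L) feats <- colnames(deltasCase[[w]]$delta)
    if (length(feats) < 3L) {
      logLine("network", "window %s: fewer than 3 features; skipped", w)
      next
    }
    pc <- partialCorrelations(deltasCase[[w]]$delta[, feats, drop = FALSE])
    kinds <- vapply(strsplit(feats, ":", fixed = TRUE), `[`, character(1), 1L)
    kindMap <- c(gene_expression = "gene", metabolomics = "metabolite",
                 dietary = "vitamin")
    firstTpIdx <- match(deltasCase[[w]]$from, timePoints(joint))
    meanCase <- colMeans(joint@values[tensorDesign(joint)$role == "case",
                                      feats, firstTpIdx, drop = FALSE])
    meta <- data.frame(feature_id = feats,
                       kind = unname(kindMap[kinds]),
                       mean_case = as.vector(meanCase))
    meta$kind[is.na(meta$kind)] <- "unknown"
    net <- buildNetwork(pc, meta, threshold = config$network_threshold,
                        window = w)
    exportNetwork(net, netDir)
    pcorVals[[w]] <- pc[upper.tri(pc)]
    winStats[[w]] <- data.frame(window = w, n_features = length(feats),
                                n_edges = nrow(net@edges), alpha = en$alpha)
  }
  if (length(pcorVals) >= 2L && all(lengths(pcorVals) >= 20L)) {
    cmp <- compareWindows(pcorVals)
    ws <- merge(do.call(rbind, winStats), cmp$kurtosis, by = "window")
    data.table::fwrite(ws, file.path(outDir, "window_stats.tsv"), sep = "\t")
    data.table::fwrite(cmp$ks, file.path(outDir, "window_ks.tsv"), sep = "\t")
    logLine("network", "%d windows; kurtosis %s", length(pcorVals),
            paste(sprintf("%.2f", cmp$kurtosis$excess_kurtosis), collapse = ", "))
  } else if (length(winStats)) {
    data.table::fwrite(do.call(rbind, winStats),
                       file.path(outDir, "window_stats.tsv"), sep = "\t")
    logLine("network", "signature too small for window distribution comparison")
  }

  # --- enrichment (optional inputs) ----------------------------------
  if (!is.null(config$gmt)) {
    geneBlock <- intersect(config$gene_blocks, blocks)[1L]
    if (!is.na(geneBlock)) {
      vb <- vipByTimepoint[[geneBlock]]
      vm <- as.matrix(vb[, -1L, drop = FALSE])
      rownames(vm) <- vb$feature_id
      colnames(vm) <- sub("^vip\\.", "", colnames(vm))
      gsea <- suppressWarnings(
        gseaByVIP(vm, readGMT(config$gmt), nPerm = config$gsea_n_perm,
                  seed = rng()))
      fc <- fisherCombine(gsea)
      data.table::fwrite(gsea, file.path(outDir, "enrichment.tsv"), sep = "\t")
      data.table::fwrite(fc$combinations,
                         file.path(outDir, "enrichment_combined.tsv"),
                         sep = "\t")
      data.table::fwrite(fc$selected,
                         file.path(outDir, "enrichment_selected.tsv"),
                         sep = "\t")
      logLine("enrich", "%d gene sets, %d selected", nrow(fc$selected),
              sum(fc$selected$selected))
    }
  }
  if (!is.null(config$metabolite_class_map)) {
    metBlocks <- setdiff(blocks, config$gene_blocks)
    if (length(metBlocks)) {
      cm <- as.data.frame(data.table::fread(config$metabolite_class_map,
                                            sep = "\t"))
      mce <- suppressWarnings(
        metaboliteClassEnrichment(analysis[[metBlocks[1L]]], cm,
                                  fdr = config$fdr))
      data.table::fwrite(mce, file.path(outDir, "metabolite_classes.tsv"),
                         sep = "\t")
      logLine("enrich", "metabolite classes: %d enriched",
              sum(mce$enriched, na.rm = TRUE))
    }
  }

  # --- manifest ------------------------------------------------------
  files <- setdiff(list.files(outDir, recursive = TRUE),
                   c("manifest.json", "run.log"))
  hashes <- tools::md5sum(file.path(outDir, files))
  manifest <- list(
    artifacts = data.frame(path = files, md5 = unname(hashes)),
    summary = list(blocks = blocks,
                   integrated = list(r2y = jointModel@R2Y, q2 = jointCV$q2,
                                     accuracy = jointCV$accuracy),
                   seed = config$seed))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(manifest)
}
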