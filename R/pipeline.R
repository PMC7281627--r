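# End-to-end orchestration: synthesize (or load) cores, deconvolve,
# segment, extract features, classify tumor/stroma, rank features and
# call Ki67 at the single-cell and core level, render false color maps,
# and write a manifest with per-stage output hashes.

#' PipelineConfig: configuration of a full run
#'
#' @slot nCores number of synthetic cores in the TMA.
#' @slot coreSpec the \code{\linkS4class{SyntheticCoreSpec}} template
#'   (its seed is re-keyed per core from the run seed).
#' @slot stainModel the \code{\linkS4class{StainModel}}.
#' @slot segParams the \code{\linkS4class{SegmentationParams}}.
#' @slot trainCfg the \code{\linkS4class{TrainConfig}}.
#' @slot thresholdMethod single-cell threshold selection method.
#' @slot rampRange "global" (ramp over the pooled tumor NHMOD range of
#'   the whole TMA; default), "core" (per-core min/max), or a numeric
#'   length-2 fixed range.
#' @slot coreRule core-positivity fraction cut, in (0, 1); strict.
#' @slot seed run seed; every stochastic stage is keyed to it.
#' @slot outDir default output directory.
#' @export
setClass("PipelineConfig",
  representation(nCores = "numeric", coreSpec = "SyntheticCoreSpec",
                 stainModel = "StainModel",
                 segParams = "SegmentationParams",
                 trainCfg = "TrainConfig", thresholdMethod = "character",
                 rampRange = "ANY", coreRule = "numeric",
                 seed = "numeric", outDir = "character"))

setValidity("PipelineConfig", function(object) {
  msgs <- character()
  if (object@nCores < 1) msgs <- c(msgs, "nCores must be >= 1")
  if (object@coreRule <= 0 || object@coreRule >= 1)
    msgs <- c(msgs, "coreRule must lie in (0, 1)")
  rr <- object@rampRange
  if (!(is.character(rr) && rr %in% c("global", "core")) &&
      !(is.numeric(rr) && length(rr) == 2 && rr[1] < rr[2]))
    msgs <- c(msgs,
              "rampRange must be 'global', 'core' or numeric c(low, high)")
  if (length(msgs)) msgs else TRUE
})

#' Construct a pipeline configuration
#'
#' @param nCores number of synthetic cores (default 10).
#' @param coreSpec core generator spec template.
#' @param stainModel stain model.
#' @param segParams segmentation parameters.
#' @param trainCfg classifier training configuration.
#' @param thresholdMethod single-cell threshold method ("youden").
#' @param rampRange "global", "core", or numeric c(low, high); see
#'   \code{\linkS4class{PipelineConfig}}.
#' @param coreRule core positivity cut (default 0.10, strict).
#' @param seed run seed.
#' @param outDir default output directory.
#' @return a \code{\linkS4class{PipelineConfig}}.
#' @export
pipelineConfig <- function(nCores = 10, coreSpec = syntheticCoreSpec(),
                           stainModel = defaultHEModel(),
                           segParams = segmentationParams(),
                           trainCfg = trainConfig(),
                           thresholdMethod = "youden",
                           rampRange = "global", coreRule = 0.10,
                           seed = 1L, outDir = tempfile("heki67_run_")) {
  new("PipelineConfig", nCores = nCores, coreSpec = coreSpec,
      stainModel = stainModel, segParams = segParams,
      trainCfg = trainCfg, thresholdMethod = thresholdMethod,
      rampRange = rampRange, coreRule = coreRule, seed = seed,
      outDir = outDir)
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys (all optional): \code{n_cores},
#' \code{seed}, \code{core_rule}, \code{ramp_range}, \code{out_dir},
#' \code{threshold_method}, and nested \code{core_spec},
#' \code{segmentation}, \code{training} sections whose fields are passed
#' to \code{\link{syntheticCoreSpec}}, \code{\link{segmentationParams}}
#' and \code{\link{trainConfig}}; \code{stain_model} names a YAML file
#' for \code{\link{readStainModel}}.
#'
#' @param path YAML file.
#' @return a \code{\linkS4class{PipelineConfig}}.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$n_cores)) args$nCores <- y$n_cores
  if (!is.null(y$seed)) args$seed <- y$seed
  if (!is.null(y$core_rule)) args$coreRule <- y$core_rule
  if (!is.null(y$ramp_range)) args$rampRange <- unlist(y$ramp_range)
  if (!is.null(y$out_dir)) args$outDir <- y$out_dir
  if (!is.null(y$threshold_method)) args$thresholdMethod <- y$threshold_method
  if (!is.null(y$core_spec))
    args$coreSpec <- do.call(syntheticCoreSpec, y$core_spec)
  if (!is.null(y$segmentation))
    args$segParams <- do.call(segmentationParams, y$segmentation)
  if (!is.null(y$training))
    args$trainCfg <- do.call(trainConfig, y$training)
  if (!is.null(y$stain_model))
    args$stainModel <- readStainModel(y$stain_model)
  do.call(pipelineConfig, args)
}

.configSnapshot <- function(config) {
  sp <- config@coreSpec
  list(
    n_cores = config@nCores,
    seed = config@seed,
    core_rule = config@coreRule,
    ramp_range = config@rampRange,
    threshold_method = config@thresholdMethod,
    core_spec = list(width = sp@width, height = sp@height,
                     n_tumor = sp@nTumor, n_stroma = sp@nStroma,
                     ki67_fraction = sp@ki67Fraction,
                     od_mean_negative = sp@odMeanNegative,
                     od_mean_positive = sp@odMeanPositive,
                     od_sd = sp@odSD,
                     tumor_radius_range = sp@tumorRadiusRange,
                     stroma_radius_range = sp@stromaRadiusRange,
                     eosin_background_od = sp@eosinBackgroundOD,
                     od_texture_sd = sp@odTextureSD,
                     noise_sd = sp@noiseSD),
    segmentation = list(od_threshold = config@segParams@odThreshold,
                        min_area = config@segParams@minArea,
                        max_area = config@segParams@maxArea,
                        smoothing_sigma = config@segParams@smoothingSigma,
                        min_peak_distance =
                          config@segParams@minPeakDistance),
    training = list(validation_split = config@trainCfg@validationSplit,
                    rf_n_trees = config@trainCfg@rfNTrees,
                    rf_min_samples_per_node =
                      config@trainCfg@rfMinSamplesPerNode))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

.hashFiles <- function(paths) {
  h <- as.character(tools::md5sum(paths))
  names(h) <- basename(paths)
  as.list(h)
}

#' Run the full pipeline on a synthetic TMA
#'
#' Executes, in order: core synthesis, stain deconvolution, nucleus
#' segmentation, feature extraction (with ground-truth attachment),
#' tumor/stroma classifier training and application, ROC feature ranking
#' with Youden threshold selection on the training half of the cores,
#' single-cell Ki67 calls, diagnostic metrics on the held-out half,
#' core-level positivity calls, and false-color-map rendering. Every
#' stochastic stage is keyed to the run seed; a re-run with the same
#' configuration reproduces identical output hashes. A stage failure
#' aborts the run naming the failing stage; partial outputs are
#' retained.
#'
#' @param config a \code{\linkS4class{PipelineConfig}}.
#' @param outDir output directory (default from the config).
#' @return the run manifest (a list, also written as
#'   \code{manifest.json}): config snapshot, package version, per-stage
#'   output-file MD5 hashes and counts, threshold and selected feature,
#'   and timings.
#' @export
runPipeline <- function(config, outDir = config@outDir) {
  validObject(config)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  manifest <- list(package = "heki67",
                   version = as.character(utils::packageVersion("heki67")),
                   config = .configSnapshot(config),
                   stages = list(), timings = list())
  t0 <- proc.time()[["elapsed"]]
  tick <- function(name) {
    manifest$timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    t0 <<- proc.time()[["elapsed"]]
  }
  nC <- as.integer(config@nCores)
  coreIds <- sprintf("core%02d", seq_len(nC))

  cores <- .stage("synth", {
    lapply(seq_len(nC), function(i) {
      sp <- config@coreSpec
      sp@seed <- as.integer(config@seed) + 101L * i
      core <- generateCore(sp, model = config@stainModel)
      writeCore(core, file.path(outDir, "cores"), coreIds[i])
      core
    })
  })
  coreFiles <- list.files(file.path(outDir, "cores"), full.names = TRUE)
  manifest$stages$synth <- list(
    files = .hashFiles(coreFiles),
    counts = list(cores = nC,
                  nuclei = sum(vapply(cores, function(c)
                    nrow(coreTruth(c)), numeric(1)))))
  message("stage synth: ", nC, " cores, ",
          manifest$stages$synth$counts$nuclei, " nuclei")
  tick("synth")

  stains <- .stage("deconvolve", lapply(cores, function(core)
    deconvolve(rgbToOD(coreImage(core), config@stainModel),
               config@stainModel)))
  tick("deconvolve")

  masks <- .stage("segment", lapply(stains, function(s)
    detectNuclei(hematoxylinMap(s), config@segParams)))
  manifest$stages$segment <- list(counts = list(
    nuclei_detected = sum(vapply(masks, max, numeric(1)))))
  message("stage segment: ",
          manifest$stages$segment$counts$nuclei_detected,
          " nuclei detected")
  tick("segment")

  records <- .stage("features", {
    recs <- lapply(seq_len(nC), function(i) {
      r <- nucleusFeatures(masks[[i]], stains[[i]])
      r <- attachTruth(r, masks[[i]], cores[[i]])
      r$core_id <- coreIds[i]
      writeFeatureTable(r, file.path(outDir,
                                     paste0(coreIds[i], "_features.csv")))
      r
    })
    do.call(rbind, recs)
  })
  featFiles <- list.files(outDir, pattern = "_features\\.csv$",
                          full.names = TRUE)
  manifest$stages$features <- list(files = .hashFiles(featFiles),
                                   counts = list(records = nrow(records)))
  tick("features")

  records$class_truth <- records$class_label
  trainCores <- coreIds[seq_len(ceiling(nC / 2))]
  labeled <- records[records$class_truth %in% c("tumor", "stroma"), ,
                     drop = FALSE]
  classifyStage <- .stage("classify", {
    clf <- trainTumorStroma(labeled, config@trainCfg)
    list(clf = clf, records = classifyCells(records, clf))
  })
  classified <- classifyStage$records
  manifest$stages$classify <- list(
    counts = list(tumor = sum(classified$class_label == "tumor"),
                  stroma = sum(classified$class_label == "stroma")),
    report = as.list(classifierReport(classifyStage$clf)))
  message("stage classify: ",
          manifest$stages$classify$counts$tumor, " tumor / ",
          manifest$stages$classify$counts$stroma, " stroma (validation ",
          "accuracy ", round(manifest$stages$classify$report$accuracy, 4),
          ")")
  tick("classify")

  selection <- .stage("select_feature", {
    trainTumor <- classified[classified$core_id %in% trainCores &
                               classified$class_label == "tumor" &
                               classified$ki67_truth %in%
                                 c("positive", "negative"), ,
                             drop = FALSE]
    if (length(unique(trainTumor$ki67_truth)) < 2) {
      # no contrast to learn a cut from (e.g. zero Ki67 fraction):
      # an infinite threshold calls every cell negative
      list(feature = "nhmod", threshold = Inf, auc = NA_real_)
    } else {
      rocs <- rocRankFeatures(trainTumor)
      best <- rocs[[1]]
      list(feature = best@featureName,
           threshold = chooseThreshold(best, config@thresholdMethod),
           auc = rocAUC(best))
    }
  })
  manifest$stages$select_feature <- selection
  message("stage select_feature: ", selection$feature,
          " (AUC ", round(selection$auc, 3), "), threshold ",
          round(selection$threshold, 4))
  tick("select_feature")

  called <- .stage("call_cells", {
    out <- callCells(classified, selection$threshold, selection$feature)
    utils::write.csv(
      out[, c("core_id", "label", "centroid_x", "centroid_y", "nhmod",
              "class_label", "ki67_truth", "ki67_pred")],
      file.path(outDir, "predictions.csv"), row.names = FALSE)
    out
  })
  manifest$stages$call_cells <- list(
    files = .hashFiles(file.path(outDir, "predictions.csv")),
    counts = list(called_positive = sum(called$ki67_pred == "positive"),
                  called_negative = sum(called$ki67_pred == "negative")))
  tick("call_cells")

  evalStage <- .stage("evaluate", {
    evalCells <- called[!(called$core_id %in% trainCores) &
                          called$class_label == "tumor", , drop = FALSE]
    cm <- confusionFromCalls(evalCells$ki67_pred, evalCells$ki67_truth)
    if (cm@tp + cm@fn + cm@fp + cm@tn > 0) {
      tab <- metricsTable(cm)
      rep <- list(counts = list(tp = cm@tp, fn = cm@fn, fp = cm@fp,
                                tn = cm@tn),
                  metrics = stats::setNames(as.list(tab$value),
                                            tab$statistic))
      jsonlite::write_json(rep, file.path(outDir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
      list(files = .hashFiles(file.path(outDir, "metrics.json")),
           counts = rep$counts)
    } else NULL
  })
  if (!is.null(evalStage)) manifest$stages$evaluate <- evalStage
  tick("evaluate")

  calls <- .stage("call_cores", {
    # the calling ramp is anchored so that its "red" level coincides with
    # the selected single-cell threshold: "red or more" then means
    # "called Ki67-positive" and the core rule is a labeling-index cut
    tumorAll <- called[called$class_label == "tumor", , drop = FALSE]
    thr <- selection$threshold
    tab <- if (!is.finite(thr)) {
      do.call(rbind, lapply(coreIds, function(id) {
        n <- sum(called$core_id == id & called$class_label == "tumor")
        data.frame(core_id = id, n_tumor_cells = n, fraction_high = 0,
                   call = "negative", stringsAsFactors = FALSE)
      }))
    } else {
      lo <- min(tumorAll[[selection$feature]], thr)
      span <- max((thr - lo) / 0.75, 1e-3)
      callingRamp <- colorRamp2(c(thr - 0.75 * span, thr + 0.25 * span))
      do.call(rbind, lapply(coreIds, function(id) {
        sub <- called[called$core_id == id, , drop = FALSE]
        callCore(sub, callingRamp, coreId = id,
                 fraction = config@coreRule,
                 featureName = selection$feature)
      }))
    }
    utils::write.csv(tab, file.path(outDir, "core_calls.csv"),
                     row.names = FALSE)
    tab
  })
  manifest$stages$call_cores <- list(
    files = .hashFiles(file.path(outDir, "core_calls.csv")),
    counts = list(positive = sum(calls$call == "positive"),
                  negative = sum(calls$call == "negative")))
  message("stage call_cores: ",
          manifest$stages$call_cores$counts$positive, " positive / ",
          manifest$stages$call_cores$counts$negative, " negative")
  tick("call_cores")

  .stage("fcm", {
    tumorAll <- called[called$class_label == "tumor", , drop = FALSE]
    for (i in seq_len(nC)) {
      sub <- called[called$core_id == coreIds[i], , drop = FALSE]
      vals <- if (identical(config@rampRange, "core"))
        sub[[selection$feature]][sub$class_label == "tumor"]
      else tumorAll[[selection$feature]]
      ramp <- if (is.numeric(config@rampRange))
        defaultRamp(NULL, valueRange = config@rampRange)
      else defaultRamp(vals)
      fcm <- renderFCM(masks[[i]], sub, ramp, coreImage(cores[[i]]),
                       selection$feature)
      writeFCM(fcm, file.path(outDir, paste0(coreIds[i], "_fcm.png")),
               colorTablePath = file.path(
                 outDir, paste0(coreIds[i], "_fcm_colors.csv")))
    }
  })
  fcmFiles <- list.files(outDir, pattern = "_fcm", full.names = TRUE)
  manifest$stages$fcm <- list(files = .hashFiles(fcmFiles))
  tick("fcm")

  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
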