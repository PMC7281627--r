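#' @import methods
NULL

#' StainModel: H&E stain vectors and background intensity
#'
#' Holds the 3x3 matrix of unit-length stain optical-density (OD) vectors
#' (rows: hematoxylin, eosin, residual) and the per-channel background
#' intensity I0 that together define the Beer-Lambert forward model
#' \eqn{I = I_0 \cdot 10^{-M^T c}} and its inverse (color deconvolution).
#'
#' @slot stainMatrix 3x3 numeric matrix; rows are unit-norm stain OD vectors.
#' @slot backgroundIntensity numeric length-3 vector of 8-bit background
#'   intensities, each in (0, 255].
#' @export
setClass("StainModel",
  representation(stainMatrix = "matrix", backgroundIntensity = "numeric"))

setValidity("StainModel", function(object) {
  M <- object@stainMatrix
  I0 <- object@backgroundIntensity
  msgs <- character()
  if (!is.numeric(M) || !identical(dim(M), c(3L, 3L)))
    msgs <- c(msgs, "stainMatrix must be a numeric 3x3 matrix")
  else {
    norms <- sqrt(rowSums(M^2))
    if (any(abs(norms - 1) > 1e-6))
      msgs <- c(msgs, "each stain vector must have Euclidean norm 1 (tol 1e-6)")
    if (!all(is.finite(M)) || rcond(M) < .Machine$double.eps * 100)
      msgs <- c(msgs, "stainMatrix must be invertible")
  }
  if (length(I0) != 3 || any(!is.finite(I0)) || any(I0 <= 0) || any(I0 > 255))
    msgs <- c(msgs, "backgroundIntensity must be 3 values in (0, 255]")
  if (length(msgs)) msgs else TRUE
})

#' StainMaps: per-stain concentration rasters
#'
#' Result of color deconvolution: one scalar raster per stain, in
#' OD-equivalent concentration units, clamped at zero.
#'
#' @slot hematoxylin,eosin,residual numeric matrices of identical shape.
#' @export
setClass("StainMaps",
  representation(hematoxylin = "matrix", eosin = "matrix",
                 residual = "matrix"))

setValidity("StainMaps", function(object) {
  d <- dim(object@hematoxylin)
  if (!identical(d, dim(object@eosin)) || !identical(d, dim(object@residual)))
    return("all three stain maps must share the same shape")
  if (min(object@hematoxylin, object@eosin, object@residual, 0) < 0)
    return("stain concentrations must be non-negative (clamped)")
  TRUE
})

#' SyntheticCoreSpec: parameters of the synthetic TMA-core generator
#'
#' @slot width,height image size in pixels.
#' @slot nTumor,nStroma nucleus counts per population.
#' @slot ki67Fraction proportion of tumor nuclei in the Ki67-positive state.
#' @slot odMeanNegative,odMeanPositive,odSD parameters (OD units) of the
#'   per-nucleus mean hematoxylin OD distribution, by Ki67 state.
#' @slot tumorRadiusRange,stromaRadiusRange equivalent-circle radius range
#'   (pixels); stroma nuclei are smaller and more elongated.
#' @slot eosinBackgroundOD uniform eosin concentration of background tissue.
#' @slot odTextureSD within-nucleus chromatin texture: per-pixel Gaussian
#'   spread (OD units) around the nucleus mean, truncated at 0.
#' @slot noiseSD Gaussian pixel noise, 8-bit intensity units.
#' @slot seed integer seed driving all sampling.
#' @export
setClass("SyntheticCoreSpec",
  representation(width = "numeric", height = "numeric",
                 nTumor = "numeric", nStroma = "numeric",
                 ki67Fraction = "numeric",
                 odMeanNegative = "numeric", odMeanPositive = "numeric",
                 odSD = "numeric",
                 tumorRadiusRange = "numeric", stromaRadiusRange = "numeric",
                 eosinBackgroundOD = "numeric", odTextureSD = "numeric",
                 noiseSD = "numeric", seed = "numeric"))

setValidity("SyntheticCoreSpec", function(object) {
  msgs <- character()
  if (object@width < 16 || object@height < 16)
    msgs <- c(msgs, "image must be at least 16x16 pixels")
  if (object@nTumor < 0 || object@nStroma < 0)
    msgs <- c(msgs, "nucleus counts must be non-negative")
  if (object@ki67Fraction < 0 || object@ki67Fraction > 1)
    msgs <- c(msgs, "ki67Fraction must lie in [0, 1]")
  if (any(c(object@odMeanNegative, object@odMeanPositive, object@odSD,
            object@eosinBackgroundOD, object@odTextureSD,
            object@noiseSD) < 0))
    msgs <- c(msgs, "all OD and noise parameters must be >= 0")
  if (object@odMeanPositive < object@odMeanNegative)
    msgs <- c(msgs, "odMeanPositive must be >= odMeanNegative")
  for (nm in c("tumorRadiusRange", "stromaRadiusRange")) {
    r <- slot(object, nm)
    if (length(r) != 2 || any(r <= 0) || r[1] > r[2])
      msgs <- c(msgs, sprintf("%s must be positive with min <= max", nm))
  }
  if (length(msgs)) msgs else TRUE
})

#' SyntheticCore: a generated H&E-like core with full ground truth
#'
#' @slot rgb numeric H x W x 3 array with 8-bit values (0-255).
#' @slot labelMask integer matrix; 0 background, k for nucleus k, labels
#'   consecutive from 1.
#' @slot truth data.frame with one row per nucleus: label, class
#'   (tumor/stroma), ki67 (positive/negative), true_mean_od, centroid_x,
#'   centroid_y (0-based, x = column).
#' @slot spec the generating SyntheticCoreSpec.
#' @export
setClass("SyntheticCore",
  representation(rgb = "array", labelMask = "matrix",
                 truth = "data.frame", spec = "SyntheticCoreSpec"))

setValidity("SyntheticCore", function(object) {
  msgs <- character()
  if (length(dim(object@rgb)) != 3 || dim(object@rgb)[3] != 3)
    msgs <- c(msgs, "rgb must be an H x W x 3 array")
  labs <- sort(unique(as.integer(object@labelMask[object@labelMask > 0])))
  n <- nrow(object@truth)
  if (!identical(labs, seq_len(length(labs))))
    msgs <- c(msgs, "mask labels must be consecutive integers from 1")
  if (length(labs) != n || (n > 0 && !setequal(object@truth$label, labs)))
    msgs <- c(msgs, "label mask and truth table must be in bijection")
  if (length(msgs)) msgs else TRUE
})

#' SegmentationParams: nucleus-detection settings
#'
#' @slot odThreshold foreground cut on the hematoxylin map (OD units).
#' @slot minArea,maxArea admissible nucleus area (px^2).
#' @slot smoothingSigma Gaussian pre-smoothing (px).
#' @slot minPeakDistance minimum watershed seed spacing (px).
#' @slot fillHoles fill holes in the foreground mask before watershed.
#' @export
setClass("SegmentationParams",
  representation(odThreshold = "numeric", minArea = "numeric",
                 maxArea = "numeric", smoothingSigma = "numeric",
                 minPeakDistance = "numeric", fillHoles = "logical"))

setValidity("SegmentationParams", function(object) {
  msgs <- character()
  if (object@minArea >= object@maxArea)
    msgs <- c(msgs, "minArea must be < maxArea")
  if (any(c(object@odThreshold, object@minArea, object@maxArea,
            object@minPeakDistance) <= 0) || object@smoothingSigma < 0)
    msgs <- c(msgs, "all parameters must be positive (smoothingSigma >= 0)")
  if (length(msgs)) msgs else TRUE
})

#' TrainConfig: training protocol for the tumor/stroma classifier
#'
#' Defaults mirror the random-trees protocol used throughout: a 0.2
#' validation split and a forest of 50 trees with at least 10 samples per
#' node and unlimited depth.
#'
#' @slot validationSplit held-out proportion, in (0, 1).
#' @slot seed integer seed for the stratified split and model fitting.
#' @slot rfNTrees,rfMinSamplesPerNode random-forest hyperparameters
#'   (tree depth is unlimited).
#' @export
setClass("TrainConfig",
  representation(validationSplit = "numeric", seed = "numeric",
                 rfNTrees = "numeric", rfMinSamplesPerNode = "numeric"))

setValidity("TrainConfig", function(object) {
  if (object@validationSplit <= 0 || object@validationSplit >= 1)
    return("validationSplit must lie strictly between 0 and 1")
  TRUE
})

#' CellClassifier: a fitted tumor/stroma classifier
#'
#' @slot method one of "random_trees", "svm", "k_nearest", "normal_bayes".
#' @slot fit the fitted model object (or, for kNN, the stored training set).
#' @slot featureNames feature columns the model was fitted on.
#' @slot center,scale z-scoring parameters (empty for scale-invariant
#'   methods).
#' @slot report one-row data.frame: classifier_name, accuracy, ci_low,
#'   ci_high, n_validation.
#' @export
setClass("CellClassifier",
  representation(method = "character", fit = "ANY",
                 featureNames = "character",
                 center = "numeric", scale = "numeric",
                 report = "data.frame"))

#' RocResult: empirical ROC curve for one feature
#'
#' @slot featureName feature the curve was computed for.
#' @slot thresholds unique feature values used as decision cuts
#'   (prediction is positive at values >= threshold), descending.
#' @slot tpr,fpr true/false positive rates along \code{thresholds}.
#' @slot auc area under the curve (trapezoid; equals the Mann-Whitney
#'   statistic with ties counted one half).
#' @slot aucCI DeLong 95\% confidence interval for the AUC.
#' @export
setClass("RocResult",
  representation(featureName = "character", thresholds = "numeric",
                 tpr = "numeric", fpr = "numeric",
                 auc = "numeric", aucCI = "numeric"))

setValidity("RocResult", function(object) {
  msgs <- character()
  if (object@auc < 0 || object@auc > 1) msgs <- c(msgs, "auc must be in [0,1]")
  if (is.unsorted(object@tpr) || is.unsorted(object@fpr))
    msgs <- c(msgs, "tpr and fpr must be monotone along the curve")
  if (length(msgs)) msgs else TRUE
})

#' ConfusionMetrics: 2x2 diagnostic counts
#'
#' Stores only the four counts; every derived statistic (sensitivity,
#' specificity, PPV, NPV, accuracy, F1) is recomputed on demand so stored
#' and derived values can never disagree.
#'
#' @slot tp,fn,fp,tn non-negative counts.
#' @export
setClass("ConfusionMetrics",
  representation(tp = "numeric", fn = "numeric", fp = "numeric",
                 tn = "numeric"))

setValidity("ConfusionMetrics", function(object) {
  k <- c(object@tp, object@fn, object@fp, object@tn)
  if (any(k < 0)) return("counts must be non-negative")
  if (sum(k) == 0) return("total count must be positive")
  TRUE
})

#' ColorRamp: the blue-to-yellow false-color scale
#'
#' Piecewise-linear color scale: blue at the lowest observed value, yellow
#' at the highest, with a defined "red" level (default three quarters of
#' the way up) used by the core-level positivity rule.
#'
#' @slot positions strictly increasing control positions from 0 to 1.
#' @slot colors matrix (one row per control point) of 8-bit RGB colors.
#' @slot valueRange measurement values (OD units) mapped to positions 0
#'   and 1.
#' @slot redPosition position of the "red" level in [0, 1].
#' @export
setClass("ColorRamp",
  representation(positions = "numeric", colors = "matrix",
                 valueRange = "numeric", redPosition = "numeric"))

setValidity("ColorRamp", function(object) {
  msgs <- character()
  p <- object@positions
  if (length(p) < 2 || p[1] != 0 || p[length(p)] != 1 || any(diff(p) <= 0))
    msgs <- c(msgs, "positions must increase strictly from 0 to 1")
  if (nrow(object@colors) != length(p) || ncol(object@colors) != 3)
    msgs <- c(msgs, "colors must be one RGB row per control position")
  if (length(object@valueRange) != 2 ||
      object@valueRange[1] >= object@valueRange[2])
    msgs <- c(msgs, "valueRange must satisfy low < high")
  if (object@redPosition < 0 || object@redPosition > 1)
    msgs <- c(msgs, "redPosition must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' FalseColorMap: rendered NHMOD overlay
#'
#' @slot overlay H x W x 3 array (0-255); nucleus pixels carry their
#'   nucleus' single ramp color, background passes through the source.
#' @slot legend rendered ramp strip (H x W x 3, 0-255).
#' @slot perNucleusColor data.frame: label, r, g, b.
#' @slot ramp the ColorRamp used.
#' @export
setClass("FalseColorMap",
  representation(overlay = "array", legend = "array",
                 perNucleusColor = "data.frame", ramp = "ColorRamp"))

# ---- show methods ------------------------------------------------------

setMethod("show", "StainModel", function(object) {
  cat("StainModel (rows: hematoxylin, eosin, residual)\n")
  M <- round(object@stainMatrix, 4)
  rownames(M) <- c("hematoxylin", "eosin", "residual")
  colnames(M) <- c("R", "G", "B")
  print(M)
  cat("background intensity I0:",
      paste(round(object@backgroundIntensity, 1), collapse = ", "), "\n")
})

setMethod("show", "SyntheticCore", function(object) {
  d <- dim(object@rgb)
  cat(sprintf("SyntheticCore: %d x %d px, %d nuclei (%d tumor, %d stroma)\n",
              d[1], d[2], nrow(object@truth),
              sum(object@truth$class == "tumor"),
              sum(object@truth$class == "stroma")))
  if (nrow(object@truth))
    cat(sprintf("  Ki67-positive fraction (tumor): %.3f\n",
                mean(object@truth$ki67[object@truth$class == "tumor"] ==
                       "positive")))
})

setMethod("show", "RocResult", function(object) {
  cat(sprintf("RocResult: %s  AUC = %.3f (95%% CI %.3f-%.3f), %d thresholds\n",
              object@featureName, object@auc, object@aucCI[1],
              object@aucCI[2], length(object@thresholds)))
})

setMethod("show", "ConfusionMetrics", function(object) {
  cat("ConfusionMetrics (counts: tp", object@tp, "fn", object@fn,
      "fp", object@fp, "tn", object@tn, ")\n")
  print(metricsTable(object), row.names = FALSE)
})

setMethod("show", "CellClassifier", function(object) {
  cat(sprintf("CellClassifier: %s, %d features; validation accuracy %.4f\n",
              object@method, length(object@featureNames),
              object@report$accuracy))
})

setMethod("show", "ColorRamp", function(object) {
  cat(sprintf(
    "ColorRamp: %d control points, value range [%.4g, %.4g], red at %.2f\n",
    length(object@positions), object@valueRange[1], object@valueRange[2],
    object@redPosition))
})

# ---- accessors ---------------------------------------------------------

#' @rdname StainModel-class
#' @param model a \code{StainModel}.
#' @return \code{stainMatrix} returns the 3x3 stain matrix;
#'   \code{backgroundIntensity} the per-channel I0.
#' @export
stainMatrix <- function(model) model@stainMatrix

#' @rdname StainModel-class
#' @export
backgroundIntensity <- function(model) model@backgroundIntensity

#' @rdname StainMaps-class
#' @param maps a \code{StainMaps}.
#' @return the requested concentration matrix.
#' @export
hematoxylinMap <- function(maps) maps@hematoxylin

#' @rdname StainMaps-class
#' @export
eosinMap <- function(maps) maps@eosin

#' @rdname StainMaps-class
#' @export
residualMap <- function(maps) maps@residual

#' @rdname SyntheticCore-class
#' @param core a \code{SyntheticCore}.
#' @return \code{coreImage}: the H x W x 3 RGB array; \code{coreLabelMask}:
#'   the integer label matrix; \code{coreTruth}: the ground-truth table.
#' @export
coreImage <- function(core) core@rgb

#' @rdname SyntheticCore-class
#' @export
coreLabelMask <- function(core) core@labelMask

#' @rdname SyntheticCore-class
#' @export
coreTruth <- function(core) core@truth

#' @rdname CellClassifier-class
#' @param object a \code{CellClassifier}.
#' @return the one-row validation report data.frame.
#' @export
classifierReport <- function(object) object@report

#' @rdname RocResult-class
#' @param x a \code{RocResult}.
#' @return \code{rocAUC}: the AUC; \code{rocAUCCI}: its 95\% CI.
#' @export
rocAUC <- function(x) x@auc

#' @rdname RocResult-class
#' @export
rocAUCCI <- function(x) x@aucCI
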