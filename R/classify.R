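# Tumor-vs-stroma classification from nuclear features: a random forest
# with the reference hyperparameters (50 trees, >=10 samples per node,
# unlimited depth), plus RBF SVM, k-nearest (k = 5) and Gaussian naive
# Bayes comparison classifiers trained on the identical stratified split.

#' Construct a training configuration
#'
#' @param validationSplit held-out proportion (default 0.2).
#' @param seed integer seed for the stratified split and model fitting.
#' @param rfNTrees number of trees (default 50).
#' @param rfMinSamplesPerNode minimum samples per node (default 10);
#'   tree depth is unlimited.
#' @return a \code{\linkS4class{TrainConfig}}.
#' @export
trainConfig <- function(validationSplit = 0.2, seed = 1L, rfNTrees = 50,
                        rfMinSamplesPerNode = 10) {
  new("TrainConfig", validationSplit = validationSplit, seed = seed,
      rfNTrees = rfNTrees, rfMinSamplesPerNode = rfMinSamplesPerNode)
}

.featureMatrix <- function(records, featureNames) {
  missing <- setdiff(featureNames, names(records))
  if (length(missing))
    stop("feature schema mismatch: records lack column(s) ",
         paste(missing, collapse = ", "))
  X <- as.matrix(records[, featureNames, drop = FALSE])
  if (nrow(X) && (any(!is.finite(X))))
    stop("features must be complete (finite) for classification")
  X
}

# Stratified validation indices, deterministic in the seed.
.stratifiedSplit <- function(y, split, seed) {
  set.seed(as.integer(seed))
  idx <- unlist(lapply(split(seq_along(y), y), function(i) {
    nVal <- max(1L, round(length(i) * split))
    sample(i, nVal)
  }), use.names = FALSE)
  sort(idx)
}

.fitOne <- function(method, Xtr, ytr, cfg) {
  center <- numeric(0); scale <- numeric(0)
  if (method %in% c("svm", "k_nearest")) {
    center <- colMeans(Xtr)
    scale <- apply(Xtr, 2, stats::sd)
    scale[scale == 0] <- 1
    Xs <- sweep(sweep(Xtr, 2, center), 2, scale, "/")
  }
  set.seed(as.integer(cfg@seed) + 1L)
  fit <- switch(method,
    random_trees = randomForest::randomForest(
      x = Xtr, y = ytr, ntree = cfg@rfNTrees,
      nodesize = cfg@rfMinSamplesPerNode),
    svm = e1071::svm(x = Xs, y = ytr, kernel = "radial", cost = 1,
                     scale = FALSE),
    k_nearest = list(train = Xs, cl = ytr, k = 5L),
    normal_bayes = e1071::naiveBayes(x = as.data.frame(Xtr), y = ytr),
    stop("unknown classifier method: ", method))
  new("CellClassifier", method = method, fit = fit,
      featureNames = colnames(Xtr), center = center, scale = scale,
      report = data.frame())
}

.predictOne <- function(clf, X) {
  if (length(clf@center))
    X <- sweep(sweep(X, 2, clf@center), 2, clf@scale, "/")
  switch(clf@method,
    random_trees = stats::predict(clf@fit, X),
    svm = stats::predict(clf@fit, X),
    k_nearest = class::knn(clf@fit$train, X, clf@fit$cl, k = clf@fit$k),
    normal_bayes = stats::predict(clf@fit, as.data.frame(X)))
}

.validationReport <- function(name, pred, truth) {
  n <- length(truth)
  k <- sum(as.character(pred) == as.character(truth))
  ci <- stats::binom.test(k, n)$conf.int  # Clopper-Pearson
  data.frame(classifier_name = name, accuracy = k / n,
             ci_low = ci[1], ci_high = ci[2], n_validation = n,
             stringsAsFactors = FALSE)
}

.trainWithSplit <- function(records, cfg, method, valIdx,
                            featureNames = nuclearFeatureNames()) {
  y <- factor(records$class_label)
  X <- .featureMatrix(records, featureNames)
  clf <- .fitOne(method, X[-valIdx, , drop = FALSE],
                 droplevels(y[-valIdx]), cfg)
  pred <- .predictOne(clf, X[valIdx, , drop = FALSE])
  clf@report <- .validationReport(method, pred, y[valIdx])
  clf
}

#' Train the tumor/stroma random-forest classifier
#'
#' Stratified split by \code{validationSplit} and \code{seed}, then a
#' random forest with the reference hyperparameters; the report carries
#' the validation accuracy with a Clopper-Pearson 95\% CI.
#'
#' @param records feature table with \code{class_label} filled with the
#'   training truth (at least two classes).
#' @param cfg a \code{\linkS4class{TrainConfig}}.
#' @param featureNames feature columns to train on.
#' @return a fitted \code{\linkS4class{CellClassifier}}; inspect the
#'   validation report with \code{\link{classifierReport}}.
#' @export
trainTumorStroma <- function(records, cfg = trainConfig(),
                             featureNames = nuclearFeatureNames()) {
  y <- records$class_label
  if (length(unique(y)) < 2)
    stop("training requires at least two classes in class_label")
  valIdx <- .stratifiedSplit(y, cfg@validationSplit, cfg@seed)
  .trainWithSplit(records, cfg, "random_trees", valIdx, featureNames)
}

#' Compare four classifiers on the identical split
#'
#' Trains random trees, RBF SVM (C = 1), k-nearest neighbours (k = 5) and
#' Gaussian naive Bayes on the same stratified training partition and
#' reports each one's validation accuracy. Features are z-scored inside
#' the SVM and kNN paths only.
#'
#' @inheritParams trainTumorStroma
#' @return data.frame of four reports sorted by decreasing accuracy.
#' @export
compareClassifiers <- function(records, cfg = trainConfig(),
                               featureNames = nuclearFeatureNames()) {
  y <- records$class_label
  if (length(unique(y)) < 2)
    stop("training requires at least two classes in class_label")
  valIdx <- .stratifiedSplit(y, cfg@validationSplit, cfg@seed)
  methods <- c("random_trees", "svm", "k_nearest", "normal_bayes")
  reports <- do.call(rbind, lapply(methods, function(m)
    .trainWithSplit(records, cfg, m, valIdx, featureNames)@report))
  reports[order(-reports$accuracy), , drop = FALSE]
}

#' Classify nuclei as tumor or stroma
#'
#' @param records feature table (any number of rows, including zero).
#' @param classifier a fitted \code{\linkS4class{CellClassifier}} trained
#'   on the same feature schema.
#' @return the records with \code{class_label} filled by the classifier.
#' @export
classifyCells <- function(records, classifier) {
  if (nrow(records) == 0) return(records)
  X <- .featureMatrix(records, classifier@featureNames)
  records$class_label <- as.character(.predictOne(classifier, X))
  records
}
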