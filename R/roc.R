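# ROC-based feature ranking and single-cell Ki67 calling. The empirical
# ROC, trapezoid AUC (equal to the Mann-Whitney statistic with ties
# counted one half) and DeLong confidence interval are implemented here;
# they are the package's central inference machinery.

.isPositive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    ok <- labels %in% c("positive", "negative")
    if (!all(ok)) stop("labels must be 'positive'/'negative' or logical")
    return(labels == "positive")
  }
  stop("labels must be 'positive'/'negative' or logical")
}

#' Empirical ROC curve for one feature
#'
#' Thresholds are the unique observed values (a prediction is positive at
#' values >= threshold), taken in decreasing order so TPR and FPR are
#' non-decreasing along the curve. The AUC is the trapezoid area, which
#' equals the Mann-Whitney U statistic with ties counted one half; its
#' 95\% confidence interval is computed by the DeLong method.
#'
#' @param values numeric feature values.
#' @param labels ground truth: logical, or "positive"/"negative".
#' @param featureName name recorded in the result.
#' @return a \code{\linkS4class{RocResult}}.
#' @export
rocCurve <- function(values, labels, featureName = "feature") {
  pos <- .isPositive(labels)
  if (length(values) != length(pos))
    stop("values and labels must have equal length")
  keep <- is.finite(values)
  values <- values[keep]; pos <- pos[keep]
  m <- sum(pos); n <- sum(!pos)
  if (m == 0 || n == 0)
    stop("both truth classes must be present to compute a ROC curve")
  x <- values[pos]; y <- values[!pos]
  thr <- sort(unique(values), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(x >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(y >= t), numeric(1))
  ff <- c(0, fpr, 1); tt <- c(0, tpr, 1)
  auc <- sum(diff(ff) * (tt[-1] + tt[-length(tt)]) / 2)
  # DeLong placements
  v10 <- vapply(x, function(xi) (sum(y < xi) + 0.5 * sum(y == xi)) / n,
                numeric(1))
  v01 <- vapply(y, function(yj) (sum(x > yj) + 0.5 * sum(x == yj)) / m,
                numeric(1))
  v <- (if (m > 1) stats::var(v10) / m else 0) +
       (if (n > 1) stats::var(v01) / n else 0)
  ci <- pmin(pmax(auc + c(-1, 1) * stats::qnorm(0.975) * sqrt(v), 0), 1)
  new("RocResult", featureName = featureName, thresholds = thr,
      tpr = tpr, fpr = fpr, auc = auc, aucCI = ci)
}

#' Rank nuclear features by ROC AUC against Ki67 ground truth
#'
#' Computes the empirical ROC of every feature on the supplied (tumor)
#' records with known \code{ki67_truth} and returns the results sorted by
#' decreasing AUC. The top-ranked feature is the package's analogue of
#' selecting NHMOD as the Ki67 predictor.
#'
#' @param records feature table with \code{ki67_truth} in
#'   \{positive, negative\} (rows with unknown truth are dropped).
#' @param featureNames features to rank.
#' @return list of \code{\linkS4class{RocResult}} sorted by AUC.
#' @export
rocRankFeatures <- function(records,
                            featureNames = nuclearFeatureNames()) {
  records <- records[records$ki67_truth %in% c("positive", "negative"), ,
                     drop = FALSE]
  if (length(unique(records$ki67_truth)) < 2)
    stop("both Ki67 truth classes must be present")
  rocs <- lapply(featureNames, function(f)
    rocCurve(records[[f]], records$ki67_truth, f))
  rocs[order(-vapply(rocs, rocAUC, numeric(1)))]
}

#' Choose a single-cell decision threshold from a ROC curve
#'
#' Youden's J (TPR - FPR) is maximized over the observed thresholds; ties
#' are broken toward the lower threshold, i.e. toward higher sensitivity.
#'
#' @param roc a \code{\linkS4class{RocResult}}.
#' @param method currently only \code{"youden"}.
#' @return the selected threshold (same units as the feature).
#' @export
chooseThreshold <- function(roc, method = c("youden")) {
  method <- match.arg(method)
  j <- roc@tpr - roc@fpr
  cand <- roc@thresholds[j == max(j)]
  min(cand)
}

#' Call single cells Ki67-positive or negative
#'
#' Tumor-class records with feature value >= threshold are called
#' positive, the rest negative; non-tumor records stay "uncalled".
#'
#' @param records feature table with \code{class_label} filled.
#' @param threshold decision threshold (>= convention).
#' @param featureName feature to threshold (default \code{"nhmod"}).
#' @return the records with \code{ki67_pred} filled.
#' @export
callCells <- function(records, threshold, featureName = "nhmod") {
  if (!featureName %in% names(records))
    stop("feature '", featureName, "' not present in records")
  records$ki67_pred <- "uncalled"
  tum <- records$class_label == "tumor"
  records$ki67_pred[tum] <-
    ifelse(records[[featureName]][tum] >= threshold, "positive",
           "negative")
  records
}

#' Diagnostic metrics from 2x2 counts
#'
#' @param tp,fn,fp,tn confusion-matrix counts (truth in rows: tp/fn are
#'   the truly positive cells, fp/tn the truly negative).
#' @return a \code{\linkS4class{ConfusionMetrics}}; see
#'   \code{\link{metricsTable}} for the derived statistics.
#' @export
confusionMetrics <- function(tp, fn, fp, tn) {
  new("ConfusionMetrics", tp = tp, fn = fn, fp = fp, tn = tn)
}

#' Compare predictions and truth into a ConfusionMetrics
#'
#' @param pred,truth vectors in \{"positive","negative"\} (rows with other
#'   values are dropped pairwise).
#' @return a \code{\linkS4class{ConfusionMetrics}}.
#' @export
confusionFromCalls <- function(pred, truth) {
  keep <- pred %in% c("positive", "negative") &
          truth %in% c("positive", "negative")
  pred <- pred[keep]; truth <- truth[keep]
  confusionMetrics(tp = sum(pred == "positive" & truth == "positive"),
                   fn = sum(pred == "negative" & truth == "positive"),
                   fp = sum(pred == "positive" & truth == "negative"),
                   tn = sum(pred == "negative" & truth == "negative"))
}

.clopperPearson <- function(k, n) {
  if (n == 0) return(c(NA_real_, NA_real_))
  as.numeric(stats::binom.test(k, n)$conf.int)
}

.logitCI <- function(k, n) {
  if (n == 0 || k == 0 || k == n) return(c(NA_real_, NA_real_))
  p <- k / n
  se <- sqrt(1 / k + 1 / (n - k))
  stats::plogis(stats::qlogis(p) + c(-1, 1) * stats::qnorm(0.975) * se)
}

#' Derived diagnostic statistics
#'
#' Sensitivity, specificity, PPV, NPV, accuracy and F1 are recomputed
#' from the stored counts on every call (never cached), with
#' Clopper-Pearson 95\% CIs on sensitivity/specificity/accuracy and
#' logit-based CIs on PPV/NPV. A statistic with a zero denominator is
#' flagged undefined (value NaN); the others are still returned.
#'
#' @param cm a \code{\linkS4class{ConfusionMetrics}}.
#' @return data.frame: statistic, value, ci_low, ci_high, defined.
#' @export
metricsTable <- function(cm) {
  tp <- cm@tp; fn <- cm@fn; fp <- cm@fp; tn <- cm@tn
  n <- tp + fn + fp + tn
  rows <- list(
    sensitivity = list(k = tp, d = tp + fn, ci = .clopperPearson),
    specificity = list(k = tn, d = tn + fp, ci = .clopperPearson),
    ppv = list(k = tp, d = tp + fp, ci = .logitCI),
    npv = list(k = tn, d = tn + fn, ci = .logitCI),
    accuracy = list(k = tp + tn, d = n, ci = .clopperPearson))
  out <- do.call(rbind, lapply(names(rows), function(nm) {
    r <- rows[[nm]]
    defined <- r$d > 0
    ci <- if (defined) r$ci(r$k, r$d) else c(NA_real_, NA_real_)
    data.frame(statistic = nm,
               value = if (defined) r$k / r$d else NaN,
               ci_low = ci[1], ci_high = ci[2], defined = defined,
               stringsAsFactors = FALSE)
  }))
  f1d <- 2 * tp + fp + fn
  out <- rbind(out, data.frame(
    statistic = "f1", value = if (f1d > 0) 2 * tp / f1d else NaN,
    ci_low = NA_real_, ci_high = NA_real_, defined = f1d > 0,
    stringsAsFactors = FALSE))
  out
}

#' @rdname metricsTable
#' @param statistic one of the \code{metricsTable} statistic names.
#' @return \code{confusionStat} returns the single recomputed value.
#' @export
confusionStat <- function(cm, statistic) {
  tab <- metricsTable(cm)
  tab$value[match(statistic, tab$statistic)]
}

#' Core-level Ki67 positivity call
#'
#' A core is called positive when strictly more than \code{fraction}
#' (default 10\%) of its tumor cells lie at or above the color ramp's
#' "red" level, i.e. have NHMOD >= valueRange low + redPosition * span.
#'
#' @param records feature table for one core with \code{class_label}
#'   filled (at least one tumor cell).
#' @param ramp the \code{\linkS4class{ColorRamp}} defining the red level.
#' @param coreId identifier recorded in the output.
#' @param fraction the core rule cut (strict inequality; default 0.10).
#' @param featureName measurement the ramp is applied to.
#' @return one-row data.frame: core_id, n_tumor_cells, fraction_high,
#'   call.
#' @export
callCore <- function(records, ramp, coreId = "core", fraction = 0.10,
                     featureName = "nhmod") {
  tum <- records[records$class_label == "tumor", , drop = FALSE]
  if (nrow(tum) == 0)
    stop("core '", coreId, "' has zero tumor cells; cannot call")
  redValue <- ramp@valueRange[1] +
    ramp@redPosition * diff(ramp@valueRange)
  fracHigh <- mean(tum[[featureName]] >= redValue)
  data.frame(core_id = coreId, n_tumor_cells = nrow(tum),
             fraction_high = fracHigh,
             call = if (fracHigh > fraction) "positive" else "negative",
             stringsAsFactors = FALSE)
}
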