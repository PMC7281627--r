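test_that("AUC limits behave correctly", {
  sep <- rocCurve(c(1, 2, 3, 11, 12, 13),
                  rep(c("negative", "positive"), each = 3))
  expect_equal(rocAUC(sep), 1)
  flat <- rocCurve(rep(0.4, 10), rep(c("negative", "positive"), 5))
  expect_equal(rocAUC(flat), 0.5)
  expect_error(rocCurve(1:5, rep("positive", 5)), "both")
})

test_that("AUC equals explicit pair counting on hand-listed scores", {
  scores <- c(0.1, 0.2, 0.2, 0.3, 0.35, 0.4, 0.4, 0.4, 0.5, 0.55,
              0.3, 0.4, 0.45, 0.5, 0.5, 0.6, 0.6, 0.7, 0.8, 0.9)
  labels <- rep(c("negative", "positive"), each = 10)
  expect_equal(rocAUC(rocCurve(scores, labels)), mwAUC(scores, labels),
               tolerance = 1e-12)
})

test_that("AUC matches the Mann-Whitney oracle on random tied data", {
  set.seed(17)
  for (i in 1:50) {
    n <- sample(10:200, 1)
    labels <- ifelse(runif(n) < 0.5, "positive", "negative")
    if (length(unique(labels)) < 2) next
    values <- round(rnorm(n, ifelse(labels == "positive", 0.6, 0.45),
                          0.15), 2)
    expect_equal(rocAUC(rocCurve(values, labels)),
                 mwAUC(values, labels), tolerance = 1e-12)
  }
})

test_that("AUC and DeLong CI agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(18)
  for (i in 1:10) {
    n <- sample(30:150, 1)
    labels <- rep(c("negative", "positive"), length.out = n)
    values <- round(rnorm(n, ifelse(labels == "positive", 0.6, 0.45),
                          0.12), 2)
    mine <- rocCurve(values, labels)
    ref <- suppressMessages(pROC::roc(labels, values,
                                      levels = c("negative", "positive"),
                                      direction = "<"))
    ci <- suppressMessages(pROC::ci.auc(ref, method = "delong"))
    expect_equal(rocAUC(mine), as.numeric(pROC::auc(ref)),
                 tolerance = 1e-10)
    expect_equal(rocAUCCI(mine), as.numeric(ci[c(1, 3)]),
                 tolerance = 1e-8)
  }
})

test_that("Youden threshold lands between two equal Gaussians", {
  set.seed(19)
  v <- c(rnorm(4000, 0.45, 0.1), rnorm(4000, 0.65, 0.1))
  lab <- rep(c("negative", "positive"), each = 4000)
  roc <- rocCurve(v, lab)
  thr <- chooseThreshold(roc)
  expect_lt(abs(thr - 0.55), 0.03)
  expect_identical(thr, chooseThreshold(roc))  # deterministic

  # perfectly separated data: threshold lies in the gap
  sep <- rocCurve(c(1, 2, 3, 11, 12, 13),
                  rep(c("negative", "positive"), each = 3))
  gapThr <- chooseThreshold(sep)
  expect_gt(gapThr, 3)
  expect_lte(gapThr, 11)
})

test_that("single-cell calls follow the >= threshold convention", {
  rec <- data.frame(label = 1:5, nhmod = c(0.1, 0.2, 0.3, 0.4, 0.5),
                    class_label = c(rep("tumor", 4), "stroma"))
  allNeg <- callCells(rec, threshold = 0.9)
  expect_true(all(allNeg$ki67_pred[1:4] == "negative"))
  expect_equal(allNeg$ki67_pred[5], "uncalled")
  allPos <- callCells(rec, threshold = min(rec$nhmod))
  expect_true(all(allPos$ki67_pred[1:4] == "positive"))
  expect_error(callCells(rec, 0.5, featureName = "absent"), "absent")
})

test_that("per-cell accuracy matches the two-Gaussian closed form", {
  recs <- do.call(rbind, lapply(1:2, function(s)
    truthRecords(syntheticCoreSpec(ki67Fraction = 0.5, odTextureSD = 0,
                                   seed = 80 + s))$records))
  tum <- recs[recs$class_label == "tumor", ]
  thr <- 0.55
  called <- callCells(tum, thr)
  acc <- mean(called$ki67_pred ==
                ifelse(called$ki67_truth == "positive", "positive",
                       "negative"))
  piPos <- mean(tum$ki67_truth == "positive")
  expected <- piPos * pnorm((0.65 - thr) / 0.1) +
    (1 - piPos) * pnorm((thr - 0.45) / 0.1)
  se <- sqrt(expected * (1 - expected) / nrow(tum))
  expect_lt(abs(acc - expected), 3 * se)
})

test_that("confusion metrics reproduce the published validation table", {
  cm <- confusionMetrics(tp = 120, fn = 71, fp = 65, tn = 145)
  tab <- metricsTable(cm)
  get <- function(s) tab$value[tab$statistic == s]
  expect_equal(round(100 * get("sensitivity"), 2), 62.83)
  expect_equal(round(100 * get("specificity"), 2), 69.05)
  expect_equal(round(100 * get("ppv"), 2), 64.86)
  expect_equal(round(100 * get("npv"), 2), 67.13)
  expect_equal(round(100 * get("accuracy"), 2), 66.08)
  expect_equal(round(get("f1"), 3), 0.638)
})

test_that("confusion metrics are self-consistent and handle zeros", {
  cm <- confusionMetrics(10, 0, 0, 10)
  tab <- metricsTable(cm)
  expect_true(all(tab$value[tab$statistic != "f1"] == 1))
  expect_equal(confusionStat(cm, "f1"), 1)

  # recomputation from counts always reproduces the reported values
  cm2 <- confusionMetrics(7, 3, 2, 8)
  tab2 <- metricsTable(cm2)
  expect_equal(tab2$value[tab2$statistic == "sensitivity"], 7 / 10)
  expect_equal(tab2$value[tab2$statistic == "specificity"], 8 / 10)
  expect_equal(tab2$value[tab2$statistic == "ppv"], 7 / 9)
  expect_equal(tab2$value[tab2$statistic == "npv"], 8 / 11)
  expect_equal(tab2$value[tab2$statistic == "accuracy"], 15 / 20)
  expect_equal(tab2$value[tab2$statistic == "f1"], 14 / 19)
  props <- tab2[tab2$statistic != "f1", ]
  expect_true(all(props$ci_low <= props$value &
                    props$value <= props$ci_high, na.rm = TRUE))

  # a zero denominator flags only that statistic
  noPos <- metricsTable(confusionMetrics(0, 0, 3, 7))
  expect_true(is.nan(noPos$value[noPos$statistic == "sensitivity"]))
  expect_false(noPos$defined[noPos$statistic == "sensitivity"])
  expect_equal(noPos$value[noPos$statistic == "specificity"], 0.7)
  expect_error(confusionMetrics(0, 0, 0, 0), "positive")
})

test_that("the core rule is a strict 10 percent boundary", {
  ramp <- colorRamp2(c(0, 1))  # red level at 0.75
  mkCore <- function(nHigh) {
    data.frame(label = 1:100,
               nhmod = c(rep(0.9, nHigh), rep(0.1, 100 - nHigh)),
               class_label = "tumor")
  }
  expect_equal(callCore(mkCore(0), ramp)$call, "negative")
  expect_equal(callCore(mkCore(10), ramp)$call, "negative")
  expect_equal(callCore(mkCore(11), ramp)$call, "positive")
  expect_equal(callCore(mkCore(11), ramp)$fraction_high, 0.11)

  stroma <- data.frame(label = 1, nhmod = 0.5, class_label = "stroma")
  expect_error(callCore(stroma, ramp), "zero tumor")
})

test_that("NHMOD tops the feature ranking on default synthetic cores", {
  for (s in 1:3) {
    mc <- measuredCore(syntheticCoreSpec(seed = 200 + s))
    tum <- mc$records[mc$records$class_label == "tumor" &
                        mc$records$ki67_truth != "unknown", ]
    rocs <- rocRankFeatures(tum)
    expect_equal(rocs[[1]]@featureName, "nhmod")
    aucs <- vapply(rocs, rocAUC, numeric(1))
    expect_true(all(diff(aucs) <= 0))
  }
})
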