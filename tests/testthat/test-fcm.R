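test_that("the default ramp runs blue to yellow over the observed range", {
  ramp <- defaultRamp(c(0.2, 0.5, 0.9))
  expect_equal(ramp@valueRange, c(0.2, 0.9))
  expect_equal(as.numeric(rampColor(ramp, 0.2)), c(0, 0, 255))
  expect_equal(as.numeric(rampColor(ramp, 0.9)), c(255, 255, 0))
  expect_equal(ramp@redPosition, 0.75)
  expect_error(defaultRamp(numeric(0)), "no values")
})

test_that("a constant value set yields a defined, single-color mapping", {
  ramp <- defaultRamp(rep(0.4, 5))
  expect_lt(ramp@valueRange[1], ramp@valueRange[2])
  cols <- rampColor(ramp, rep(0.4, 5))
  expect_equal(nrow(unique(cols)), 1)
})

test_that("ramp evaluation equals the piecewise-linear oracle", {
  ramp <- defaultRamp(c(0.1, 0.8))
  set.seed(41)
  vals <- runif(200, 0, 0.9)
  cols <- rampColor(ramp, vals)
  for (i in seq_along(vals))
    expect_equal(as.numeric(cols[i, ]),
                 as.numeric(rampOracle(ramp, vals[i])))
})

test_that("ramp position is monotone in the measurement", {
  ramp <- defaultRamp(c(0, 1))
  set.seed(42)
  v <- sort(runif(50))
  # position toward yellow: r + g - b increases along the default ramp
  score <- function(cols) cols[, 1] + cols[, 2] - cols[, 3]
  s <- score(rampColor(ramp, v))
  expect_true(all(diff(s) >= 0))
})

test_that("rendering fills nuclei with single ramp colors over the source", {
  core <- generateCore(smallSpec(seed = 13))
  mask <- coreLabelMask(core)
  stains <- deconvolve(rgbToOD(coreImage(core)))
  rec <- nucleusFeatures(mask, stains)
  ramp <- defaultRamp(rec$nhmod)
  fcm <- renderFCM(mask, rec, ramp, coreImage(core))

  # every nucleus pixel carries its nucleus' single color
  for (k in sample(rec$label, 5)) {
    idx <- which(mask == k)
    expCol <- as.numeric(
      fcm@perNucleusColor[fcm@perNucleusColor$label == k, c("r", "g", "b")])
    for (ch in 1:3)
      expect_true(all(fcm@overlay[idx + (ch - 1) * length(mask)] ==
                        expCol[ch]))
  }
  # background passes through
  bg <- which(mask == 0)
  expect_identical(fcm@overlay[bg], coreImage(core)[bg])

  # endpoint nuclei are pure blue and pure yellow
  lo <- rec$label[which.min(rec$nhmod)]
  hi <- rec$label[which.max(rec$nhmod)]
  pc <- fcm@perNucleusColor
  expect_equal(as.numeric(pc[pc$label == lo, c("r", "g", "b")]),
               c(0, 0, 255))
  expect_equal(as.numeric(pc[pc$label == hi, c("r", "g", "b")]),
               c(255, 255, 0))

  # per-nucleus colors equal the interpolation oracle
  for (i in seq_len(nrow(rec)))
    expect_equal(as.numeric(pc[i, c("r", "g", "b")]),
                 as.numeric(rampOracle(ramp, rec$nhmod[i])))

  expect_error(renderFCM(mask, rec[-3, ], ramp, coreImage(core)), "3")
})

test_that("the red level recovers the positive set under strong separation", {
  recs <- truthRecords(syntheticCoreSpec(ki67Fraction = 0.5, odSD = 0.01,
                                         odTextureSD = 0,
                                         seed = 21))$records
  tum <- recs[recs$class_label == "tumor", ]
  ramp <- defaultRamp(tum$nhmod)
  redValue <- ramp@valueRange[1] + 0.75 * diff(ramp@valueRange)
  redSet <- tum$nhmod >= redValue
  redAcc <- mean(redSet == (tum$ki67_truth == "positive"))

  roc <- rocCurve(tum$nhmod, tum$ki67_truth)
  thr <- chooseThreshold(roc)
  called <- callCells(tum, thr)
  thrAcc <- mean(called$ki67_pred == called$ki67_truth)
  expect_gte(redAcc, thrAcc)
  expect_equal(thrAcc, 1)
})

test_that("false color map files are written", {
  core <- generateCore(smallSpec(seed = 14))
  mask <- coreLabelMask(core)
  rec <- nucleusFeatures(mask, deconvolve(rgbToOD(coreImage(core))))
  fcm <- renderFCM(mask, rec, defaultRamp(rec$nhmod), coreImage(core))
  dir <- withr::local_tempdir()
  paths <- writeFCM(fcm, file.path(dir, "o.png"),
                    legendPath = file.path(dir, "l.png"),
                    colorTablePath = file.path(dir, "c.csv"))
  expect_true(all(file.exists(paths)))
  back <- readRGBImage(paths[["overlay"]])
  expect_identical(back, fcm@overlay)
})
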