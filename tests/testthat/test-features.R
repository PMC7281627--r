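test_that("constant-field statistics are exact", {
  mask <- diskMask(8)
  stains <- stainMapsFrom(0.5 * mask, 0.2 * (mask * 0 + 1))
  rec <- nucleusFeatures(mask, stains)
  expect_equal(rec$nhmod, 0.5)
  expect_equal(rec$hema_od_max, 0.5)
  expect_equal(rec$hema_od_min, 0.5)
  expect_equal(rec$hema_od_sd, 0)
  expect_equal(rec$hema_od_range, 0)
  expect_equal(rec$hema_od_sum, 0.5 * sum(mask))
  expect_equal(rec$eosin_od_mean, 0.2)
})

test_that("NHMOD equals the explicit pixel-loop oracle", {
  mc <- measuredCore(smallSpec(seed = 4))
  hm <- hematoxylinMap(mc$stains)
  for (k in mc$records$label) {
    idx <- which(mc$mask == k)
    oracle <- sum(hm[idx]) / length(idx)
    expect_equal(mc$records$nhmod[mc$records$label == k], oracle,
                 tolerance = 1e-12)
  }
})

test_that("a rasterized disk has the expected area and circularity", {
  rec <- nucleusFeatures(diskMask(10), stainMapsFrom(diskMask(10) * 0.3))
  expect_lt(abs(rec$area - 100 * pi) / (100 * pi), 0.03)
  expect_gte(rec$circularity, 0.88)
  expect_lte(rec$circularity, 1.1)
  expect_equal(rec$max_caliper, 21, tolerance = 0.5)
  expect_equal(rec$min_caliper, 21, tolerance = 0.5)
  expect_lt(rec$eccentricity, 0.1)
})

test_that("features are invariant under translation and 90-degree rotation", {
  core <- generateCore(smallSpec(seed = 8, noiseSD = 0))
  mask <- coreLabelMask(core)
  hm <- hematoxylinMap(deconvolve(rgbToOD(coreImage(core))))
  base <- nucleusFeatures(mask, stainMapsFrom(hm))

  pad <- function(m, dy, dx) {
    out <- matrix(0, nrow(m) + dy, ncol(m) + dx)
    out[(dy + 1):(dy + nrow(m)), (dx + 1):(dx + ncol(m))] <- m
    out
  }
  trans <- nucleusFeatures(pad(mask, 7, 3), stainMapsFrom(pad(hm, 7, 3)))
  rot <- nucleusFeatures(t(mask[nrow(mask):1, ]),
                         stainMapsFrom(t(hm[nrow(hm):1, ])))

  odCols <- c("nhmod", "hema_od_sum", "hema_od_max", "hema_od_min",
              "hema_od_sd", "hema_od_range")
  shapeCols <- c("area", "perimeter", "circularity", "eccentricity",
                 "max_caliper", "min_caliper")
  for (other in list(trans, rot)) {
    expect_equal(other[, odCols], base[, odCols], tolerance = 1e-12)
    for (col in shapeCols)
      expect_equal(other[[col]], base[[col]],
                   tolerance = 0.01, ignore_attr = TRUE)
  }
  expect_equal(trans$centroid_x, base$centroid_x + 3)
  expect_equal(trans$centroid_y, base$centroid_y + 7)
})

test_that("the feature table round-trips through CSV", {
  mc <- measuredCore(smallSpec(seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(mc$records, path)
  back <- readFeatureTable(path)
  cols <- c("label", "centroid_x", "centroid_y", nuclearFeatureNames(),
            "class_label", "ki67_truth", "ki67_pred")
  expect_equal(back, mc$records[, cols], ignore_attr = TRUE)

  writeFeatureTable(mc$records[0, ], path)
  empty <- readFeatureTable(path)
  expect_equal(nrow(empty), 0)
  expect_identical(names(empty), cols)
})

test_that("Ki67-positive nuclei carry the designed OD separation", {
  recs <- do.call(rbind, lapply(1:4, function(s)
    truthRecords(syntheticCoreSpec(seed = 70 + s))$records))
  tum <- recs[recs$class_label == "tumor", ]
  pos <- tum$nhmod[tum$ki67_truth == "positive"]
  neg <- tum$nhmod[tum$ki67_truth == "negative"]
  # chromatin extremes replace 10% of pixels, attenuating the latent
  # separation of 0.20 to 0.9 * 0.20 = 0.18
  sep <- mean(pos) - mean(neg)
  se <- sqrt(var(pos) / length(pos) + var(neg) / length(neg))
  expect_lt(abs(sep - 0.18), 3 * se + 0.01)
})

test_that("shape mismatch between mask and maps is an error", {
  expect_error(nucleusFeatures(matrix(0L, 4, 4),
                               stainMapsFrom(matrix(0, 5, 5))),
               "shape")
})
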