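test_that("empty spec yields a blank background and empty truth table", {
  spec <- smallSpec(nTumor = 0, nStroma = 0, noiseSD = 0)
  core <- generateCore(spec)
  expect_equal(nrow(coreTruth(core)), 0)
  expect_true(all(coreLabelMask(core) == 0L))
  # pure eosin background renders as one constant color
  img <- coreImage(core)
  for (ch in 1:3) expect_equal(length(unique(as.numeric(img[, , ch]))), 1)
})

test_that("generation is bit-identical for a fixed seed", {
  spec <- smallSpec(seed = 7)
  a <- generateCore(spec)
  b <- generateCore(spec)
  expect_identical(coreImage(a), coreImage(b))
  expect_identical(coreLabelMask(a), coreLabelMask(b))
  expect_identical(coreTruth(a), coreTruth(b))
})

test_that("label mask and truth table are in bijection", {
  for (s in 1:4) {
    core <- generateCore(smallSpec(seed = s, nTumor = 10, nStroma = 10))
    labs <- sort(unique(as.integer(coreLabelMask(core)
                                   [coreLabelMask(core) > 0])))
    expect_identical(labs, seq_along(labs))
    expect_setequal(coreTruth(core)$label, labs)
  }
  touch <- generateCore(smallSpec(seed = 2, nTumor = 6, nStroma = 0),
                        touching = TRUE)
  labs <- sort(unique(as.integer(coreLabelMask(touch)
                                 [coreLabelMask(touch) > 0])))
  expect_setequal(coreTruth(touch)$label, labs)
})

test_that("noise-free single-nucleus render round-trips through the pipeline", {
  # texture off: measured NHMOD must equal the sampled nucleus mean up to
  # 8-bit quantization
  spec <- syntheticCoreSpec(width = 128, height = 128, nTumor = 1,
                            nStroma = 0, ki67Fraction = 1,
                            odMeanPositive = 0.8, odSD = 0,
                            odTextureSD = 0, noiseSD = 0, seed = 3)
  core <- generateCore(spec)
  stains <- deconvolve(rgbToOD(coreImage(core)))
  rec <- nucleusFeatures(coreLabelMask(core), stains)
  expect_equal(rec$nhmod, 0.8, tolerance = 0.02)
  expect_equal(rec$nhmod, coreTruth(core)$true_mean_od, tolerance = 0.02)

  # with chromatin texture the rendered per-nucleus mean is still
  # recovered to quantization accuracy
  spec2 <- smallSpec(noiseSD = 0, seed = 5)
  core2 <- generateCore(spec2)
  stains2 <- deconvolve(rgbToOD(coreImage(core2)))
  rec2 <- nucleusFeatures(coreLabelMask(core2), stains2)
  expect_equal(rec2$nhmod, coreTruth(core2)$true_mean_od,
               tolerance = 0.02)
})

test_that("empirical Ki67-positive fraction converges to the spec value", {
  ki <- unlist(lapply(1:10, function(s) {
    tr <- coreTruth(generateCore(syntheticCoreSpec(seed = 40 + s)))
    tr$ki67[tr$class == "tumor"] == "positive"
  }))
  p <- 0.30
  se <- sqrt(p * (1 - p) / length(ki))
  expect_lt(abs(mean(ki) - p), 3 * se)
})

test_that("infeasible packing fails with an informative error", {
  spec <- syntheticCoreSpec(width = 64, height = 64, nTumor = 200,
                            nStroma = 0, seed = 1)
  expect_error(generateCore(spec, maxTries = 50), "packing")
})

test_that("core files round-trip through PNG/TIFF/CSV", {
  dir <- withr::local_tempdir()
  core <- generateCore(smallSpec(seed = 9))
  paths <- writeCore(core, dir, "t")
  img <- readRGBImage(paths[["image"]])
  expect_identical(img, coreImage(core))
  mask <- readLabelMask(paths[["mask"]])
  expect_identical(mask, coreLabelMask(core))
  truth <- utils::read.csv(paths[["truth"]])
  expect_equal(truth$true_mean_od, coreTruth(core)$true_mean_od,
               tolerance = 1e-6)
  expect_identical(names(truth),
                   c("label", "class", "ki67", "true_mean_od",
                     "centroid_x", "centroid_y"))
})

test_that("spec invariants are enforced", {
  expect_error(syntheticCoreSpec(ki67Fraction = 1.2), "ki67Fraction")
  expect_error(syntheticCoreSpec(odMeanPositive = 0.3,
                                 odMeanNegative = 0.5), "odMeanPositive")
  expect_error(syntheticCoreSpec(tumorRadiusRange = c(10, 5)),
               "tumorRadiusRange")
})

test_that("design AUC calibration solves the truncated-normal overlap", {
  sd69 <- odSDForDesignAUC(0.688)
  expect_equal(designAUC(syntheticCoreSpec(odSD = sd69)), 0.688,
               tolerance = 1e-6)
  # small-sigma limit reduces to the Gaussian formula
  expect_equal(designAUC(syntheticCoreSpec(odSD = 0.1)),
               pnorm(0.2 / (0.1 * sqrt(2))), tolerance = 1e-4)
})
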