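test_that("optical density transform matches the Beer-Lambert formula", {
  m <- defaultHEModel()
  blank <- array(255, c(2, 2, 3))
  expect_equal(rgbToOD(blank, m), array(0, c(2, 2, 3)))

  one <- array(25.5, c(1, 1, 3))
  expect_equal(as.numeric(rgbToOD(one, m)), rep(1, 3), tolerance = 1e-12)

  set.seed(21)
  img <- array(sample(0:255, 32 * 32 * 3, replace = TRUE), c(32, 32, 3))
  od <- rgbToOD(img, m)
  oracle <- array(0, c(32, 32, 3))
  for (i in 1:32) for (j in 1:32) for (ch in 1:3)
    oracle[i, j, ch] <- -log10(max(img[i, j, ch], 1) / 255)
  expect_equal(od, oracle, tolerance = 1e-12)

  expect_error(rgbToOD(matrix(1, 4, 4), m), "3-channel")
})

test_that("rgb -> od -> rgb reproduces the image within quantization", {
  m <- defaultHEModel()
  set.seed(22)
  img <- array(sample(1:255, 16 * 16 * 3, replace = TRUE), c(16, 16, 3))
  back <- odToRGB(rgbToOD(img, m), m)
  expect_lte(max(abs(back - img)), 1)
})

test_that("default H&E model is normalized and well-conditioned", {
  m <- defaultHEModel()
  M <- stainMatrix(m)
  expect_equal(sqrt(rowSums(M^2)), c(h = 1, e = 1, r = 1),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_lt(abs(sum(M[3, ] * M[1, ])), 1e-6)
  expect_lt(abs(sum(M[3, ] * M[2, ])), 1e-6)
  k <- kappa(M, exact = TRUE)
  expect_lt(k, 10)
  expect_equal(k, 2.7936, tolerance = 1e-3)  # frozen regression value
})

test_that("deconvolution inverts the forward model", {
  m <- defaultHEModel()
  M <- stainMatrix(m)

  # pure-stain axis
  od <- array(0.7 * M[1, ], c(1, 1, 3))
  sm <- deconvolve(od, m)
  expect_equal(as.numeric(sm@hematoxylin), 0.7, tolerance = 1e-6)
  expect_equal(as.numeric(sm@eosin), 0, tolerance = 1e-6)
  expect_equal(as.numeric(sm@residual), 0, tolerance = 1e-6)

  # float-path round trip for random non-negative concentrations
  set.seed(23)
  for (i in 1:100) {
    cc <- c(runif(1, 0, 1.2), runif(1, 0, 1.2), runif(1, 0, 0.3))
    od <- array(matrix(cc, 1, 3) %*% M, c(1, 1, 3))
    sm <- deconvolve(od, m)
    expect_equal(c(sm@hematoxylin[1], sm@eosin[1], sm@residual[1]), cc,
                 tolerance = 1e-6)
  }

  # all-zero OD
  smz <- deconvolve(array(0, c(3, 3, 3)), m)
  expect_true(all(smz@hematoxylin == 0 & smz@eosin == 0 &
                    smz@residual == 0))

  # negative concentrations clamp to zero
  odn <- array(-0.1 * M[1, ] + 0.2 * M[2, ], c(1, 1, 3))
  odn[odn < 0] <- 0  # OD itself is non-negative
  smn <- deconvolve(odn, m)
  expect_gte(min(smn@hematoxylin, smn@eosin, smn@residual), 0)
})

test_that("singular stain matrix is rejected naming the degenerate pair", {
  M <- rbind(c(0.65, 0.70, 0.29), c(0.65, 0.70, 0.29) + 1e-9,
             c(0, 0, 1))
  m <- stainModel(M)
  expect_error(deconvolve(array(0.1, c(1, 1, 3)), m),
               "hematoxylin.*eosin")
})

test_that("stain model YAML serialization round-trips", {
  m <- defaultHEModel()
  path <- withr::local_tempfile(fileext = ".yaml")
  writeStainModel(m, path)
  m2 <- readStainModel(path)
  expect_equal(stainMatrix(m2), stainMatrix(m), tolerance = 1e-12)
  expect_equal(backgroundIntensity(m2), backgroundIntensity(m))
})
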