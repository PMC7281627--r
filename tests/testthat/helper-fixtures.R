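# Shared fixtures and independent oracles. Everything is generated in
# code; no binary fixtures.

# Small, fast core spec for unit tests (the acceptance tests use the
# generator defaults).
smallSpec <- function(...) {
  args <- list(width = 192, height = 192, nTumor = 12, nStroma = 8,
               seed = 1L)
  args[names(list(...))] <- list(...)
  do.call(syntheticCoreSpec, args)
}

# Generate a core and measure it through the full detection path.
measuredCore <- function(spec, model = defaultHEModel(),
                         params = segmentationParams()) {
  core <- generateCore(spec, model = model)
  stains <- deconvolve(rgbToOD(coreImage(core), model), model)
  mask <- detectNuclei(hematoxylinMap(stains), params)
  records <- attachTruth(nucleusFeatures(mask, stains), mask, core)
  list(core = core, stains = stains, mask = mask, records = records)
}

# Features measured on the ground-truth mask (no segmentation error).
truthRecords <- function(spec, model = defaultHEModel()) {
  core <- generateCore(spec, model = model)
  stains <- deconvolve(rgbToOD(coreImage(core), model), model)
  records <- nucleusFeatures(coreLabelMask(core), stains)
  truth <- coreTruth(core)
  records$class_label <- truth$class
  records$ki67_truth <- truth$ki67
  list(core = core, records = records)
}

# Independent Mann-Whitney AUC oracle: explicit pair counting, ties 1/2.
mwAUC <- function(values, labels) {
  pos <- values[labels == "positive"]
  neg <- values[labels != "positive"]
  cmp <- outer(pos, neg, function(a, b)
    (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Independent piecewise-linear ramp oracle: explicit segment search.
rampOracle <- function(ramp, value) {
  t <- (value - ramp@valueRange[1]) / diff(ramp@valueRange)
  t <- min(max(t, 0), 1)
  p <- ramp@positions
  i <- findInterval(t, p, rightmost.closed = TRUE)
  i <- min(max(i, 1), length(p) - 1)
  w <- (t - p[i]) / (p[i + 1] - p[i])
  round((1 - w) * ramp@colors[i, ] + w * ramp@colors[i + 1, ])
}

# A rasterized disk label mask.
diskMask <- function(radius, size = 2 * radius + 11,
                     center = c(size, size) / 2) {
  m <- matrix(0L, size, size)
  for (r in seq_len(size)) for (cc in seq_len(size))
    if ((r - center[1])^2 + (cc - center[2])^2 <= radius^2)
      m[r, cc] <- 1L
  m
}

stainMapsFrom <- function(hema, eosin = NULL) {
  if (is.null(eosin)) eosin <- matrix(0, nrow(hema), ncol(hema))
  new("StainMaps", hematoxylin = hema, eosin = eosin,
      residual = matrix(0, nrow(hema), ncol(hema)))
}

# Two-Gaussian toy feature records for classifier tests.
toyRecords <- function(n, separationSD = 6, seed = 1) {
  set.seed(seed)
  half <- n %/% 2
  cls <- rep(c("tumor", "stroma"), c(half, n - half))
  shift <- ifelse(cls == "tumor", 0, separationSD)
  rec <- data.frame(class_label = cls)
  for (f in paste0("f", 1:4))
    rec[[f]] <- stats::rnorm(n) + shift
  rec
}

# Balanced tumor/stroma fixture measured on truth masks; nCores cores of
# nPerClass nuclei per class.
classifierFixture <- function(nCores, nPerClass = 100, seedBase = 500) {
  do.call(rbind, lapply(seq_len(nCores), function(i) {
    tr <- truthRecords(syntheticCoreSpec(nTumor = nPerClass,
                                         nStroma = nPerClass,
                                         seed = seedBase + i))
    tr$records
  }))
}
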