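# Synthetic H&E TMA-core generator. Emulates two cell populations (tumor:
# large, round nuclei; stroma: small, elongated) where each nucleus carries
# a latent Ki67 state that shifts its mean hematoxylin OD upward when
# positive -- the statistical structure the downstream analysis assumes.

#' Specification of a synthetic TMA core
#'
#' Defaults define the package's reference study conditions: a 512x512
#' core with 120 tumor and 80 stroma nuclei, a tumor Ki67-positive
#' fraction of 0.30, per-nucleus mean hematoxylin OD drawn from
#' N(0.45, 0.10) for Ki67-negative and N(0.65, 0.10) for Ki67-positive
#' nuclei (truncated at 0), a uniform eosin tissue background, and mild
#' Gaussian pixel noise.
#'
#' @param width,height image size in pixels.
#' @param nTumor,nStroma nucleus counts.
#' @param ki67Fraction proportion of tumor nuclei that are Ki67-positive.
#' @param odMeanNegative,odMeanPositive,odSD hematoxylin mean-OD
#'   distribution parameters by Ki67 state (OD units).
#' @param tumorRadiusRange,stromaRadiusRange equivalent-circle radius range
#'   in pixels (nucleus area = pi * r^2); stroma nuclei are drawn more
#'   elongated than tumor nuclei.
#' @param eosinBackgroundOD eosin concentration of the background tissue.
#' @param odTextureSD within-nucleus chromatin texture: per-pixel Gaussian
#'   spread (OD units) around the nucleus mean, truncated at 0. Texture is
#'   what makes the nuclear \emph{mean} OD, rather than pixel extremes,
#'   the reliable estimator of a nucleus' staining level.
#' @param noiseSD Gaussian pixel noise standard deviation, 8-bit units.
#' @param seed integer seed; all sampling is keyed to it.
#' @return a \code{\linkS4class{SyntheticCoreSpec}}.
#' @export
syntheticCoreSpec <- function(width = 512, height = 512,
                              nTumor = 120, nStroma = 80,
                              ki67Fraction = 0.30,
                              odMeanNegative = 0.45,
                              odMeanPositive = 0.65,
                              odSD = 0.10,
                              tumorRadiusRange = c(8, 14),
                              stromaRadiusRange = c(4, 7),
                              eosinBackgroundOD = 0.25,
                              odTextureSD = 0.15,
                              noiseSD = 2,
                              seed = 1L) {
  new("SyntheticCoreSpec", width = width, height = height,
      nTumor = nTumor, nStroma = nStroma, ki67Fraction = ki67Fraction,
      odMeanNegative = odMeanNegative, odMeanPositive = odMeanPositive,
      odSD = odSD, tumorRadiusRange = tumorRadiusRange,
      stromaRadiusRange = stromaRadiusRange,
      eosinBackgroundOD = eosinBackgroundOD, odTextureSD = odTextureSD,
      noiseSD = noiseSD, seed = seed)
}

# AUC of two normals with common sd, both truncated at 0:
# P(X+ > X-) = integral of f+(x) F-(x) dx over [0, Inf).
.truncNormAUC <- function(muNeg, muPos, sd) {
  if (sd == 0) return(if (muPos > muNeg) 1 else 0.5)
  zNeg <- stats::pnorm(0, muNeg, sd)
  zPos <- stats::pnorm(0, muPos, sd)
  f <- function(x)
    stats::dnorm(x, muPos, sd) / (1 - zPos) *
      (stats::pnorm(x, muNeg, sd) - zNeg) / (1 - zNeg)
  stats::integrate(f, 0, muPos + 12 * sd, rel.tol = 1e-9)$value
}

#' Design AUC implied by generator parameters
#'
#' The single-feature AUC of the per-nucleus mean-OD discriminator,
#' \eqn{P(X_+ > X_-)} for the two truncated-at-zero normal mean-OD
#' populations the generator samples from. For small sigma this reduces
#' to the familiar \eqn{\Phi((\mu_+ - \mu_-)/(\sigma\sqrt{2}))}; at
#' larger sigma the truncation matters and is accounted for exactly.
#'
#' @param spec a \code{\linkS4class{SyntheticCoreSpec}}.
#' @return the design AUC in [0.5, 1].
#' @export
designAUC <- function(spec) {
  .truncNormAUC(spec@odMeanNegative, spec@odMeanPositive, spec@odSD)
}

#' Solve for the OD standard deviation giving a target design AUC
#'
#' Inverse of \code{\link{designAUC}} in sigma (for fixed means): used to
#' calibrate the generator to a prescribed single-feature AUC (for
#' example 0.688).
#'
#' @param auc target AUC in (0.5, 1).
#' @param muNeg,muPos mean OD of the negative and positive populations.
#' @return the common standard deviation (OD units).
#' @export
odSDForDesignAUC <- function(auc, muNeg = 0.45, muPos = 0.65) {
  if (auc <= 0.5 || auc >= 1) stop("target AUC must lie in (0.5, 1)")
  stats::uniroot(function(s) .truncNormAUC(muNeg, muPos, s) - auc,
                 interval = c(0.01, 5), tol = 1e-9)$root
}

# Truncated-at-zero normal sampling (inverse-CDF).
.rtnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  u <- stats::runif(n, stats::pnorm(0, mean, sd), 1)
  stats::qnorm(u, mean, sd)
}

# Rasterize one ellipse into the label mask (first writer wins).
# Returns the updated mask.
.rasterizeEllipse <- function(mask, cx, cy, a, b, theta, label) {
  h <- nrow(mask); w <- ncol(mask)
  r0 <- max(1L, floor(cy - a)); r1 <- min(h, ceiling(cy + a))
  c0 <- max(1L, floor(cx - a)); c1 <- min(w, ceiling(cx + a))
  rows <- r0:r1; cols <- c0:c1
  dy <- matrix(rows - cy, length(rows), length(cols))
  dx <- matrix(cols - cx, length(rows), length(cols), byrow = TRUE)
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- (u^2 + v^2) <= 1
  sub <- mask[rows, cols, drop = FALSE]
  write <- inside & sub == 0L
  sub[write] <- label
  mask[rows, cols] <- sub
  mask
}

#' Generate a synthetic H&E core with ground truth
#'
#' Places non-overlapping elliptical nuclei by rejection sampling (minimum
#' centroid distance = sum of the two bounding radii plus a 2 px margin),
#' samples each nucleus' mean hematoxylin OD from the truncated normal of
#' its Ki67 state, superimposes per-pixel chromatin texture
#' (\code{odTextureSD}), and renders the core through the forward
#' Beer-Lambert model with the supplied stain matrix, adding a uniform
#' eosin tissue background and Gaussian pixel noise. Deterministic for a
#' fixed seed.
#'
#' With \code{touching = TRUE} nuclei are placed in pairs whose centroid
#' distance is 1.5 times the mean bounding radius, producing touching
#' objects for watershed testing.
#'
#' @param spec a \code{\linkS4class{SyntheticCoreSpec}}.
#' @param model stain model used for the forward render.
#' @param touching place nuclei as touching pairs (default FALSE).
#' @param maxTries rejection-sampling attempts per nucleus before the
#'   packing is declared infeasible.
#' @return a \code{\linkS4class{SyntheticCore}}.
#' @export
generateCore <- function(spec, model = defaultHEModel(), touching = FALSE,
                         maxTries = 5000) {
  validObject(spec)
  h <- as.integer(spec@height); w <- as.integer(spec@width)
  nT <- as.integer(spec@nTumor); nS <- as.integer(spec@nStroma)
  n <- nT + nS

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(as.integer(spec@seed))

  cls <- c(rep("tumor", nT), rep("stroma", nS))
  # geometry: equivalent radius r (area = pi r^2); tumor rounder
  req <- ifelse(cls == "tumor",
                stats::runif(n, spec@tumorRadiusRange[1],
                             spec@tumorRadiusRange[2]),
                stats::runif(n, spec@stromaRadiusRange[1],
                             spec@stromaRadiusRange[2]))
  ratio <- ifelse(cls == "tumor", stats::runif(n, 0.75, 1.0),
                  stats::runif(n, 0.35, 0.50))
  aAx <- req / sqrt(ratio)      # semi-major
  bAx <- req * sqrt(ratio)      # semi-minor
  theta <- stats::runif(n, 0, pi)

  # Ki67 state: tumor nuclei Bernoulli(ki67Fraction); stroma negative
  ki67 <- rep("negative", n)
  if (nT > 0)
    ki67[seq_len(nT)] <- ifelse(
      stats::runif(nT) < spec@ki67Fraction, "positive", "negative")
  meanOD <- .rtnorm0(n, ifelse(ki67 == "positive", spec@odMeanPositive,
                               spec@odMeanNegative), spec@odSD)

  # placement by rejection sampling on centroid distance
  cx <- numeric(n); cy <- numeric(n)
  if (n > 0) {
    for (i in seq_len(n)) {
      pairAnchor <- touching && i %% 2 == 0
      placed <- FALSE
      for (try in seq_len(maxTries)) {
        if (pairAnchor) {
          ang <- stats::runif(1, 0, 2 * pi)
          d <- 1.5 * (aAx[i] + aAx[i - 1]) / 2
          px <- cx[i - 1] + d * cos(ang)
          py <- cy[i - 1] + d * sin(ang)
        } else {
          px <- stats::runif(1, aAx[i] + 1, w - aAx[i] - 1)
          py <- stats::runif(1, aAx[i] + 1, h - aAx[i] - 1)
        }
        if (px < 2 || py < 2 || px > w - 1 || py > h - 1) next
        prev <- seq_len(i - 1)
        if (pairAnchor) prev <- setdiff(prev, i - 1)
        ok <- TRUE
        if (length(prev)) {
          dd <- sqrt((cx[prev] - px)^2 + (cy[prev] - py)^2)
          ok <- all(dd >= aAx[prev] + aAx[i] + 2)
        }
        if (ok) { cx[i] <- px; cy[i] <- py; placed <- TRUE; break }
      }
      if (!placed)
        stop("packing failure: could not place nucleus ", i, " of ", n,
             " after ", maxTries, " attempts; reduce counts or radii, or ",
             "enlarge the image")
    }
  }

  mask <- matrix(0L, h, w)
  for (i in seq_len(n))
    mask <- .rasterizeEllipse(mask, cx[i], cy[i], aAx[i], bAx[i],
                              theta[i], i)

  # drop any nucleus that lost all pixels (possible only in touching mode)
  kept <- which(tabulate(mask[mask > 0L], nbins = max(n, 1)) > 0)
  if (n > 0 && length(kept) < n) {
    remap <- integer(n); remap[kept] <- seq_along(kept)
    nz <- mask > 0L
    mask[nz] <- remap[mask[nz]]
  } else kept <- seq_len(n)

  hema <- matrix(0, h, w)
  if (length(kept)) {
    nz <- which(mask > 0L)
    hema[nz] <- meanOD[kept][mask[nz]]
    if (spec@odTextureSD > 0) {
      # chromatin texture: Gaussian grain around the nucleus mean, plus
      # class-independent extremes -- condensed-chromatin clumps (5% of
      # pixels, OD 1.2-1.6) and pale vacuoles (5%, OD 0.02-0.10). The
      # extremes are material properties of chromatin, not of the
      # nucleus' average staining: they are what makes per-pixel max/min
      # statistics unreliable while the nuclear mean stays informative.
      nPix <- length(nz)
      vals <- hema[nz] + stats::rnorm(nPix, 0, spec@odTextureSD)
      u <- stats::runif(nPix)
      dark <- u < 0.05
      pale <- u >= 0.05 & u < 0.10
      vals[dark] <- stats::runif(sum(dark), 1.2, 1.6)
      vals[pale] <- stats::runif(sum(pale), 0.02, 0.10)
      hema[nz] <- pmax(vals, 0)
    }
  }
  eos <- matrix(spec@eosinBackgroundOD, h, w)

  img <- renderStains(hema, eos, model = model, quantize = FALSE)
  if (spec@noiseSD > 0)
    img <- img + array(stats::rnorm(length(img), 0, spec@noiseSD),
                       dim(img))
  img <- round(pmax(pmin(img, 255), 0))

  # centroids of the rasterized pixel sets, 0-based, x = column
  # true_mean_od is the mean of the concentration field actually
  # rendered for the nucleus (what NHMOD estimates); latent_mean_od is
  # the sampled class-level draw. They coincide when odTextureSD = 0.
  truth <- data.frame(label = integer(0), class = character(0),
                      ki67 = character(0), true_mean_od = numeric(0),
                      centroid_x = numeric(0), centroid_y = numeric(0),
                      latent_mean_od = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(kept)) {
    nz <- which(mask > 0L)
    lab <- mask[nz]
    rowIdx <- (nz - 1L) %% h + 1L
    colIdx <- (nz - 1L) %/% h + 1L
    truth <- data.frame(
      label = seq_along(kept),
      class = cls[kept],
      ki67 = ki67[kept],
      true_mean_od = as.numeric(tapply(hema[nz], lab, mean)),
      centroid_x = as.numeric(tapply(colIdx - 1, lab, mean)),
      centroid_y = as.numeric(tapply(rowIdx - 1, lab, mean)),
      latent_mean_od = meanOD[kept],
      stringsAsFactors = FALSE)
  }

  new("SyntheticCore", rgb = img, labelMask = mask, truth = truth,
      spec = spec)
}

#' Write a synthetic core to disk
#'
#' Writes the RGB image as 8-bit PNG, the label mask as 16-bit
#' single-channel TIFF, and the truth table as CSV with header
#' \code{label,class,ki67,true_mean_od,centroid_x,centroid_y}
#' (0-based coordinates, x = column).
#'
#' @param core a \code{\linkS4class{SyntheticCore}}.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return named character vector of the three paths, invisibly.
#' @export
writeCore <- function(core, dir, prefix = "core") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pImg <- file.path(dir, paste0(prefix, ".png"))
  pMask <- file.path(dir, paste0(prefix, "_mask.tiff"))
  pTruth <- file.path(dir, paste0(prefix, "_truth.csv"))
  png::writePNG(coreImage(core) / 255, pImg)
  tiff::writeTIFF(coreLabelMask(core) / 65535,
                  pMask, bits.per.sample = 16L)
  truthCols <- c("label", "class", "ki67", "true_mean_od", "centroid_x",
                 "centroid_y")
  utils::write.csv(coreTruth(core)[, truthCols, drop = FALSE], pTruth,
                   row.names = FALSE)
  invisible(c(image = pImg, mask = pMask, truth = pTruth))
}

#' Read an 8-bit RGB raster (PNG or TIFF) as a 0-255 array
#'
#' @param path image file; format chosen by extension.
#' @return numeric H x W x 3 array with values 0-255.
#' @export
readRGBImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported raster format: .", ext))
  if (length(dim(img)) == 3 && dim(img)[3] == 4)
    img <- img[, , 1:3, drop = FALSE]
  .checkRGB(img)
  round(img * 255)
}

#' Read a 16-bit label mask written by \code{\link{writeCore}}
#'
#' @param path TIFF file.
#' @return integer label matrix.
#' @export
readLabelMask <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}
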