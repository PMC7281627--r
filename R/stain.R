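# Beer-Lambert optical-density transform and H&E color deconvolution.
# Convention: RGB images are numeric H x W x 3 arrays with 8-bit values
# (0-255); OD is base-10 absorbance, intensities floored at 1 before the
# log so OD stays finite.

#' Construct a StainModel
#'
#' @param stainMatrix 3x3 numeric matrix, rows = stain OD vectors
#'   (hematoxylin, eosin, residual). Rows are renormalized to unit length.
#' @param backgroundIntensity per-channel background intensity I0; a single
#'   value is recycled to all three channels.
#' @return a validated \code{\linkS4class{StainModel}}.
#' @export
stainModel <- function(stainMatrix, backgroundIntensity = 255) {
  stainMatrix <- as.matrix(stainMatrix)
  norms <- sqrt(rowSums(stainMatrix^2))
  if (any(norms == 0)) stop("stain vectors must be non-zero")
  stainMatrix <- stainMatrix / norms
  dimnames(stainMatrix) <- list(c("hematoxylin", "eosin", "residual"),
                                c("R", "G", "B"))
  if (length(backgroundIntensity) == 1)
    backgroundIntensity <- rep(backgroundIntensity, 3)
  new("StainModel", stainMatrix = stainMatrix,
      backgroundIntensity = as.numeric(backgroundIntensity))
}

#' Default H&E stain model
#'
#' The classical Ruifrok-Johnston hematoxylin and eosin absorbance vectors
#' with a residual direction constructed as their normalized cross product,
#' and background intensity I0 = 255 on all channels. Used whenever
#' slide-specific stain vectors are not supplied.
#'
#' @return a \code{\linkS4class{StainModel}}.
#' @examples
#' m <- defaultHEModel()
#' sqrt(rowSums(stainMatrix(m)^2))  # all 1
#' @export
defaultHEModel <- function() {
  h <- c(0.65, 0.70, 0.29)
  e <- c(0.07, 0.99, 0.11)
  h <- h / sqrt(sum(h^2))
  e <- e / sqrt(sum(e^2))
  r <- c(h[2] * e[3] - h[3] * e[2],
         h[3] * e[1] - h[1] * e[3],
         h[1] * e[2] - h[2] * e[1])
  r <- r / sqrt(sum(r^2))
  stainModel(rbind(h, e, r), 255)
}

.checkRGB <- function(image) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("expected a 3-channel (H x W x 3) RGB image, got dims: ",
         paste(dim(image), collapse = " x "))
}

#' RGB to optical density
#'
#' Per-channel Beer-Lambert transform \eqn{OD = -\log_{10}(\max(I,1)/I_0)}.
#' Monotone decreasing in intensity; intensities are floored at 1 so the
#' result is finite everywhere.
#'
#' @param image numeric H x W x 3 array, 8-bit values.
#' @param model a \code{\linkS4class{StainModel}} supplying I0.
#' @return H x W x 3 array of optical densities (>= 0).
#' @export
rgbToOD <- function(image, model = defaultHEModel()) {
  .checkRGB(image)
  I0 <- backgroundIntensity(model)
  od <- array(0, dim(image))
  for (ch in 1:3)
    od[, , ch] <- -log10(pmax(pmin(image[, , ch], I0[ch]), 1) / I0[ch])
  od
}

#' Optical density to RGB (forward Beer-Lambert render)
#'
#' Inverse of \code{\link{rgbToOD}} up to 8-bit quantization:
#' \eqn{I = round(I_0 \cdot 10^{-OD})}, clipped to [0, 255].
#'
#' @param od H x W x 3 array of optical densities.
#' @param model a \code{\linkS4class{StainModel}}.
#' @param quantize round to integer 8-bit values (default TRUE).
#' @return H x W x 3 numeric array of intensities.
#' @export
odToRGB <- function(od, model = defaultHEModel(), quantize = TRUE) {
  .checkRGB(od)
  I0 <- backgroundIntensity(model)
  img <- array(0, dim(od))
  for (ch in 1:3) {
    v <- I0[ch] * 10^(-od[, , ch])
    img[, , ch] <- pmax(pmin(v, 255), 0)
  }
  if (quantize) img <- round(img)
  img
}

#' H&E color deconvolution
#'
#' Solves the per-pixel linear system \eqn{OD = M^T c} for the stain
#' concentrations c by inverting the stain matrix (Ruifrok-Johnston color
#' deconvolution). Negative concentrations are clamped to zero. The
#' hematoxylin map feeds all downstream NHMOD computation.
#'
#' @param od H x W x 3 OD array from \code{\link{rgbToOD}}.
#' @param model a \code{\linkS4class{StainModel}}; must be invertible.
#' @return a \code{\linkS4class{StainMaps}} object.
#' @export
deconvolve <- function(od, model = defaultHEModel()) {
  .checkRGB(od)
  M <- stainMatrix(model)
  if (rcond(M) < 1e-10) {
    # name the near-parallel pair for the error message
    nm <- c("hematoxylin", "eosin", "residual")
    cs <- abs(c(sum(M[1, ] * M[2, ]), sum(M[1, ] * M[3, ]),
                sum(M[2, ] * M[3, ])))
    pair <- list(c(1, 2), c(1, 3), c(2, 3))[[which.max(cs)]]
    stop("stain matrix is singular: vectors '", nm[pair[1]], "' and '",
         nm[pair[2]], "' are (near) collinear")
  }
  d <- dim(od)
  odMat <- matrix(od, nrow = d[1] * d[2], ncol = 3)
  conc <- odMat %*% solve(M)  # OD_row = c_row %*% M  =>  c = OD %*% M^-1
  conc[conc < 0] <- 0
  new("StainMaps",
      hematoxylin = matrix(conc[, 1], d[1], d[2]),
      eosin = matrix(conc[, 2], d[1], d[2]),
      residual = matrix(conc[, 3], d[1], d[2]))
}

#' Render stain concentrations to an RGB image
#'
#' Forward model: builds the OD image \eqn{OD = M^T c} from concentration
#' maps and converts to 8-bit RGB. The synthetic-core generator and the
#' round-trip tests are built on this.
#'
#' @param hematoxylin,eosin,residual concentration matrices (missing maps
#'   are taken as zero).
#' @param model a \code{\linkS4class{StainModel}}.
#' @param quantize round to 8-bit (default TRUE).
#' @return H x W x 3 numeric RGB array.
#' @export
renderStains <- function(hematoxylin, eosin = NULL, residual = NULL,
                         model = defaultHEModel(), quantize = TRUE) {
  d <- dim(hematoxylin)
  if (is.null(eosin)) eosin <- matrix(0, d[1], d[2])
  if (is.null(residual)) residual <- matrix(0, d[1], d[2])
  M <- stainMatrix(model)
  conc <- cbind(as.vector(hematoxylin), as.vector(eosin),
                as.vector(residual))
  odMat <- conc %*% M
  od <- array(odMat, c(d[1], d[2], 3))
  odToRGB(od, model, quantize = quantize)
}

#' Read or write a StainModel as YAML
#'
#' Serialization stores the nine stain-matrix entries (row-major, rows
#' hematoxylin/eosin/residual) and the background intensity.
#'
#' @param model a \code{\linkS4class{StainModel}}.
#' @param path file path.
#' @return \code{readStainModel} returns a \code{StainModel};
#'   \code{writeStainModel} returns \code{path} invisibly.
#' @export
writeStainModel <- function(model, path) {
  M <- stainMatrix(model)
  obj <- list(
    hematoxylin = as.numeric(M[1, ]),
    eosin = as.numeric(M[2, ]),
    residual = as.numeric(M[3, ]),
    background_intensity = as.numeric(backgroundIntensity(model)))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname writeStainModel
#' @export
readStainModel <- function(path) {
  obj <- yaml::read_yaml(path)
  stainModel(rbind(obj$hematoxylin, obj$eosin, obj$residual),
             obj$background_intensity)
}
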