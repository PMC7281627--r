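# False color map: each nucleus recolored by its NHMOD through a
# blue-to-yellow ramp and overlaid on the source H&E image. The default
# five-point ramp (blue, cyan, green, red, yellow) fixes "red" at
# position 0.75, which makes the core-level ">10% red or more" rule a
# well-defined computation.

.defaultControlColors <- function() {
  rbind(blue = c(0, 0, 255),
        cyan = c(0, 255, 255),
        green = c(0, 255, 0),
        red = c(255, 0, 0),
        yellow = c(255, 255, 0))
}

#' Construct a color ramp
#'
#' @param valueRange measurement values (OD units) mapped to ramp
#'   positions 0 and 1; low < high.
#' @param positions control positions, strictly increasing from 0 to 1.
#' @param colors matrix of 8-bit RGB rows, one per control position.
#' @param redPosition position of the "red" level (default 0.75).
#' @return a \code{\linkS4class{ColorRamp}}.
#' @export
colorRamp2 <- function(valueRange,
                       positions = c(0, 0.25, 0.5, 0.75, 1),
                       colors = .defaultControlColors(),
                       redPosition = 0.75) {
  new("ColorRamp", positions = positions, colors = colors,
      valueRange = as.numeric(valueRange), redPosition = redPosition)
}

#' Default blue-to-yellow ramp over observed values
#'
#' Blue maps to the lowest observed value and yellow to the highest, with
#' cyan, green and red in between (red at position 0.75). A degenerate
#' (constant) value set has its range expanded by a small epsilon so the
#' mapping stays defined and every nucleus takes one color.
#'
#' @param values observed measurement values (nonempty), or their range.
#' @param valueRange optional explicit range override (e.g. a fixed
#'   TMA-global range).
#' @return a \code{\linkS4class{ColorRamp}}.
#' @export
defaultRamp <- function(values, valueRange = NULL) {
  if (is.null(valueRange)) {
    values <- values[is.finite(values)]
    if (!length(values)) stop("cannot build a ramp from no values")
    valueRange <- range(values)
    if (diff(valueRange) == 0)
      valueRange <- valueRange + c(-1, 1) * max(1e-6, abs(valueRange[1]) * 1e-6)
  }
  colorRamp2(valueRange)
}

#' Evaluate a ramp at measurement values
#'
#' Values are normalized to (v - low)/(high - low), clamped to [0, 1],
#' and each RGB channel is linearly interpolated between the control
#' points.
#'
#' @param ramp a \code{\linkS4class{ColorRamp}}.
#' @param values numeric measurement values.
#' @return n x 3 matrix of 8-bit RGB colors (rounded).
#' @export
rampColor <- function(ramp, values) {
  t <- (values - ramp@valueRange[1]) / diff(ramp@valueRange)
  t <- pmin(pmax(t, 0), 1)
  out <- vapply(1:3, function(ch)
    stats::approx(ramp@positions, ramp@colors[, ch], xout = t,
                  rule = 2)$y, numeric(length(t)))
  out <- matrix(out, ncol = 3)
  colnames(out) <- c("r", "g", "b")
  round(out)
}

#' Render the false color map
#'
#' Every nucleus is filled with the single ramp color of its NHMOD;
#' background pixels pass through the source image. The legend strip
#' renders the ramp from low (left) to high (right).
#'
#' @param mask integer label mask.
#' @param records feature table with one row per mask label (column
#'   \code{nhmod}, or \code{featureName}).
#' @param ramp a \code{\linkS4class{ColorRamp}}.
#' @param source H x W x 3 source RGB array (0-255) of the same shape.
#' @param featureName measurement column to map (default \code{"nhmod"}).
#' @return a \code{\linkS4class{FalseColorMap}}.
#' @export
renderFCM <- function(mask, records, ramp, source,
                      featureName = "nhmod") {
  if (!identical(dim(mask), dim(source)[1:2]))
    stop("mask and source image must share the same shape")
  labs <- sort(unique(as.integer(mask[mask > 0])))
  miss <- setdiff(labs, records$label)
  if (length(miss))
    stop("no record for mask label(s): ", paste(miss, collapse = ", "))
  ord <- match(labs, records$label)
  cols <- rampColor(ramp, records[[featureName]][ord])
  overlay <- source
  h <- nrow(mask)
  nz <- which(mask > 0L)
  lab2row <- integer(if (length(labs)) max(labs) else 0)
  lab2row[labs] <- seq_along(labs)
  ri <- lab2row[mask[nz]]
  for (ch in 1:3) overlay[nz + (ch - 1L) * length(mask)] <- cols[ri, ch]
  legend <- array(0, c(24, 256, 3))
  legendCols <- rampColor(
    ramp, seq(ramp@valueRange[1], ramp@valueRange[2], length.out = 256))
  for (ch in 1:3)
    legend[, , ch] <- matrix(legendCols[, ch], 24, 256, byrow = TRUE)
  new("FalseColorMap", overlay = overlay, legend = legend,
      perNucleusColor = data.frame(label = labs, r = cols[, 1],
                                   g = cols[, 2], b = cols[, 3]),
      ramp = ramp)
}

#' Write a false color map to disk
#'
#' Writes the overlay and legend as 8-bit PNG and the per-nucleus colors
#' as CSV (label,r,g,b).
#'
#' @param fcm a \code{\linkS4class{FalseColorMap}}.
#' @param path overlay PNG path.
#' @param legendPath optional legend PNG path.
#' @param colorTablePath optional CSV path.
#' @return named vector of written paths, invisibly.
#' @export
writeFCM <- function(fcm, path, legendPath = NULL,
                     colorTablePath = NULL) {
  png::writePNG(fcm@overlay / 255, path)
  out <- c(overlay = path)
  if (!is.null(legendPath)) {
    png::writePNG(fcm@legend / 255, legendPath)
    out <- c(out, legend = legendPath)
  }
  if (!is.null(colorTablePath)) {
    utils::write.csv(fcm@perNucleusColor, colorTablePath,
                     row.names = FALSE)
    out <- c(out, colors = colorTablePath)
  }
  invisible(out)
}
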