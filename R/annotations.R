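# GeoJSON region annotations (the QuPath export dialect): polygons with a
# classification name; nuclei inherit the class of the polygon containing
# their centroid. Coordinates are image pixels, 0-based, x = column.

# Ray-casting point-in-polygon (even-odd rule) for one ring given as a
# two-column matrix; vertices need not repeat the first point.
.pointInRing <- function(px, py, ring) {
  n <- nrow(ring)
  if (n >= 2 && all(ring[1, ] == ring[n, ])) {
    ring <- ring[-n, , drop = FALSE]
    n <- n - 1L
  }
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

.ringMatrix <- function(coords, featureIndex) {
  m <- try(do.call(rbind, lapply(coords, function(pt)
    as.numeric(unlist(pt)[1:2]))), silent = TRUE)
  if (inherits(m, "try-error") || any(!is.finite(m)) || nrow(m) < 3)
    stop("malformed polygon geometry in feature ", featureIndex)
  m
}

#' Read polygon annotations from GeoJSON
#'
#' Parses a FeatureCollection of Polygon/MultiPolygon features carrying a
#' class name in \code{properties$classification$name} (the QuPath
#' convention) or \code{properties$class}. Recognized names: Tumor,
#' Stroma, Ki67pos, Ki67neg (case-insensitive).
#'
#' @param path GeoJSON file.
#' @return list of annotations, each with \code{class} (normalized name)
#'   and \code{rings} (list of two-column coordinate matrices; for a
#'   polygon with holes the first ring is the shell).
#' @export
readAnnotations <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (!is.null(gj$features)) gj$features else list()
  out <- list()
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    g <- f$geometry
    if (is.null(g) || is.null(g$type))
      stop("malformed geometry in feature ", i)
    cls <- f$properties$classification$name
    if (is.null(cls)) cls <- f$properties$class
    if (is.null(cls)) cls <- "unassigned"
    polys <- switch(g$type,
      Polygon = list(g$coordinates),
      MultiPolygon = g$coordinates,
      stop("feature ", i, ": unsupported geometry type '", g$type, "'"))
    for (p in polys)
      out[[length(out) + 1L]] <- list(
        class = tolower(as.character(cls)),
        rings = lapply(p, .ringMatrix, featureIndex = i))
  }
  out
}

# Containment in a polygon with holes: inside the shell and in an even
# number of hole rings (even-odd over all rings).
.inPolygon <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  for (r in rings) inside <- xor(inside, .pointInRing(px, py, r))
  inside
}

#' Assign annotation classes to nuclei by centroid containment
#'
#' Each nucleus inherits the class of the polygon containing its
#' centroid: Tumor/Stroma fill \code{class_label}, Ki67pos/Ki67neg fill
#' \code{ki67_truth}. Nuclei contained in no polygon stay unassigned.
#' Later annotations win where polygons overlap.
#'
#' @param records feature table with \code{centroid_x}, \code{centroid_y}
#'   (0-based pixels).
#' @param annotations result of \code{\link{readAnnotations}}.
#' @return the records with class fields filled.
#' @export
assignAnnotations <- function(records, annotations) {
  if (!nrow(records)) return(records)
  px <- records$centroid_x; py <- records$centroid_y
  for (a in annotations) {
    hit <- .inPolygon(px, py, a$rings)
    if (!any(hit)) next
    if (a$class %in% c("tumor", "stroma"))
      records$class_label[hit] <- a$class
    else if (a$class == "ki67pos") records$ki67_truth[hit] <- "positive"
    else if (a$class == "ki67neg") records$ki67_truth[hit] <- "negative"
  }
  records
}
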