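# Per-nucleus morphometric and densitometric features. The central
# quantity is NHMOD: the arithmetic mean of the deconvolved hematoxylin
# concentration over the nucleus mask (not the raw blue channel).

.featureColumns <- c("area", "perimeter", "circularity", "eccentricity",
                     "max_caliper", "min_caliper", "nhmod", "hema_od_sum",
                     "hema_od_max", "hema_od_min", "hema_od_sd",
                     "hema_od_range", "eosin_od_mean")

#' Names of the numeric nuclear feature columns
#'
#' @return character vector of feature column names in table order.
#' @export
nuclearFeatureNames <- function() .featureColumns

# Crofton perimeter (2 directions): P = pi/4 * (horizontal + vertical
# boundary crossings), computed on a zero-padded binary submask.
.croftonPerimeter <- function(B) {
  B <- rbind(0L, cbind(0L, B, 0L), 0L)
  ix <- sum(B[, -1] != B[, -ncol(B)])
  iy <- sum(B[-1, ] != B[-nrow(B), ])
  pi / 4 * (ix + iy)
}

# Caliper (Feret) diameters from the convex hull of pixel centers; the +1
# accounts for pixel extent. minimum caliper by projection over 1-degree
# rotations.
.calipers <- function(xs, ys) {
  if (length(xs) == 1) return(c(1, 1))
  hull <- grDevices::chull(xs, ys)
  hx <- xs[hull]; hy <- ys[hull]
  dmax <- sqrt(max(outer(hx, hx, "-")^2 + outer(hy, hy, "-")^2))
  ang <- seq(0, pi, length.out = 181)[-181]
  proj <- outer(hx, cos(ang)) + outer(hy, sin(ang))
  widths <- apply(proj, 2, max) - apply(proj, 2, min)
  c(dmax + 1, min(widths) + 1)
}

#' Compute per-nucleus features
#'
#' One record per label, ordered by label: area, Crofton perimeter,
#' circularity (4 pi A / P^2), eccentricity (from central second moments),
#' maximum and minimum caliper, the hematoxylin OD statistics over the
#' nucleus pixels -- mean (NHMOD), sum, max, min, sd, range -- and the
#' mean eosin OD. Class and Ki67 fields are initialized unassigned.
#'
#' @param mask integer label matrix from \code{\link{detectNuclei}} (or a
#'   ground-truth mask).
#' @param stains a \code{\linkS4class{StainMaps}} of the same shape.
#' @return data.frame with columns \code{label}, \code{centroid_x},
#'   \code{centroid_y}, the features of \code{\link{nuclearFeatureNames}},
#'   and \code{class_label}, \code{ki67_truth}, \code{ki67_pred}.
#' @export
nucleusFeatures <- function(mask, stains) {
  hem <- hematoxylinMap(stains)
  if (!identical(dim(mask), dim(hem)))
    stop("label mask and stain maps must share the same shape")
  eos <- eosinMap(stains)
  h <- nrow(mask)
  nz <- which(mask > 0L)
  labs <- sort(unique(as.integer(mask[nz])))
  out <- data.frame(label = labs,
                    centroid_x = NA_real_, centroid_y = NA_real_)
  for (col in .featureColumns) out[[col]] <- NA_real_
  if (!length(labs)) {
    out$class_label <- character(0)
    out$ki67_truth <- character(0)
    out$ki67_pred <- character(0)
    return(out)
  }
  idxByLab <- split(nz, mask[nz])
  for (k in seq_along(labs)) {
    idx <- idxByLab[[as.character(labs[k])]]
    rows <- (idx - 1L) %% h + 1L
    cols <- (idx - 1L) %/% h + 1L
    xs <- cols - 1; ys <- rows - 1     # 0-based, x = column
    area <- length(idx)
    out$centroid_x[k] <- mean(xs)
    out$centroid_y[k] <- mean(ys)
    out$area[k] <- area
    # binary submask for the perimeter
    B <- matrix(0L, diff(range(rows)) + 1L, diff(range(cols)) + 1L)
    B[cbind(rows - min(rows) + 1L, cols - min(cols) + 1L)] <- 1L
    P <- .croftonPerimeter(B)
    out$perimeter[k] <- P
    out$circularity[k] <- 4 * pi * area / P^2
    mu20 <- mean((xs - mean(xs))^2)
    mu02 <- mean((ys - mean(ys))^2)
    mu11 <- mean((xs - mean(xs)) * (ys - mean(ys)))
    common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
    l1 <- (mu20 + mu02 + common) / 2
    l2 <- (mu20 + mu02 - common) / 2
    out$eccentricity[k] <- if (l1 > 0) sqrt(pmax(1 - l2 / l1, 0)) else 0
    cal <- .calipers(xs, ys)
    out$max_caliper[k] <- cal[1]
    out$min_caliper[k] <- cal[2]
    hv <- hem[idx]
    out$nhmod[k] <- mean(hv)
    out$hema_od_sum[k] <- sum(hv)
    out$hema_od_max[k] <- max(hv)
    out$hema_od_min[k] <- min(hv)
    out$hema_od_sd[k] <- if (area > 1) stats::sd(hv) else 0
    out$hema_od_range[k] <- max(hv) - min(hv)
    out$eosin_od_mean[k] <- mean(eos[idx])
  }
  out$class_label <- rep("unassigned", length(labs))
  out$ki67_truth <- rep("unknown", length(labs))
  out$ki67_pred <- rep("uncalled", length(labs))
  out
}

#' Attach ground-truth labels to measured nuclei
#'
#' Matches a measured label mask to a ground-truth mask by IoU
#' (\code{\link{matchToTruth}}) and copies the truth table's class and
#' Ki67 state onto the matched records. When the features were computed
#' directly on the truth mask the match is the identity.
#'
#' @param records feature table from \code{\link{nucleusFeatures}}.
#' @param mask the label mask the records were measured on.
#' @param core a \code{\linkS4class{SyntheticCore}} (or list with
#'   \code{labelMask} and \code{truth}).
#' @return the records with \code{class_label} and \code{ki67_truth}
#'   filled for matched nuclei.
#' @export
attachTruth <- function(records, mask, core) {
  truthMask <- if (is(core, "SyntheticCore")) coreLabelMask(core)
               else core$labelMask
  truth <- if (is(core, "SyntheticCore")) coreTruth(core) else core$truth
  m <- matchToTruth(mask, truthMask)
  if (nrow(m$pairs)) {
    i <- match(m$pairs$pred_label, records$label)
    j <- match(m$pairs$truth_label, truth$label)
    records$class_label[i] <- truth$class[j]
    records$ki67_truth[i] <- truth$ki67[j]
  }
  records
}

#' Write / read a nucleus feature table as CSV
#'
#' Column order is stable (label, centroids, features, class fields); a
#' round-trip read returns records equal to the input.
#'
#' @param records feature data.frame.
#' @param path CSV path.
#' @return \code{readFeatureTable} returns the data.frame;
#'   \code{writeFeatureTable} returns \code{path} invisibly.
#' @export
writeFeatureTable <- function(records, path) {
  cols <- c("label", "centroid_x", "centroid_y", .featureColumns,
            "class_label", "ki67_truth", "ki67_pred")
  utils::write.csv(records[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(label = "integer",
                                 class_label = "character",
                                 ki67_truth = "character",
                                 ki67_pred = "character"))
}
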