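# Nuclei separation by distance-transform watershed and region measurement.

# Euclidean distance transform treating pixels outside the frame as
# background (mask is padded with a 1-px background ring).
.distmapPadded <- function(raster) {
  nr <- nrow(raster); nc <- ncol(raster)
  p <- matrix(0, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- raster * 1
  d <- EBImage::distmap(p)
  d[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
}

# Eccentricity of a pixel region from central second moments:
# sqrt(1 - lambda_minor / lambda_major).
.regionEccentricity <- function(rows, cols) {
  if (length(rows) < 2L) return(0)
  r <- rows - mean(rows); c <- cols - mean(cols)
  mrr <- mean(r * r); mcc <- mean(c * c); mrc <- mean(r * c)
  tr <- mrr + mcc
  det <- mrr * mcc - mrc * mrc
  disc <- sqrt(max(0, tr * tr / 4 - det))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  if (l1 <= 0) return(0)
  sqrt(max(0, 1 - l2 / l1))
}

.regionTable <- function(lab, cal, scaleFactor = 1L) {
  n <- max(lab)
  if (n == 0L)
    return(data.frame(label = integer(), area_px = integer(),
                      area_um2 = numeric(), centroid_row = numeric(),
                      centroid_col = numeric(), bbox_row_min = integer(),
                      bbox_row_max = integer(), bbox_col_min = integer(),
                      bbox_col_max = integer(), eccentricity = numeric()))
  idx <- which(lab > 0L)
  l <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  effPx <- cal@pixelSizeUm / scaleFactor
  tab <- data.frame(
    label = seq_len(n),
    area_px = as.integer(tabulate(l, n)),
    area_um2 = tabulate(l, n) * effPx^2,
    centroid_row = as.numeric(tapply(rows, l, mean)),
    centroid_col = as.numeric(tapply(cols, l, mean)),
    bbox_row_min = as.integer(tapply(rows, l, min)),
    bbox_row_max = as.integer(tapply(rows, l, max)),
    bbox_col_min = as.integer(tapply(cols, l, min)),
    bbox_col_max = as.integer(tapply(cols, l, max)),
    eccentricity = vapply(seq_len(n), function(k) {
      sel <- l == k
      .regionEccentricity(rows[sel], cols[sel])
    }, numeric(1))
  )
  rownames(tab) <- NULL
  tab
}

#' Separate clustered nuclei with a distance-transform watershed
#'
#' Markers are the regional maxima of the Euclidean distance transform of
#' the mask, after suppression of maxima shallower than
#' `hDepth * max(distance)` and closer together than
#' `minPeakSeparationPx`; flooding the negated distance transform
#' restricted to the mask assigns every foreground pixel to exactly one
#' label.
#'
#' @param mask preprocessed nuclear-channel [BinaryMask-class].
#' @param minPeakSeparationPx minimum marker separation (px).
#' @param hDepth marker suppression depth, as a fraction of the global
#'   maximum distance value.
#' @return a [LabeledRegions-class]; an empty mask yields zero regions.
#' @export
splitTouchingNuclei <- function(mask, minPeakSeparationPx = 10,
                                hDepth = 0.2) {
  r <- mask@raster
  if (!any(r)) {
    return(new("LabeledRegions",
               labelRaster = matrix(0L, nrow(r), ncol(r)),
               regionTable = .regionTable(matrix(0L, 1, 1), mask@calibration),
               calibration = mask@calibration))
  }
  d <- .distmapPadded(r)
  # the maxima-detection neighbourhood is a box of the given radius, so
  # half the stated separation suppresses markers closer than it
  ws <- EBImage::watershed(d, tolerance = hDepth * max(d),
                           ext = max(1L, ceiling(minPeakSeparationPx / 2)))
  lab <- matrix(as.integer(ws), nrow(r), ncol(r))
  # relabel consecutively in row-major first-occurrence order
  u <- unique(lab[lab > 0L])
  if (length(u) && !identical(sort(u), seq_along(u))) {
    map <- integer(max(u)); map[u] <- seq_along(u)
    lab[lab > 0L] <- map[lab[lab > 0L]]
  }
  new("LabeledRegions", labelRaster = lab,
      regionTable = .regionTable(lab, mask@calibration, mask@scaleFactor),
      calibration = mask@calibration)
}

#' @rdname LabeledRegions
#' @export
setMethod("regionTable", "LabeledRegions", function(object) object@regionTable)

#' @rdname LabeledRegions
#' @export
setMethod("labelRaster", "LabeledRegions", function(object) object@labelRaster)

#' @rdname LabeledRegions
#' @export
setMethod("regionCount", "LabeledRegions",
          function(object) nrow(object@regionTable))

setMethod("show", "LabeledRegions", function(object) {
  n <- regionCount(object)
  cat(sprintf("LabeledRegions: %d region(s)\n", n))
  if (n > 0)
    cat(sprintf("  mean area %.2f um^2 (range %.2f-%.2f)\n",
                mean(object@regionTable$area_um2),
                min(object@regionTable$area_um2),
                max(object@regionTable$area_um2)))
})

#' Summary statistics over labelled nucleus regions
#'
#' @param regions a [LabeledRegions-class].
#' @param cal calibration used for physical areas (defaults to the
#'   regions' own calibration).
#' @return list with `count`, `area_um2` (per region), `mean_area_um2`
#'   (`NA` with `undefined = TRUE` when there are no regions).
#' @export
measureRegions <- function(regions, cal = calibration(regions)) {
  areas <- regions@regionTable$area_px * cal@pixelSizeUm^2
  n <- length(areas)
  list(count = n,
       area_um2 = areas,
       mean_area_um2 = if (n > 0) mean(areas) else NA_real_,
       undefined = n == 0)
}
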