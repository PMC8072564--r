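# Reading/writing calibrated two-channel 16-bit TIFF frames and QC overlays.

#' Construct a MicrographFrame from channel matrices
#'
#' @param nuclear,neurite integer matrices of 16-bit intensities.
#' @param cal a [Calibration-class] matching the channel dimensions.
#' @param frameId identifier string.
#' @param condition named list (`compound`, `concentrationNM`, `isControl`,
#'   `experimentId`); missing entries are filled with defaults.
#' @return a [MicrographFrame-class].
#' @export
micrographFrame <- function(nuclear, neurite, cal, frameId = "frame",
                            condition = list()) {
  cond <- utils::modifyList(
    list(compound = NA_character_, concentrationNM = NA_real_,
         isControl = FALSE, experimentId = NA_character_),
    condition)
  storage.mode(nuclear) <- "integer"
  storage.mode(neurite) <- "integer"
  new("MicrographFrame", nuclearChannel = nuclear, neuriteChannel = neurite,
      calibration = cal, frameId = as.character(frameId), condition = cond)
}

#' @rdname MicrographFrame
#' @export
setMethod("nuclearChannel", "MicrographFrame", function(object) object@nuclearChannel)

#' @rdname MicrographFrame
#' @export
setMethod("neuriteChannel", "MicrographFrame", function(object) object@neuriteChannel)

#' @rdname MicrographFrame
#' @export
setMethod("frameId", "MicrographFrame", function(object) object@frameId)

setMethod("show", "MicrographFrame", function(object) {
  d <- dim(object@nuclearChannel)
  cat(sprintf("MicrographFrame '%s': %d x %d px, 2 channels (nuclear, neurite)\n",
              object@frameId, d[2], d[1]))
  cat(sprintf("  condition: %s @ %s nM%s\n", object@condition$compound,
              format(object@condition$concentrationNM),
              if (isTRUE(object@condition$isControl)) " (control)" else ""))
  show(object@calibration)
})

#' Read a calibrated two-channel 16-bit TIFF frame
#'
#' Expects a two-page 16-bit grayscale TIFF; page order is `channelOrder`
#' (default: page 1 = nuclear stain, page 2 = neurite stain). No intensity
#' rescaling is applied. Files with a page count other than two, or with a
#' sample format other than 16-bit grayscale, are rejected.
#'
#' @param path path to the TIFF file.
#' @param cal a [Calibration-class]; must match the image dimensions.
#' @param condition condition list, see [micrographFrame()].
#' @param frameId identifier; defaults to the file name without extension.
#' @param channelOrder character vector naming the page order, a permutation
#'   of `c("nuclear", "neurite")`.
#' @return a [MicrographFrame-class].
#' @export
readFrame <- function(path, cal, condition = list(),
                      frameId = sub("\\.[^.]*$", "", basename(path)),
                      channelOrder = c("nuclear", "neurite")) {
  if (!file.exists(path)) stop("file not found: ", path)
  stopifnot(identical(sort(channelOrder), c("neurite", "nuclear")))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (length(pages) != 2L)
    stop("expected a two-page TIFF, found ", length(pages), " page(s): ", path)
  for (pg in pages) {
    bps <- attr(pg, "bits.per.sample")
    if (is.null(bps) || bps != 16L)
      stop("expected 16-bit samples, found ",
           if (is.null(bps)) "unknown" else bps, "-bit: ", path)
    if (length(dim(pg)) != 2L)
      stop("expected single-sample (grayscale) pages: ", path)
  }
  chans <- list()
  for (i in 1:2) {
    m <- pages[[i]]
    attributes(m) <- list(dim = dim(m))
    storage.mode(m) <- "integer"
    chans[[channelOrder[i]]] <- m
  }
  micrographFrame(chans$nuclear, chans$neurite, cal, frameId, condition)
}

#' Write a frame as a two-page 16-bit TIFF
#'
#' Inverse of [readFrame()] under the default channel order; the round trip
#' is bit-exact.
#'
#' @param frame a [MicrographFrame-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFrame <- function(frame, path) {
  tiff::writeTIFF(list(frame@nuclearChannel / 65535,
                       frame@neuriteChannel / 65535),
                  path, bits.per.sample = 16L)
  invisible(path)
}

#' Construct a BinaryMask
#'
#' @param raster logical (or coercible) matrix.
#' @param cal source-frame [Calibration-class].
#' @param scaleFactor mask pixels per source pixel along each axis.
#' @return a [BinaryMask-class].
#' @export
binaryMask <- function(raster, cal, scaleFactor = 1L) {
  r <- matrix(as.logical(raster), nrow(raster), ncol(raster))
  new("BinaryMask", raster = r, scaleFactor = as.integer(scaleFactor),
      calibration = cal)
}

#' @rdname BinaryMask
#' @export
setMethod("scaleFactor", "BinaryMask", function(object) object@scaleFactor)

#' @rdname BinaryMask
#' @export
setMethod("maskRaster", "BinaryMask", function(object) object@raster)

#' @rdname BinaryMask
#' @export
setMethod("scaleFactor", "NeuriteSkeleton", function(object) object@scaleFactor)

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask: %d x %d px (scale %dx, %.5f um/px), %d fg px (%.1f%%)\n",
              ncol(object@raster), nrow(object@raster), object@scaleFactor,
              object@calibration@pixelSizeUm / object@scaleFactor,
              sum(object@raster), 100 * mean(object@raster)))
})

#' Write an RGB QC overlay as 8-bit PNG
#'
#' Renders the neurite channel in gray, an optional binary mask in green,
#' an optional (dilated) skeleton in red and an optional soma mask in blue.
#'
#' @param frame a [MicrographFrame-class].
#' @param path output PNG path.
#' @param mask optional [BinaryMask-class] at source scale.
#' @param skeleton optional [NeuriteSkeleton-class]; drawn dilated by 1 px
#'   at source scale.
#' @param somaMask optional [BinaryMask-class] at source scale.
#' @return `path`, invisibly.
#' @export
writeOverlayPng <- function(frame, path, mask = NULL, skeleton = NULL,
                            somaMask = NULL) {
  base <- frame@neuriteChannel
  g <- base / max(1L, max(base))
  rgb <- array(rep(g * 0.8, 3), dim = c(nrow(g), ncol(g), 3))
  if (!is.null(mask)) {
    m <- mask@raster
    rgb[, , 2][m] <- pmin(1, rgb[, , 2][m] + 0.4)
  }
  if (!is.null(somaMask)) {
    s <- somaMask@raster
    rgb[, , 3][s] <- pmin(1, rgb[, , 3][s] + 0.6)
  }
  if (!is.null(skeleton) && nrow(skeleton@points) > 0) {
    f <- skeleton@scaleFactor
    rr <- pmax(1L, pmin(nrow(g), as.integer(round(skeleton@points$y / f)) + 1L))
    cc <- pmax(1L, pmin(ncol(g), as.integer(round(skeleton@points$x / f)) + 1L))
    for (dr in -1:1) for (dc in -1:1) {
      r2 <- pmax(1L, pmin(nrow(g), rr + dr))
      c2 <- pmax(1L, pmin(ncol(g), cc + dc))
      rgb[, , 1][cbind(r2, c2)] <- 1
    }
  }
  png::writePNG(rgb, path)
  invisible(path)
}
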