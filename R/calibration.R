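# Calibration, unit conversion, and shared accessors.

#' Default pixel size (um per pixel edge)
#'
#' 884.89 um / 1376 px at the reference frame geometry.
#' @export
DEFAULT_PIXEL_SIZE_UM <- 884.89 / 1376

#' Construct a frame calibration
#'
#' @param frameWidthPx,frameHeightPx frame size in pixels.
#' @param physicalWidthUm,physicalHeightUm physical extents in um. By
#'   default derived from `pixelSizeUm` so any frame size is consistent.
#' @param pixelSizeUm um per pixel edge; defaults to
#'   [DEFAULT_PIXEL_SIZE_UM].
#' @return a [Calibration-class] object.
#' @examples
#' cal <- Calibration()                      # 1376 x 1038 reference frame
#' lengthUm(10, cal)                         # ~6.43 um
#' @export
Calibration <- function(frameWidthPx = 1376L, frameHeightPx = 1038L,
                        physicalWidthUm = pixelSizeUm * frameWidthPx,
                        physicalHeightUm = pixelSizeUm * frameHeightPx,
                        pixelSizeUm = DEFAULT_PIXEL_SIZE_UM) {
  new("Calibration",
      pixelSizeUm = physicalWidthUm / frameWidthPx,
      frameWidthPx = as.integer(frameWidthPx),
      frameHeightPx = as.integer(frameHeightPx),
      physicalWidthUm = physicalWidthUm,
      physicalHeightUm = physicalHeightUm)
}

#' @rdname Calibration
#' @export
setMethod("pixelSizeUm", "Calibration", function(object) object@pixelSizeUm)

#' @rdname Calibration
#' @export
setMethod("calibration", "MicrographFrame", function(object) object@calibration)

#' @rdname Calibration
#' @export
setMethod("calibration", "BinaryMask", function(object) object@calibration)

#' @rdname Calibration
#' @export
setMethod("calibration", "LabeledRegions", function(object) object@calibration)

#' @rdname Calibration
#' @export
setMethod("calibration", "NeuriteSkeleton", function(object) object@calibration)

setMethod("show", "Calibration", function(object) {
  cat(sprintf("Calibration: %d x %d px = %.2f x %.2f um (%.5f um/px)\n",
              object@frameWidthPx, object@frameHeightPx,
              object@physicalWidthUm, object@physicalHeightUm,
              object@pixelSizeUm))
})

#' Convert a pixel length to micrometres
#'
#' @param lengthPx length in pixels (>= 0).
#' @param cal a [Calibration-class].
#' @return length in um: `lengthPx * pixelSizeUm(cal)`.
#' @export
lengthUm <- function(lengthPx, cal) {
  stopifnot(is(cal, "Calibration"))
  if (any(lengthPx < 0)) stop("lengthPx must be >= 0")
  lengthPx * cal@pixelSizeUm
}

#' Convert a pixel area to square micrometres
#'
#' @param areaPx area in pixels (>= 0).
#' @param cal a [Calibration-class].
#' @return area in um^2: `areaPx * pixelSizeUm(cal)^2`.
#' @export
areaUm2 <- function(areaPx, cal) {
  stopifnot(is(cal, "Calibration"))
  if (any(areaPx < 0)) stop("areaPx must be >= 0")
  areaPx * cal@pixelSizeUm^2
}
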