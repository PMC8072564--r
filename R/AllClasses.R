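#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib neuritracer, .registration = TRUE
NULL

#' Physical calibration of a micrograph frame
#'
#' Links pixel coordinates to physical micrometres. The default corresponds
#' to a 1376 x 1038 px frame imaging 884.89 um x 667.52 um, i.e. an
#' isotropic pixel edge of 884.89/1376 ~ 0.64309 um.
#'
#' @slot pixelSizeUm micrometres per pixel edge (isotropic).
#' @slot frameWidthPx,frameHeightPx frame dimensions in pixels.
#' @slot physicalWidthUm,physicalHeightUm physical frame extents in um.
#' @export
setClass("Calibration",
  representation(
    pixelSizeUm = "numeric",
    frameWidthPx = "integer",
    frameHeightPx = "integer",
    physicalWidthUm = "numeric",
    physicalHeightUm = "numeric"
  )
)

setValidity("Calibration", function(object) {
  msg <- NULL
  if (length(object@pixelSizeUm) != 1 || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be a single positive number")
  pw <- object@physicalWidthUm / object@frameWidthPx
  ph <- object@physicalHeightUm / object@frameHeightPx
  if (abs(pw - object@pixelSizeUm) / object@pixelSizeUm > 1e-3 ||
      abs(ph - object@pixelSizeUm) / object@pixelSizeUm > 1e-3)
    msg <- c(msg, "physical extents inconsistent with pixel size (rel. tol 1e-3)")
  if (is.null(msg)) TRUE else msg
})

#' Calibrated two-channel 16-bit micrograph frame
#'
#' The unit of analysis: a nuclear-stain channel (e.g. DAPI) and a
#' neurite-stain channel (e.g. Alexa 488 / tyrosine hydroxylase) sharing one
#' physical calibration. Intensities are unscaled 16-bit integers.
#'
#' @slot nuclearChannel,neuriteChannel integer matrices in [0, 65535].
#' @slot calibration a [Calibration-class] whose frame size matches the
#'   channel dimensions.
#' @slot frameId opaque frame identifier.
#' @slot condition named list: `compound`, `concentrationNM`, `isControl`,
#'   `experimentId`.
#' @export
setClass("MicrographFrame",
  representation(
    nuclearChannel = "matrix",
    neuriteChannel = "matrix",
    calibration = "Calibration",
    frameId = "character",
    condition = "list"
  )
)

setValidity("MicrographFrame", function(object) {
  msg <- NULL
  dn <- dim(object@nuclearChannel)
  de <- dim(object@neuriteChannel)
  if (!identical(dn, de))
    msg <- c(msg, "channels must share identical dimensions")
  cal <- object@calibration
  if (dn[1] != cal@frameHeightPx || dn[2] != cal@frameWidthPx)
    msg <- c(msg, "channel dimensions do not match calibration frame size")
  rng <- range(object@nuclearChannel, object@neuriteChannel)
  if (rng[1] < 0 || rng[2] > 65535)
    msg <- c(msg, "intensities must lie in [0, 65535]")
  if (is.null(msg)) TRUE else msg
})

#' Binary foreground mask at a stated scale
#'
#' A {0,1} raster derived from a frame channel. `scaleFactor` counts mask
#' pixels per source-frame pixel along each axis, so the effective pixel
#' size is `pixelSizeUm(calibration) / scaleFactor`.
#'
#' @slot raster logical matrix.
#' @slot scaleFactor integer >= 1.
#' @slot calibration calibration of the *source* frame.
#' @export
setClass("BinaryMask",
  representation(
    raster = "matrix",
    scaleFactor = "integer",
    calibration = "Calibration"
  )
)

setValidity("BinaryMask", function(object) {
  msg <- NULL
  if (!is.logical(object@raster))
    msg <- c(msg, "raster must be a logical matrix")
  if (object@scaleFactor < 1L)
    msg <- c(msg, "scaleFactor must be >= 1")
  cal <- object@calibration
  if (nrow(object@raster) != cal@frameHeightPx * object@scaleFactor ||
      ncol(object@raster) != cal@frameWidthPx * object@scaleFactor)
    msg <- c(msg, "raster dimensions must equal source dimensions x scaleFactor")
  if (is.null(msg)) TRUE else msg
})

#' Labelled nucleus regions
#'
#' Watershed-separated nuclei: a label raster (0 = background, labels
#' consecutive 1..N) plus a per-region table with pixel/physical areas,
#' centroid, bounding box and eccentricity.
#'
#' @slot labelRaster integer matrix.
#' @slot regionTable data.frame, one row per label.
#' @slot calibration source-frame calibration.
#' @export
setClass("LabeledRegions",
  representation(
    labelRaster = "matrix",
    regionTable = "data.frame",
    calibration = "Calibration"
  )
)

setValidity("LabeledRegions", function(object) {
  msg <- NULL
  n <- nrow(object@regionTable)
  labs <- object@labelRaster[object@labelRaster > 0]
  if (n > 0) {
    if (!identical(sort(unique(as.integer(labs))), seq_len(n)))
      msg <- c(msg, "labels must be consecutive 1..N")
    if (length(labs) != sum(object@regionTable$area_px))
      msg <- c(msg, "region areas must sum to foreground pixel count")
  } else if (length(labs) > 0) {
    msg <- c(msg, "label raster has labels but region table is empty")
  }
  if (is.null(msg)) TRUE else msg
})

#' Pruned medial-axis skeleton of a neurite mask
#'
#' Skeleton of an (upscaled) binary mask: pixel-centre points with their
#' maximal-disk radii, organised into branch polylines. Coordinates are
#' 0-based (x = column, y = row) in upscaled-mask pixel space.
#'
#' @slot points data.frame with columns `x`, `y`, `r` (maximal-disk radius,
#'   px, equal to the Euclidean distance transform at the point).
#' @slot branches list of integer vectors indexing `points`; each is a
#'   maximal polyline between nodes of degree != 2 (or a closed cycle).
#' @slot epsilonPx pruning precision epsilon, in upscaled-mask pixels.
#' @slot scaleFactor integer copied from the source mask.
#' @slot calibration source-frame calibration.
#' @slot maskDim dimensions (rows, cols) of the skeletonized raster.
#' @export
setClass("NeuriteSkeleton",
  representation(
    points = "data.frame",
    branches = "list",
    epsilonPx = "numeric",
    scaleFactor = "integer",
    calibration = "Calibration",
    maskDim = "integer"
  )
)

setValidity("NeuriteSkeleton", function(object) {
  msg <- NULL
  if (!all(c("x", "y", "r") %in% names(object@points)))
    msg <- c(msg, "points must have columns x, y, r")
  if (length(object@epsilonPx) != 1 || object@epsilonPx <= 0)
    msg <- c(msg, "epsilonPx must be a single positive number")
  np <- nrow(object@points)
  idx <- unlist(object@branches, use.names = FALSE)
  if (length(idx) && (min(idx) < 1 || max(idx) > np))
    msg <- c(msg, "branch indices out of range")
  if (is.null(msg)) TRUE else msg
})

#' Neuron identification by nucleus-neurite overlap
#'
#' @slot neuronNucleusLabels integer labels of nuclei whose contour
#'   intersects the neurite mask (the automated TH+/neuron criterion).
#' @slot neuronCount integer, `length(neuronNucleusLabels)`.
#' @slot somaMask a [BinaryMask-class] of detected somata, or `NULL`.
#' @export
setClass("NeuronAssignment",
  representation(
    neuronNucleusLabels = "integer",
    neuronCount = "integer",
    somaMask = "ANY"
  )
)

setValidity("NeuronAssignment", function(object) {
  if (object@neuronCount != length(object@neuronNucleusLabels))
    "neuronCount must equal length(neuronNucleusLabels)" else TRUE
})

#' Constrained variable-slope dose-response fit
#'
#' Four-parameter logistic
#' `y = bottom + (top - bottom) / (1 + 10^((log10(ld50) - log10(c)) * hillSlope))`
#' with the upper asymptote fixed to the solvent-control value.
#'
#' @slot top upper asymptote (%, fixed during fitting).
#' @slot bottom lower asymptote (%, constrained >= 0).
#' @slot hillSlope dimensionless slope.
#' @slot ld50 half-maximal lesion concentration (nM); NA if not converged.
#' @slot rss residual sum of squares.
#' @slot converged logical.
#' @export
setClass("DoseResponseFit",
  representation(
    top = "numeric",
    bottom = "numeric",
    hillSlope = "numeric",
    ld50 = "numeric",
    rss = "numeric",
    converged = "logical"
  )
)

setValidity("DoseResponseFit", function(object) {
  if (isTRUE(object@converged) && (!is.finite(object@ld50) || object@ld50 <= 0))
    "a converged fit must have ld50 > 0" else TRUE
})
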