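# Generics for accessors shared across the core classes.

#' @rdname Calibration
#' @param object,x an object.
#' @export
setGeneric("pixelSizeUm", function(object) standardGeneric("pixelSizeUm"))

#' @rdname Calibration
#' @export
setGeneric("calibration", function(object) standardGeneric("calibration"))

#' @rdname BinaryMask
#' @export
setGeneric("scaleFactor", function(object) standardGeneric("scaleFactor"))

#' @rdname BinaryMask
#' @export
setGeneric("maskRaster", function(object) standardGeneric("maskRaster"))

#' @rdname MicrographFrame
#' @export
setGeneric("nuclearChannel", function(object) standardGeneric("nuclearChannel"))

#' @rdname MicrographFrame
#' @export
setGeneric("neuriteChannel", function(object) standardGeneric("neuriteChannel"))

#' @rdname MicrographFrame
#' @export
setGeneric("frameId", function(object) standardGeneric("frameId"))

#' @rdname LabeledRegions
#' @export
setGeneric("regionTable", function(object) standardGeneric("regionTable"))

#' @rdname LabeledRegions
#' @export
setGeneric("labelRaster", function(object) standardGeneric("labelRaster"))

#' @rdname LabeledRegions
#' @export
setGeneric("regionCount", function(object) standardGeneric("regionCount"))

#' Skeleton measurements
#'
#' `branchStatistics()` counts endpoints (degree-1 nodes), branch points
#' (degree >= 3 nodes) and branch segments (maximal polylines between nodes
#' of degree != 2). `totalLengthUm()` sums Euclidean polyline lengths over
#' all branches, corrected for the mask scale factor and converted to
#' micrometres; branch polylines are lightly smoothed first so that length
#' does not inherit pixel-staircase bias.
#'
#' @param skeleton a [NeuriteSkeleton-class].
#' @return `branchStatistics()`: named list with `endpoint_count`,
#'   `branch_point_count`, `branch_segment_count`. `totalLengthUm()`: a
#'   single number (um).
#' @export
setGeneric("branchStatistics", function(skeleton) standardGeneric("branchStatistics"))

#' @rdname branchStatistics
#' @export
setGeneric("totalLengthUm", function(skeleton) standardGeneric("totalLengthUm"))
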