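# Soma detection, neuron identification, orphan removal, skeleton/soma
# combination and neurite area.

#' Detect somata in the neurite mask
#'
#' Seeds are mask pixels whose Euclidean distance-transform value reaches
#' `somaRadiusPx`; a single geodesic dilation of size `somaRadiusPx`
#' (dilation intersected with the mask, i.e. a morphological opening
#' restricted to the mask) grows the seeds back to the soma extent without
#' flooding attached neurites. Thin structures (half-width below
#' `somaRadiusPx`) contribute nothing. Only mask components that overlap at
#' least one nucleus are retained.
#'
#' @param neuriteMask neurite-channel [BinaryMask-class] at source scale.
#' @param nucleiRegions [LabeledRegions-class] from the nuclear channel.
#' @param somaRadiusPx distance-transform threshold in px (default 8,
#'   ~5.1 um at the reference pixel size).
#' @return soma [BinaryMask-class] (subset of `neuriteMask`).
#' @export
detectSomata <- function(neuriteMask, nucleiRegions, somaRadiusPx = 8) {
  r <- neuriteMask@raster
  empty <- function() binaryMask(matrix(FALSE, nrow(r), ncol(r)),
                                 neuriteMask@calibration,
                                 neuriteMask@scaleFactor)
  if (!any(r)) return(empty())
  d <- .distmapPadded(r)
  seeds <- d >= somaRadiusPx
  if (!any(seeds)) return(empty())
  brush <- EBImage::makeBrush(2L * as.integer(ceiling(somaRadiusPx)) + 1L,
                              shape = "disc")
  soma <- (EBImage::dilate(seeds * 1, brush) > 0.5) & r
  lab <- labelComponents(neuriteMask)
  withNucleus <- unique(lab[lab > 0L & nucleiRegions@labelRaster > 0L])
  soma <- soma & matrix(lab %in% withNucleus, nrow(r), ncol(r))
  binaryMask(soma, neuriteMask@calibration, neuriteMask@scaleFactor)
}

#' Identify neurons by nucleus-neurite overlap
#'
#' A nucleus is a neuron iff at least one of its pixels overlaps
#' neurite-mask foreground — the automated analogue of counting cells
#' positive for the neurite-channel stain.
#'
#' @param nucleiRegions [LabeledRegions-class].
#' @param neuriteMask neurite-channel [BinaryMask-class] at source scale.
#' @param somaMask optional soma [BinaryMask-class] to carry along.
#' @return a [NeuronAssignment-class].
#' @export
identifyNeurons <- function(nucleiRegions, neuriteMask, somaMask = NULL) {
  lab <- nucleiRegions@labelRaster
  hits <- unique(lab[lab > 0L & neuriteMask@raster])
  hits <- sort(as.integer(hits))
  new("NeuronAssignment", neuronNucleusLabels = hits,
      neuronCount = length(hits), somaMask = somaMask)
}

setMethod("show", "NeuronAssignment", function(object) {
  cat(sprintf("NeuronAssignment: %d neuron(s) (nucleus labels: %s)\n",
              object@neuronCount,
              paste(object@neuronNucleusLabels, collapse = ", ")))
})

#' Remove neurite components not anchored to a neuron
#'
#' 8-connected neurite-mask components containing no pixel of any neuron
#' nucleus are removed (false positives, staining artifacts); all other
#' components are unchanged.
#'
#' @param neuriteMask neurite-channel [BinaryMask-class] at source scale.
#' @param assignment a [NeuronAssignment-class] from [identifyNeurons()].
#' @param nucleiRegions the [LabeledRegions-class] the assignment refers to.
#' @return filtered [BinaryMask-class].
#' @export
removeOrphanComponents <- function(neuriteMask, assignment, nucleiRegions) {
  r <- neuriteMask@raster
  if (!any(r) || assignment@neuronCount == 0L) {
    return(binaryMask(matrix(FALSE, nrow(r), ncol(r)),
                      neuriteMask@calibration, neuriteMask@scaleFactor))
  }
  lab <- labelComponents(neuriteMask)
  neuronNuc <- nucleiRegions@labelRaster %in% assignment@neuronNucleusLabels
  keepLabs <- unique(lab[lab > 0L & neuronNuc])
  keep <- r & matrix(lab %in% keepLabs, nrow(r), ncol(r))
  binaryMask(keep, neuriteMask@calibration, neuriteMask@scaleFactor)
}

#' Clip skeleton branches where they overlap the soma mask
#'
#' Skeleton vertices inside the soma mask (upsampled to the skeleton's
#' scale) are deleted; branches are thereby clipped at the soma boundary,
#' branches entirely inside are removed, and node degrees/endpoints are
#' recomputed. Per-vertex clipping (not whole-branch deletion) keeps
#' legitimate neurites that pass near a soma.
#'
#' @param skeleton a [NeuriteSkeleton-class].
#' @param somaMask soma [BinaryMask-class] at source scale (or any scale
#'   dividing the skeleton's).
#' @return clipped [NeuriteSkeleton-class]. Idempotent; never increases
#'   total length.
#' @export
pruneSomaOverlap <- function(skeleton, somaMask) {
  if (nrow(skeleton@points) == 0L || !any(somaMask@raster)) return(skeleton)
  fac <- skeleton@scaleFactor / somaMask@scaleFactor
  if (fac != as.integer(fac) || fac < 1)
    stop("soma mask scale must divide the skeleton scale")
  up <- if (fac > 1) upscaleMask(somaMask, as.integer(fac)) else somaMask
  if (!all(dim(up@raster) == skeleton@maskDim))
    stop("soma mask dimensions do not match the skeleton raster")
  rows <- skeleton@points$y + 1L
  cols <- skeleton@points$x + 1L
  inSoma <- up@raster[cbind(rows, cols)]
  if (!any(inSoma)) return(skeleton)
  sk <- matrix(FALSE, skeleton@maskDim[1], skeleton@maskDim[2])
  sk[cbind(rows[!inSoma], cols[!inSoma])] <- TRUE
  g <- .skGraph(sk)
  keepMap <- matrix(0L, skeleton@maskDim[1], skeleton@maskDim[2])
  keepMap[cbind(rows, cols)] <- seq_along(rows)
  radii <- skeleton@points$r[keepMap[cbind(g$rows, g$cols)]]
  pts <- data.frame(x = g$cols - 1, y = g$rows - 1, r = radii)
  new("NeuriteSkeleton", points = pts, branches = g$branches,
      epsilonPx = skeleton@epsilonPx, scaleFactor = skeleton@scaleFactor,
      calibration = skeleton@calibration, maskDim = skeleton@maskDim)
}

#' Neurite area after soma subtraction
#'
#' @param neuriteMask neurite [BinaryMask-class].
#' @param somaMask soma [BinaryMask-class] of identical dimensions/scale.
#' @param cal calibration (defaults to the neurite mask's).
#' @return area in um^2 of `neuriteMask AND NOT somaMask`.
#' @export
neuriteAreaUm2 <- function(neuriteMask, somaMask,
                           cal = calibration(neuriteMask)) {
  if (!all(dim(neuriteMask@raster) == dim(somaMask@raster)))
    stop("mask dimensions differ")
  px <- sum(neuriteMask@raster & !somaMask@raster)
  effPx <- cal@pixelSizeUm / neuriteMask@scaleFactor
  px * effPx^2
}
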