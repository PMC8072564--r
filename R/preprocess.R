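# Channel preprocessing: brightness normalization, Phansalkar local
# thresholding, morphological closing and the plausibility-area filter.

#' Preprocessing parameters
#'
#' Defaults: canonical Phansalkar coefficients (p = 2, q = 10, k = 0.25,
#' R = 0.5) in a 25 px window (~16 um at the reference pixel size, spanning
#' a neurite cross-section plus local background); closing with a disk of
#' radius 2 px; plausibility criterion <= 82.71 um^2 (200 px^2 at the
#' reference calibration); brightness reduction triggered when more than
#' 0.5% of pixels sit at full scale, rescaling the 99.9th percentile to
#' full scale.
#'
#' @param windowPx odd local-window width (>= 3 px).
#' @param p,q,k,r Phansalkar coefficients (on intensities normalized to
#'   \[0, 1\]).
#' @param closingRadiusPx disk radius of the morphological closing (0
#'   disables closing).
#' @param maxImplausibleAreaUm2 components with area up to this value
#'   (compared at its printed 0.01 um^2 precision) are removed.
#' @param saturationFraction fraction of full-scale pixels that triggers
#'   brightness reduction.
#' @param clipPercentile percentile mapped to full scale when reducing.
#' @return a named list of class `PreprocessParams`.
#' @export
preprocessParams <- function(windowPx = 25L, p = 2, q = 10, k = 0.25, r = 0.5,
                             closingRadiusPx = 2L,
                             maxImplausibleAreaUm2 = 82.71,
                             saturationFraction = 0.005,
                             clipPercentile = 99.9) {
  windowPx <- as.integer(windowPx)
  if (windowPx < 3L || windowPx %% 2L == 0L)
    stop("windowPx must be an odd integer >= 3")
  if (maxImplausibleAreaUm2 <= 0)
    stop("maxImplausibleAreaUm2 must be > 0")
  structure(list(windowPx = windowPx, p = p, q = q, k = k, r = r,
                 closingRadiusPx = as.integer(closingRadiusPx),
                 maxImplausibleAreaUm2 = maxImplausibleAreaUm2,
                 saturationFraction = saturationFraction,
                 clipPercentile = clipPercentile),
            class = "PreprocessParams")
}

#' Dynamically reduce brightness of an overexposed raster
#'
#' If the fraction of full-scale (65535) pixels exceeds
#' `saturationFraction`, intensities are linearly rescaled so that the
#' `clipPercentile` value maps to full scale (values above are clipped);
#' otherwise the raster is returned unchanged.
#'
#' @param raster integer matrix of 16-bit intensities.
#' @param params a [preprocessParams()] list.
#' @return integer matrix with range within \[0, 65535\].
#' @export
normalizeBrightness <- function(raster, params = preprocessParams()) {
  if (length(raster) == 0) stop("empty raster")
  if (mean(raster >= 65535L) <= params$saturationFraction) return(raster)
  v <- stats::quantile(raster, params$clipPercentile / 100, names = FALSE)
  if (v <= 0) return(raster)
  out <- as.integer(pmin(65535, round(as.numeric(raster) * (65535 / v))))
  matrix(out, nrow(raster), ncol(raster))
}

# Box-window mean and sd with symmetric (reflective) edge padding,
# via summed-area tables.
.localMeanSd <- function(x, w) {
  h <- (w - 1L) / 2L
  nr <- nrow(x); nc <- ncol(x)
  ri <- c(h:1, 1:nr, nr:(nr - h + 1L))
  ci <- c(h:1, 1:nc, nc:(nc - h + 1L))
  p <- x[ri, ci, drop = FALSE]
  sat <- function(m) {
    m <- apply(m, 2, cumsum)
    m <- t(apply(m, 1, cumsum))
    rbind(0, cbind(0, m))  # zero-padded so windows index cleanly
  }
  s1 <- sat(p); s2 <- sat(p * p)
  i0 <- 1:nr; j0 <- 1:nc  # window top-left in padded coords (1-based)
  box <- function(s) {
    s[i0 + w, j0 + w, drop = FALSE] - s[i0, j0 + w, drop = FALSE] -
      s[i0 + w, j0, drop = FALSE] + s[i0, j0, drop = FALSE]
  }
  n <- w * w
  m <- box(s1) / n
  v <- pmax(0, box(s2) / n - m * m)
  list(mean = m, sd = sqrt(v))
}

#' Binarize a channel with Phansalkar local thresholding
#'
#' Intensities are normalized to \[0, 1\]; a pixel is foreground iff its
#' normalized intensity exceeds
#' `T = m * (1 + p * exp(-q * m) + k * (s / R - 1))`, where `m` and `s` are
#' the mean and standard deviation over the `windowPx` x `windowPx`
#' neighbourhood (symmetric reflective edge padding). The exponential term
#' lowers the threshold in dark regions, which suits fluorescence images
#' with faint structures on a dark background.
#'
#' @param raster integer matrix of 16-bit intensities.
#' @param cal source-frame [Calibration-class].
#' @param params a [preprocessParams()] list.
#' @return a [BinaryMask-class] at scale factor 1.
#' @export
binarizePhansalkar <- function(raster, cal, params = preprocessParams()) {
  w <- params$windowPx
  if (w > min(dim(raster))) stop("window larger than image")
  x <- raster / 65535
  ms <- .localMeanSd(x, w)
  thr <- ms$mean * (1 + params$p * exp(-params$q * ms$mean) +
                      params$k * (ms$sd / params$r - 1))
  binaryMask(x > thr, cal, 1L)
}

#' Morphological closing of a binary mask
#'
#' Dilation followed by erosion with a disk structuring element of radius
#' `closingRadiusPx`; bridges small binarization gaps without changing the
#' mask dimensions.
#'
#' @param mask a [BinaryMask-class].
#' @param params a [preprocessParams()] list.
#' @return closed [BinaryMask-class].
#' @export
closeMask <- function(mask, params = preprocessParams()) {
  rad <- params$closingRadiusPx
  if (rad < 1L) return(mask)
  brush <- EBImage::makeBrush(2L * rad + 1L, shape = "disc")
  closed <- EBImage::closing(mask@raster * 1, brush) > 0.5
  binaryMask(closed, mask@calibration, mask@scaleFactor)
}

#' Remove implausibly small foreground structures
#'
#' Every 8-connected foreground component whose physical area (pixel count
#' at the mask's effective pixel size) does not exceed
#' `maxImplausibleAreaUm2` is removed; larger components are preserved
#' verbatim. Areas are compared at the criterion's printed precision
#' (0.01 um^2), so a component whose area rounds to the stated threshold is
#' still removed.
#'
#' @param mask a [BinaryMask-class].
#' @param params a [preprocessParams()] list.
#' @return filtered [BinaryMask-class].
#' @export
filterImplausible <- function(mask, params = preprocessParams()) {
  lab <- labelComponents(mask)
  if (max(lab) == 0L) return(mask)
  effPx <- mask@calibration@pixelSizeUm / mask@scaleFactor
  areas <- tabulate(lab[lab > 0L])
  drop <- which(areas * effPx^2 <= params$maxImplausibleAreaUm2 + 5e-3)
  if (length(drop) == 0L) return(mask)
  keep <- mask@raster & !(lab %in% drop)
  binaryMask(matrix(keep, nrow(lab), ncol(lab)), mask@calibration,
             mask@scaleFactor)
}

#' 8-connected component labelling
#'
#' @param mask a [BinaryMask-class] or logical matrix.
#' @return integer matrix with labels consecutive 1..N (row-major first
#'   occurrence), 0 = background.
#' @export
labelComponents <- function(mask) {
  r <- if (is(mask, "BinaryMask")) mask@raster else mask
  .cpp_label8(matrix(as.integer(r), nrow(r), ncol(r)))
}

#' Full preprocessing chain for one channel
#'
#' [normalizeBrightness()] then [binarizePhansalkar()], [closeMask()] and
#' (optionally) [filterImplausible()]. Deterministic: identical input gives
#' an identical mask.
#'
#' @param raster integer matrix of 16-bit intensities.
#' @param cal source-frame [Calibration-class].
#' @param params a [preprocessParams()] list.
#' @param plausibilityFilter apply the area filter (default TRUE).
#' @return a [BinaryMask-class] at scale factor 1.
#' @export
preprocessChannel <- function(raster, cal, params = preprocessParams(),
                              plausibilityFilter = TRUE) {
  x <- normalizeBrightness(raster, params)
  m <- binarizePhansalkar(x, cal, params)
  m <- closeMask(m, params)
  if (plausibilityFilter) m <- filterImplausible(m, params)
  m
}
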