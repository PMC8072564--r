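# Synthetic two-channel micrographs with exact ground truth: somata with
# arborized curvilinear neurites of known total length and branch count,
# elliptical nuclei (optionally clumped), staining artifacts, exposure
# variation and Gaussian intensity noise.

#' Specification of one synthetic frame
#'
#' Defaults emulate the reference imaging conditions: a 1376 x 1038 px
#' frame at the reference pixel size, a handful of neurons whose somata
#' carry 2-4 neurites of 60-160 um drawn as smooth random-walk polylines
#' (collision-avoiding, so structures from different cells stay separate),
#' non-neuron nuclei, and staining artifacts drawn in two size classes,
#' below and above the plausibility criterion.
#'
#' @param widthPx,heightPx frame size in pixels.
#' @param pixelSizeUm um per pixel edge.
#' @param nNeurons somata with neurites (each gets one nucleus).
#' @param nNonNeuronNuclei nuclei placed away from any neurite structure.
#' @param somaRadiusRangePx,nucleusRadiusRangePx radius ranges (px).
#' @param neuritesPerNeuronRange integer range of neurites per soma.
#' @param neuriteLengthRangeUm total tree length per neurite (um).
#' @param neuriteWidthPx drawn neurite width (>= 2 px).
#' @param branchingProbPerUm probability of spawning a side branch per um
#'   of drawn neurite.
#' @param headingSdRad angular diffusion of the walk per step (radians).
#' @param clumpFraction probability that a non-neuron nucleus receives a
#'   touching partner nucleus (the clumped-pair failure mode).
#' @param artifactCount isolated blobs added to the neurite channel.
#' @param artifactAreaRangesPx2 list of two px^2 ranges, `small` (below the
#'   plausibility criterion) and `large` (above it).
#' @param backgroundIntensity,nuclearIntensity,neuriteIntensity 16-bit
#'   intensity levels.
#' @param noiseSigma additive Gaussian noise sd (16-bit units).
#' @param exposureGainRange per-frame multiplicative exposure jitter.
#' @param seed RNG seed; generation is bit-reproducible given the spec.
#' @return a named list of class `FrameSpec`.
#' @export
frameSpec <- function(widthPx = 1376L, heightPx = 1038L,
                      pixelSizeUm = DEFAULT_PIXEL_SIZE_UM,
                      nNeurons = 6L, nNonNeuronNuclei = 6L,
                      somaRadiusRangePx = c(13, 18),
                      nucleusRadiusRangePx = c(9, 12),
                      neuritesPerNeuronRange = c(2L, 4L),
                      neuriteLengthRangeUm = c(60, 160),
                      neuriteWidthPx = 4,
                      branchingProbPerUm = 0.008,
                      headingSdRad = 0.10,
                      clumpFraction = 0,
                      artifactCount = 6L,
                      artifactAreaRangesPx2 = list(small = c(50, 150),
                                                   large = c(300, 500)),
                      backgroundIntensity = 2000,
                      nuclearIntensity = 30000,
                      neuriteIntensity = 28000,
                      noiseSigma = 800,
                      exposureGainRange = c(0.85, 1.2),
                      seed = 1L) {
  spec <- list(widthPx = as.integer(widthPx), heightPx = as.integer(heightPx),
               pixelSizeUm = pixelSizeUm, nNeurons = as.integer(nNeurons),
               nNonNeuronNuclei = as.integer(nNonNeuronNuclei),
               somaRadiusRangePx = somaRadiusRangePx,
               nucleusRadiusRangePx = nucleusRadiusRangePx,
               neuritesPerNeuronRange = as.integer(neuritesPerNeuronRange),
               neuriteLengthRangeUm = neuriteLengthRangeUm,
               neuriteWidthPx = neuriteWidthPx,
               branchingProbPerUm = branchingProbPerUm,
               headingSdRad = headingSdRad,
               clumpFraction = clumpFraction,
               artifactCount = as.integer(artifactCount),
               artifactAreaRangesPx2 = artifactAreaRangesPx2,
               backgroundIntensity = backgroundIntensity,
               nuclearIntensity = nuclearIntensity,
               neuriteIntensity = neuriteIntensity,
               noiseSigma = noiseSigma,
               exposureGainRange = exposureGainRange,
               seed = as.integer(seed))
  if (spec$neuriteWidthPx < 2) stop("neuriteWidthPx must be >= 2")
  if (any(unlist(spec[c("somaRadiusRangePx", "nucleusRadiusRangePx",
                        "neuriteLengthRangeUm")]) <= 0))
    stop("ranges must be positive")
  if (any(c(backgroundIntensity, nuclearIntensity, neuriteIntensity) < 0) ||
      any(c(backgroundIntensity, nuclearIntensity, neuriteIntensity) > 65535))
    stop("intensities must lie within the 16-bit range")
  structure(spec, class = "FrameSpec")
}

# Evaluate expr with a fixed seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.diskOffsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
}

# Stamp disks of fixed radius at (rows, cols) into a logical matrix.
.stampDisks <- function(mask, rows, cols, radius) {
  off <- .diskOffsets(radius)
  nr <- nrow(mask); nc <- ncol(mask)
  rr <- rep(round(rows), each = nrow(off)) + off$dr
  cc <- rep(round(cols), each = nrow(off)) + off$dc
  ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
  mask[cbind(rr[ok], cc[ok])] <- TRUE
  mask
}

.stampEllipse <- function(mask, cr, cc, a, b, phi) {
  r <- ceiling(max(a, b))
  rows <- max(1, round(cr) - r):min(nrow(mask), round(cr) + r)
  cols <- max(1, round(cc) - r):min(ncol(mask), round(cc) + r)
  g <- expand.grid(r = rows, c = cols)
  dr <- g$r - cr; dc <- g$c - cc
  u <- (dc * cos(phi) + dr * sin(phi)) / a
  v <- (-dc * sin(phi) + dr * cos(phi)) / b
  inside <- u^2 + v^2 <= 1
  mask[cbind(g$r[inside], g$c[inside])] <- TRUE
  mask
}

# Does stamping a disk of `radius` at (row, col) touch `occ`? Hits inside
# an optional exemption disk (a walk's own origin region) are ignored.
.collides <- function(occ, row, col, radius, exempt = NULL) {
  off <- .diskOffsets(radius)
  rr <- round(row) + off$dr; cc <- round(col) + off$dc
  ok <- rr >= 1 & rr <= nrow(occ) & cc >= 1 & cc <= ncol(occ)
  rr <- rr[ok]; cc <- cc[ok]
  hit <- occ[cbind(rr, cc)]
  if (!is.null(exempt) && any(hit)) {
    inEx <- (rr - exempt[1])^2 + (cc - exempt[2])^2 <= exempt[3]^2
    hit <- hit & !inEx
  }
  any(hit)
}

# Random smooth walk of one neurite tree with exact length accounting.
# The walk carries its own copy of the collision field and stamps its trail
# into it with a short delay, so a tree avoids its own earlier limbs (no
# self- or sibling-crossings) while still being allowed to leave its origin
# (an exemption disk covers each limb's spawn point). Returns polylines
# (px), consumed length (um) and branch count.
.growNeuriteTree <- function(start, heading, budgetUm, spec, occ,
                             clearRadius) {
  stepUm <- 1.5
  stepPx <- stepUm / spec$pixelSizeUm
  margin <- 6
  stampR <- spec$neuriteWidthPx / 2
  delay <- ceiling((clearRadius + stampR + 1) / stepPx)
  polylines <- list()
  consumed <- 0
  branches <- 0L
  stack <- list(list(pos = start, heading = heading, budget = budgetUm))
  while (length(stack) > 0) {
    wk <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    pts <- matrix(wk$pos, 1, 2)  # (row, col)
    pos <- wk$pos; th <- wk$heading; left <- wk$budget
    exempt <- c(wk$pos, clearRadius + stampR + 2)
    while (left > 1e-9) {
      ds <- min(stepUm, left)
      th <- th + stats::rnorm(1, 0, spec$headingSdRad)
      placed <- FALSE
      for (dth in c(0, 0.5, -0.5, 1.0, -1.0, 1.5, -1.5)) {
        cand <- pos + (ds / stepUm) * stepPx * c(sin(th + dth), cos(th + dth))
        if (cand[1] < margin || cand[1] > nrow(occ) - margin ||
            cand[2] < margin || cand[2] > ncol(occ) - margin) next
        ex <- if (sum((cand[1:2] - exempt[1:2])^2) <= (exempt[3] +
                                                         clearRadius)^2)
          exempt else NULL
        if (.collides(occ, cand[1], cand[2], clearRadius, ex)) next
        th <- th + dth; pos <- cand; placed <- TRUE
        break
      }
      if (!placed) break  # blocked: terminate, truth = consumed length
      pts <- rbind(pts, pos)
      consumed <- consumed + ds
      left <- left - ds
      # delayed self-stamping: the trail more than `delay` steps back
      # becomes part of the walk's own collision field
      if (nrow(pts) > delay)
        occ <- .stampDisks(occ, pts[nrow(pts) - delay, 1],
                           pts[nrow(pts) - delay, 2], stampR)
      if (left > 8 && stats::runif(1) < spec$branchingProbPerUm * ds) {
        share <- stats::runif(1, 0.35, 0.65)
        sgn <- sample(c(-1, 1), 1)
        # spawn beside the parent tube (touching, not co-linear) so the
        # child's drawn length is not swallowed by the parent's stamp
        off <- (stampR + 0.5) * c(sin(th + sgn * pi / 2),
                                  cos(th + sgn * pi / 2))
        stack[[length(stack) + 1L]] <-
          list(pos = pos + off,
               heading = th + sgn * stats::runif(1, 0.9, 1.3),
               budget = left * share)
        left <- left * (1 - share)
        branches <- branches + 1L
      }
    }
    # flush the whole polyline before the next limb starts
    if (nrow(pts) > 1) {
      dp <- .densify(pts)
      occ <- .stampDisks(occ, dp[, 1], dp[, 2], stampR)
      polylines[[length(polylines) + 1L]] <- pts
    }
  }
  list(polylines = polylines, lengthUm = consumed, branchPoints = branches)
}

# Densely sample a polyline at ~0.4 px spacing for rasterization.
.densify <- function(pts, spacing = 0.4) {
  out <- list()
  for (i in seq_len(nrow(pts) - 1L)) {
    a <- pts[i, ]; b <- pts[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    n <- max(2L, ceiling(len / spacing) + 1L)
    t <- seq(0, 1, length.out = n)
    out[[i]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  do.call(rbind, out)
}

#' Generate one synthetic two-channel frame with exact ground truth
#'
#' Deterministic given the spec (including its seed). Neurites are grown in
#' physical units and rasterized at the spec's pixel size, so ground-truth
#' lengths are resolution-independent and equal the generated polyline
#' lengths exactly. Structures from different cells avoid each other by
#' construction (a blocked walk terminates and its truth length is the
#' consumed length).
#'
#' @param spec a [frameSpec()].
#' @param frameId frame identifier.
#' @param condition condition list, see [micrographFrame()].
#' @return list with elements `frame` (a [MicrographFrame-class]) and
#'   `truth` (nuclei/neuron counts, exact total neurite length in um,
#'   branch-point count, soma/nucleus/artifact inventories).
#' @export
generateFrame <- function(spec, frameId = "synthetic", condition = list()) {
  .withSeed(spec$seed, .generateFrameImpl(spec, frameId, condition))
}

.generateFrameImpl <- function(spec, frameId, condition) {
  nr <- spec$heightPx; nc <- spec$widthPx
  somaMask <- matrix(FALSE, nr, nc)
  neuriteMask <- matrix(FALSE, nr, nc)
  nucMask <- matrix(FALSE, nr, nc)
  artifactMask <- matrix(FALSE, nr, nc)

  # somata: rejection-sampled, mutually well separated
  somata <- data.frame(row = numeric(0), col = numeric(0), r = numeric(0))
  for (i in seq_len(spec$nNeurons)) {
    r <- stats::runif(1, spec$somaRadiusRangePx[1], spec$somaRadiusRangePx[2])
    ok <- FALSE
    for (try in 1:300) {
      row <- stats::runif(1, r + 25, nr - r - 25)
      col <- stats::runif(1, r + 25, nc - r - 25)
      if (nrow(somata) == 0 ||
          all(sqrt((somata$row - row)^2 + (somata$col - col)^2) >
              somata$r + r + 35)) { ok <- TRUE; break }
    }
    if (!ok) stop("overcrowded spec: cannot place soma ", i)
    somata <- rbind(somata, data.frame(row = row, col = col, r = r))
  }

  for (i in seq_len(nrow(somata)))
    somaMask <- .stampDisks(somaMask, somata$row[i], somata$col[i],
                            somata$r[i])

  # neurites per soma, collision-avoiding against everything drawn so far
  # (other trees, all somata except the own one)
  clearRadius <- spec$neuriteWidthPx / 2 + 11
  totalLen <- 0
  branchPoints <- 0L
  neuriteTab <- data.frame(neuron = integer(0), target_um = numeric(0),
                           length_um = numeric(0), branch_points = integer(0))
  for (i in seq_len(nrow(somata))) {
    occ <- neuriteMask | somaMask
    # own soma is a legal origin: carve it out of the collision field
    ownOff <- .diskOffsets(somata$r[i] + 1)
    rr <- round(somata$row[i]) + ownOff$dr
    cc <- round(somata$col[i]) + ownOff$dc
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    occ[cbind(rr[ok], cc[ok])] <- FALSE
    k <- sample(seq(spec$neuritesPerNeuronRange[1],
                    spec$neuritesPerNeuronRange[2]), 1)
    base <- stats::runif(1, 0, 2 * pi)
    for (j in seq_len(k)) {
      target <- stats::runif(1, spec$neuriteLengthRangeUm[1],
                             spec$neuriteLengthRangeUm[2])
      remaining <- target
      grown <- 0
      bp <- 0L
      # a blocked walk re-spawns its unconsumed budget at a fresh angle,
      # so realized tree length tracks the drawn target closely
      for (attempt in 1:4) {
        if (remaining <= 2) break
        th <- if (attempt == 1)
          base + (j - 1) * 2 * pi / k + stats::rnorm(1, 0, 0.2)
        else stats::runif(1, 0, 2 * pi)
        start <- c(somata$row[i] + somata$r[i] * sin(th),
                   somata$col[i] + somata$r[i] * cos(th))
        tree <- .growNeuriteTree(start, th, remaining, spec, occ,
                                 clearRadius)
        for (pl in tree$polylines) {
          dp <- .densify(pl)
          neuriteMask <- .stampDisks(neuriteMask, dp[, 1], dp[, 2],
                                     spec$neuriteWidthPx / 2)
          occ <- .stampDisks(occ, dp[, 1], dp[, 2], spec$neuriteWidthPx / 2)
        }
        grown <- grown + tree$lengthUm
        remaining <- remaining - tree$lengthUm
        bp <- bp + tree$branchPoints
      }
      totalLen <- totalLen + grown
      branchPoints <- branchPoints + bp
      neuriteTab <- rbind(neuriteTab,
                          data.frame(neuron = i, target_um = target,
                                     length_um = grown,
                                     branch_points = bp))
    }
  }

  # nuclei: one per soma (centred), plus non-neuron nuclei placed clear of
  # neurite structures; clumped pairs with probability clumpFraction
  nuclei <- data.frame(row = numeric(0), col = numeric(0),
                       a = numeric(0), b = numeric(0), neuron = logical(0))
  for (i in seq_len(nrow(somata))) {
    a <- stats::runif(1, spec$nucleusRadiusRangePx[1],
                      min(spec$nucleusRadiusRangePx[2], somata$r[i] - 1))
    b <- stats::runif(1, spec$nucleusRadiusRangePx[1], max(
      spec$nucleusRadiusRangePx[1], a))
    nuclei <- rbind(nuclei, data.frame(row = somata$row[i],
                                       col = somata$col[i],
                                       a = a, b = b, neuron = TRUE))
  }
  structureOcc <- neuriteMask | somaMask
  rmax <- spec$nucleusRadiusRangePx[2]
  for (i in seq_len(spec$nNonNeuronNuclei)) {
    a <- stats::runif(1, spec$nucleusRadiusRangePx[1], rmax)
    b <- stats::runif(1, spec$nucleusRadiusRangePx[1], rmax)
    placed <- FALSE
    for (try in 1:300) {
      row <- stats::runif(1, 2 * rmax + 6, nr - 2 * rmax - 6)
      col <- stats::runif(1, 2 * rmax + 6, nc - 2 * rmax - 6)
      clear <- !.collides(structureOcc, row, col, max(a, b) + 6)
      farFromNuclei <- nrow(nuclei) == 0 ||
        all(sqrt((nuclei$row - row)^2 + (nuclei$col - col)^2) >
            max(a, b) + nuclei$a + 4)
      if (clear && farFromNuclei) { placed <- TRUE; break }
    }
    if (!placed) next
    nuclei <- rbind(nuclei, data.frame(row = row, col = col, a = a, b = b,
                                       neuron = FALSE))
    if (stats::runif(1) < spec$clumpFraction) {
      phi <- stats::runif(1, 0, 2 * pi)
      a2 <- stats::runif(1, spec$nucleusRadiusRangePx[1], rmax)
      b2 <- a2
      d <- 0.95 * (max(a, b) + a2)
      row2 <- row + d * sin(phi); col2 <- col + d * cos(phi)
      if (row2 > rmax + 4 && row2 < nr - rmax - 4 &&
          col2 > rmax + 4 && col2 < nc - rmax - 4 &&
          !.collides(structureOcc, row2, col2, a2 + 6)) {
        nuclei <- rbind(nuclei, data.frame(row = row2, col = col2, a = a2,
                                           b = b2, neuron = FALSE))
      }
    }
  }
  for (i in seq_len(nrow(nuclei))) {
    nucMask <- .stampEllipse(nucMask, nuclei$row[i], nuclei$col[i],
                             nuclei$a[i], nuclei$b[i],
                             stats::runif(1, 0, pi))
  }

  # artifacts: isolated elliptical blobs, two size classes
  artifacts <- data.frame(row = numeric(0), col = numeric(0),
                          a = numeric(0), b = numeric(0), phi = numeric(0),
                          area_px = integer(0), area_um2 = numeric(0),
                          below_criterion = logical(0))
  allOcc <- structureOcc | nucMask
  for (i in seq_len(spec$artifactCount)) {
    small <- i %% 2L == 1L
    rng <- if (small) spec$artifactAreaRangesPx2$small
           else spec$artifactAreaRangesPx2$large
    area <- stats::runif(1, rng[1], rng[2])
    aspect <- stats::runif(1, 1, 2)
    a <- sqrt(area * aspect / pi); b <- a / aspect
    placed <- FALSE
    for (try in 1:300) {
      row <- stats::runif(1, a + 8, nr - a - 8)
      col <- stats::runif(1, a + 8, nc - a - 8)
      if (!.collides(allOcc, row, col, a + 10)) { placed <- TRUE; break }
    }
    if (!placed) next
    phi <- stats::runif(1, 0, pi)
    blob <- .stampEllipse(matrix(FALSE, nr, nc), row, col, a, b, phi)
    artifactMask <- artifactMask | blob
    allOcc <- allOcc | blob
    px <- sum(blob)
    artifacts <- rbind(artifacts,
                       data.frame(row = row, col = col, a = a, b = b,
                                  phi = phi, area_px = px,
                                  area_um2 = px * spec$pixelSizeUm^2,
                                  below_criterion = px <= 200L))
  }

  gain <- stats::runif(1, spec$exposureGainRange[1], spec$exposureGainRange[2])
  render <- function(fgMask, level) {
    clean <- spec$backgroundIntensity + (level - spec$backgroundIntensity) *
      fgMask
    noisy <- clean * gain + stats::rnorm(nr * nc, 0, spec$noiseSigma)
    matrix(as.integer(pmax(0, pmin(65535, round(noisy)))), nr, nc)
  }
  nuclear <- render(nucMask, spec$nuclearIntensity)
  neurite <- render(neuriteMask | somaMask | artifactMask,
                    spec$neuriteIntensity)

  cal <- Calibration(frameWidthPx = nc, frameHeightPx = nr,
                     pixelSizeUm = spec$pixelSizeUm)
  frame <- micrographFrame(nuclear, neurite, cal, frameId, condition)
  truth <- list(nucleiCount = nrow(nuclei),
                neuronCount = nrow(somata),
                totalNeuriteLengthUm = totalLen,
                branchPointCount = branchPoints,
                neurites = neuriteTab,
                somata = somata,
                nuclei = nuclei,
                artifacts = artifacts,
                exposureGain = gain)
  list(frame = frame, truth = truth)
}

#' Generate a synthetic dose-response plate
#'
#' Control frames plus `framesPerCondition` frames per concentration; the
#' expected neurite length per condition follows a four-parameter-logistic
#' lesion model (scaled relative to its top; the negative default hill
#' slope makes the response decline with dose), with mild lognormal
#' inter-frame variability around the expectation. The ground-truth table
#' records the generating parameters and exact per-frame truths.
#'
#' @param baseSpec a [frameSpec()] describing the control condition.
#' @param concentrations positive concentrations (nM); empty gives a
#'   control-only plate.
#' @param lesionModel list with `top`, `bottom`, `ld50`, `hill`.
#' @param framesPerCondition frames per concentration (and controls).
#' @param compound compound label; controls are labelled `controlLabel`.
#' @param controlLabel solvent-control label (default `"DMSO"`).
#' @param frameCV lognormal coefficient of variation of per-frame expected
#'   length around the condition mean.
#' @return list with `frames` (list of `generateFrame()` results),
#'   `truth` (per-frame data.frame) and the model/design.
#' @export
generateDoseResponsePlate <- function(baseSpec,
                                      concentrations = c(100, 250, 500,
                                                         1000, 2500, 5000),
                                      lesionModel = list(top = 100,
                                                         bottom = 10,
                                                         ld50 = 500,
                                                         hill = -1.2),
                                      framesPerCondition = 6L,
                                      compound = "rotenone",
                                      controlLabel = "DMSO",
                                      frameCV = 0.05) {
  condLabels <- if (length(concentrations))
    paste0(compound, "_", format(concentrations, trim = TRUE,
                                 scientific = FALSE))
  else character(0)
  conds <- data.frame(condition = c(controlLabel, condLabels),
                      concentration_nM = c(0, concentrations),
                      is_control = c(TRUE, rep(FALSE,
                                               length(concentrations))),
                      stringsAsFactors = FALSE)
  frames <- list()
  rows <- list()
  fidx <- 0L
  for (ci in seq_len(nrow(conds))) {
    conc <- conds$concentration_nM[ci]
    frac <- if (conc == 0) 1 else
      fourParamLogistic(conc, lesionModel$top, lesionModel$bottom,
                        lesionModel$ld50, lesionModel$hill) / lesionModel$top
    for (k in seq_len(framesPerCondition)) {
      fidx <- fidx + 1L
      seed <- (baseSpec$seed + 104729L * fidx) %% 2147483647L
      jitter <- .withSeed(seed + 1L, exp(stats::rnorm(1, 0, frameCV)))
      spec <- baseSpec
      spec$neuriteLengthRangeUm <- baseSpec$neuriteLengthRangeUm * frac *
        jitter
      spec$seed <- seed
      id <- sprintf("f%03d_%s", fidx, conds$condition[ci])
      res <- generateFrame(spec, frameId = id,
                           condition = list(
                             compound = if (conc == 0) controlLabel
                                        else compound,
                             concentrationNM = conc,
                             isControl = conds$is_control[ci],
                             experimentId = "E1"))
      frames[[id]] <- res
      rows[[id]] <- data.frame(frame_id = id,
                               condition = conds$condition[ci],
                               concentration_nM = conc,
                               is_control = conds$is_control[ci],
                               expected_fraction = frac,
                               true_total_length_um =
                                 res$truth$totalNeuriteLengthUm,
                               true_nuclei = res$truth$nucleiCount,
                               true_neurons = res$truth$neuronCount,
                               true_branch_points =
                                 res$truth$branchPointCount,
                               stringsAsFactors = FALSE)
    }
  }
  list(frames = frames, truth = do.call(rbind, c(rows,
                                                 make.row.names = FALSE)),
       lesionModel = lesionModel, concentrations = concentrations,
       compound = compound, controlLabel = controlLabel)
}

#' Compact synthetic frame spec used by the validation suites
#'
#' A 360 x 270 px field at the reference pixel size with 3 neurons (2-3
#' neurites of 45-90 um each), 3 non-neuron nuclei and 4 artifacts: small
#' enough to run whole plates through the full pipeline in seconds while
#' exercising every stage.
#'
#' @param seed RNG seed.
#' @param ... overrides passed to [frameSpec()].
#' @return a [frameSpec()].
#' @export
standardTestSpec <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(widthPx = 360L, heightPx = 270L, nNeurons = 3L,
         nNonNeuronNuclei = 3L, somaRadiusRangePx = c(13, 16),
         neuritesPerNeuronRange = c(2L, 3L),
         neuriteLengthRangeUm = c(45, 90), artifactCount = 4L,
         seed = seed),
    list(...))
  do.call(frameSpec, args)
}

#' Write a generated plate as TIFF frames + manifest + truth CSVs
#'
#' Materializes [generateDoseResponsePlate()] output for the batch
#' pipeline: one two-page 16-bit TIFF per frame, `manifest.csv`
#' (columns `path`, `experiment_id`, `condition`, `concentration_nM`,
#' `is_control`) and `truth.csv`.
#'
#' @param plate result of [generateDoseResponsePlate()].
#' @param dir output directory (created if needed).
#' @return path to the manifest, invisibly.
#' @export
writePlate <- function(plate, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(names(plate$frames), function(id) {
    f <- plate$frames[[id]]$frame
    path <- file.path(dir, paste0(id, ".tif"))
    writeFrame(f, path)
    data.frame(path = path,
               experiment_id = f@condition$experimentId,
               condition = if (isTRUE(f@condition$isControl))
                 plate$controlLabel else
                   paste0(f@condition$compound, "_",
                          format(f@condition$concentrationNM,
                                 trim = TRUE, scientific = FALSE)),
               compound = f@condition$compound,
               concentration_nM = f@condition$concentrationNM,
               is_control = f@condition$isControl,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  utils::write.csv(plate$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(mpath)
}
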