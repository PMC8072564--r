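# Shared fixtures: calibrations, canonical masks, and independent
# brute-force oracles (window statistics, medial axis, reconstruction
# checker). Oracles use plain double loops so they share no code path with
# the implementation.

mkCal <- function(w, h) Calibration(frameWidthPx = w, frameHeightPx = h)

mkMask <- function(m) binaryMask(m, mkCal(ncol(m), nrow(m)))

skLenPx <- function(sk) totalLengthUm(sk) / pixelSizeUm(calibration(sk))

diskMatrix <- function(n, cr, cc, r) {
  g <- as.matrix(expand.grid(1:n, 1:n))
  m <- matrix(FALSE, n, n)
  m[g[(g[, 1] - cr)^2 + (g[, 2] - cc)^2 <= r^2, , drop = FALSE]] <- TRUE
  m
}

rectMatrix <- function(nr, nc, r0, r1, c0, c1) {
  m <- matrix(FALSE, nr, nc)
  m[r0:r1, c0:c1] <- TRUE
  m
}

# 400 x 60 px bar with one centred square protrusion of the given outward
# extent (px), as a logical matrix; bar rows 41:100, protrusion above.
barWithProtrusion <- function(extentPx) {
  m <- matrix(FALSE, 140, 440)
  m[41:100, 21:420] <- TRUE
  e <- round(extentPx)
  if (e > 0) {
    half <- max(1, round(extentPx / 2))
    m[(40 - e + 1):40, (220 - half + 1):(220 + half)] <- TRUE
  }
  m
}

rotatedBarMatrix <- function(angleDeg, n = 260, halfLen = 100, halfWid = 20) {
  th <- angleDeg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  g <- as.matrix(expand.grid(1:n, 1:n))
  loc <- t(t(g) - c(n / 2, n / 2)) %*% R
  matrix(abs(loc[, 1]) <= halfLen & abs(loc[, 2]) <= halfWid, n, n)
}

# connected blob of one component with exactly `areaPx` pixels, filled
# row-major inside a strip `wide` columns across
blobOfArea <- function(areaPx, wide = 15L, nr = 40L, nc = 40L) {
  m <- matrix(FALSE, nr, nc)
  full <- areaPx %/% wide
  rest <- areaPx %% wide
  if (full > 0) m[5:(4 + full), 5:(4 + wide)] <- TRUE
  if (rest > 0) m[5 + full, 5:(4 + rest)] <- TRUE
  stopifnot(sum(m) == areaPx)
  m
}

# Brute-force Phansalkar oracle: double loop, symmetric reflective padding.
phansalkarOracle <- function(raster, windowPx, p = 2, q = 10, k = 0.25,
                             rr = 0.5) {
  x <- raster / 65535
  h <- (windowPx - 1) / 2
  nr <- nrow(x); nc <- ncol(x)
  ri <- c(h:1, 1:nr, nr:(nr - h + 1))
  ci <- c(h:1, 1:nc, nc:(nc - h + 1))
  pad <- x[ri, ci]
  out <- matrix(FALSE, nr, nc)
  for (i in 1:nr) {
    for (j in 1:nc) {
      win <- pad[i:(i + 2 * h), j:(j + 2 * h)]
      m <- mean(win)
      s <- sqrt(max(0, mean(win^2) - m^2))
      thr <- m * (1 + p * exp(-q * m) + k * (s / rr - 1))
      out[i, j] <- x[i, j] > thr
    }
  }
  out
}

# Brute-force exact EDT against background pixel centres (image border
# counts as background).
bruteEdt <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  bg <- which(!m, arr.ind = TRUE)
  bg <- rbind(bg,
              cbind(0L, 0:(nc + 1L)), cbind(nr + 1L, 0:(nc + 1L)),
              cbind(0:(nr + 1L), 0L), cbind(0:(nr + 1L), nc + 1L))
  fg <- which(m, arr.ind = TRUE)
  d <- numeric(nrow(fg))
  for (i in seq_len(nrow(fg))) {
    d[i] <- sqrt(min((bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2))
  }
  list(coords = fg, r = d)
}

# Brute-force discrete medial axis: foreground pixels with at least two
# nearest boundary pixels (ties within one pixel of the minimum).
bruteMedialAxis <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  bg <- which(!m, arr.ind = TRUE)
  bg <- rbind(bg,
              cbind(0L, 0:(nc + 1L)), cbind(nr + 1L, 0:(nc + 1L)),
              cbind(0:(nr + 1L), 0L), cbind(0:(nr + 1L), nc + 1L))
  fg <- which(m, arr.ind = TRUE)
  keep <- logical(nrow(fg))
  r <- numeric(nrow(fg))
  for (i in seq_len(nrow(fg))) {
    dd <- sqrt((bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2)
    r[i] <- min(dd)
    keep[i] <- sum(dd <= r[i] + 1) >= 2
  }
  list(coords = fg[keep, , drop = FALSE], r = r[keep])
}

# The pruning criterion re-applied to an arbitrary point set, brute force:
# iteratively drop points that are eps-contained in a strictly larger kept
# disk, provided every already-dropped point stays within the 2*eps
# inflation of some kept disk and the removal does not disconnect the
# remaining set (the homotopy guard a skeleton must obey).
oraclePrune <- function(coords, r, eps) {
  n <- nrow(coords)
  removed <- logical(n)
  gapTo <- function(i, keepIdx) {
    if (length(keepIdx) == 0) return(Inf)
    min(sqrt((coords[keepIdx, 1] - coords[i, 1])^2 +
               (coords[keepIdx, 2] - coords[i, 2])^2) + r[i] - r[keepIdx])
  }
  # local homotopy guard: a point may go only if its remaining neighbours
  # form a single 8-connected cluster within the 3x3 neighbourhood, so
  # curve interiors and cycles (hole topology) are preserved exactly as a
  # homotopic skeleton preserves them
  disconnects <- function(i) {
    nb <- which(!removed & abs(coords[, 1] - coords[i, 1]) <= 1 &
                  abs(coords[, 2] - coords[i, 2]) <= 1)
    nb <- nb[nb != i]
    if (length(nb) <= 1) return(FALSE)
    comp <- seq_along(nb)
    for (a in seq_along(nb)) for (b in seq_along(nb)) {
      if (a < b && abs(coords[nb[a], 1] - coords[nb[b], 1]) <= 1 &&
          abs(coords[nb[a], 2] - coords[nb[b], 2]) <= 1)
        comp[comp == comp[b]] <- comp[a]
    }
    length(unique(comp)) > 1
  }
  repeat {
    changed <- FALSE
    for (i in order(r)) {
      if (removed[i]) next
      kept <- which(!removed)
      kept <- kept[kept != i]
      larger <- kept[r[kept] > r[i]]
      if (gapTo(i, larger) >= eps) next
      if (disconnects(i)) next
      old <- which(removed)
      ok <- TRUE
      for (j in old) {
        if (gapTo(j, kept) >= 2 * eps) { ok <- FALSE; break }
      }
      if (ok) {
        removed[i] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(coords = coords[!removed, , drop = FALSE], r = r[!removed])
}

# Hausdorff distance between two point sets (rows = points).
hausdorff <- function(a, b) {
  if (nrow(a) == 0 && nrow(b) == 0) return(0)
  if (nrow(a) == 0 || nrow(b) == 0) return(Inf)
  dmat <- outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j) {
    sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2)
  })
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

# Independent reconstruction checker: max over foreground pixels of the
# distance to the union of maximal disks, max(0, min_p(|x-p| - r_p)).
# Chunked vectorized arithmetic only; no implementation code reused.
maxUncovered <- function(m, skeleton) {
  pts <- skeleton@points
  if (nrow(pts) == 0) return(if (any(m)) Inf else 0)
  fg <- which(m, arr.ind = TRUE)
  worst <- 0
  step <- 2000L
  for (s in seq(1, nrow(fg), by = step)) {
    idx <- s:min(nrow(fg), s + step - 1L)
    # points are 0-based (x = col-1, y = row-1)
    dd <- outer(fg[idx, 1], pts$y + 1, "-")^2 +
      outer(fg[idx, 2], pts$x + 1, "-")^2
    slack <- sqrt(dd) - rep(pts$r, each = length(idx))
    worst <- max(worst, max(pmin.int(1e18, apply(slack, 1, min))))
  }
  max(0, worst)
}

# Random polyomino: connected union of 3x3-px cells grown by seeded random
# walk inside a <= 40x40 bounding box (cells of a few pixels keep every
# feature wider than a single pixel, where discrete medial axes are
# ambiguous by definition).
randomPolyomino <- function(ncells, blk = 3L, nr = 40L, nc = 40L) {
  gr <- nr %/% blk; gc <- nc %/% blk
  m <- matrix(FALSE, gr, gc)
  pos <- c(gr %/% 2L, gc %/% 2L)
  m[pos[1], pos[2]] <- TRUE
  placed <- 1L
  while (placed < ncells) {
    step <- sample(4L, 1)
    d <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))[[step]]
    cand <- pos + d
    if (any(cand < 1L) || cand[1] > gr || cand[2] > gc) next
    pos <- cand
    if (!m[pos[1], pos[2]]) placed <- placed + 1L
    m[pos[1], pos[2]] <- TRUE
  }
  m[rep(seq_len(gr), each = blk), rep(seq_len(gc), each = blk)]
}

# Random test shape for reconstruction certificates: bars crossing near
# their middles (every arm extends well beyond twice the pruning
# precision), optionally with a central disk. This is the regime the
# epsilon reconstruction bound describes: boundary features are either
# finer than epsilon or coarser than 2*epsilon. Features in between are
# deliberately dropped by the pruning rule (no branch below 2*epsilon),
# leaving a residual bounded by their own extent instead.
randomBlobShape <- function(n = 130L, eps = 10) {
  m <- matrix(FALSE, n, n)
  ctr <- n / 2
  nb <- sample(2:3, 1)
  for (i in seq_len(nb)) {
    w <- sample(22:32, 1)
    len <- sample(104:(n - 10), 1)
    off <- sample(-6:6, 1)   # crossing stays near every bar's middle
    a0 <- round(ctr - len / 2)
    b0 <- round(ctr + off - w / 2)
    if (i %% 2L == 1L) m[b0:(b0 + w), a0:(a0 + len)] <- TRUE
    else m[a0:(a0 + len), b0:(b0 + w)] <- TRUE
  }
  if (runif(1) < 0.5) {
    r <- runif(1, 15, 20)
    m <- m | diskMatrix(n, ctr + sample(-4:4, 1), ctr + sample(-4:4, 1), r)
  }
  m
}
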