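# Propagated-skeleton extraction: EDT-guided homotopic thinning of the
# upscaled neurite mask, branch-graph extraction, and epsilon pruning.
#
# The contract (rather than any particular propagation order) is normative:
#  * every skeleton point carries its maximal-disk radius r = EDT value;
#  * Hausdorff(shape, union of maximal disks) <= epsilon;
#  * boundary protrusions of extent < 2*epsilon generate no branch;
#  * one connected skeleton per connected foreground component.
# Pruning removes terminal-branch tails while the reconstruction stays
# strictly within epsilon; for a square protrusion of extent e on a wide
# bar the junction-stub disks cover e/2 of it, so a branch first enters the
# protrusion at e = 2*epsilon.

#' Upscale a binary mask by nearest-neighbour replication
#'
#' Each source pixel becomes a `factor` x `factor` block; the mask's scale
#' factor is multiplied accordingly. Upscaling by 3 guarantees that 1-px
#' structures in the source are >= 3 px wide, thick enough for the
#' skeletonizer.
#'
#' @param mask a [BinaryMask-class].
#' @param factor integer >= 1.
#' @return upscaled [BinaryMask-class].
#' @export
upscaleMask <- function(mask, factor = 3L) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  if (factor == 1L) return(mask)
  r <- mask@raster
  up <- r[rep(seq_len(nrow(r)), each = factor),
          rep(seq_len(ncol(r)), each = factor), drop = FALSE]
  binaryMask(up, mask@calibration, mask@scaleFactor * factor)
}

# Build the branch graph of a 1-px skeleton raster.
# Returns rows/cols (1-based), adjacency, degrees and branch index paths.
.skGraph <- function(skRaster) {
  idx <- which(skRaster)
  n <- length(idx)
  nr <- nrow(skRaster)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  if (n == 0L)
    return(list(rows = rows, cols = cols, adj = list(), deg = integer(),
                branches = list()))
  lab <- matrix(0L, nr, ncol(skRaster))
  lab[idx] <- seq_len(n)
  ei <- integer(); ej <- integer()
  nc <- ncol(skRaster)
  for (off in list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
                   c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))) {
    rr <- rows + off[1]; cc <- cols + off[2]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    nb <- integer(n)
    nb[ok] <- lab[cbind(rr[ok], cc[ok])]
    hit <- which(nb > 0L)
    if (abs(off[1]) == 1L && abs(off[2]) == 1L && length(hit)) {
      # drop redundant diagonal adjacency when a shared 4-neighbour exists
      s1 <- lab[cbind(rows[hit] + off[1], cols[hit])] > 0L
      s2 <- lab[cbind(rows[hit], cols[hit] + off[2])] > 0L
      hit <- hit[!(s1 | s2)]
    }
    ei <- c(ei, hit); ej <- c(ej, nb[hit])
  }
  adj <- split(ej, factor(ei, levels = seq_len(n)))
  adj <- lapply(adj, function(v) sort(unname(v)))
  deg <- lengths(adj)
  branches <- .traceBranches(adj, deg)
  list(rows = rows, cols = cols, adj = adj, deg = as.integer(deg),
       branches = branches)
}

# Maximal polylines between nodes of degree != 2, plus pure cycles.
.traceBranches <- function(adj, deg) {
  n <- length(deg)
  visited <- lapply(adj, function(v) logical(length(v)))
  branches <- list()
  nodes <- which(deg != 2L)
  for (u in nodes) {
    if (deg[u] == 0L) { branches[[length(branches) + 1L]] <- u; next }
    for (k in seq_along(adj[[u]])) {
      if (visited[[u]][k]) next
      visited[[u]][k] <- TRUE
      v <- adj[[u]][k]
      path <- c(u, v)
      prev <- u
      while (deg[v] == 2L) {
        nbrs <- adj[[v]]
        visited[[v]][nbrs == prev] <- TRUE
        nxt <- nbrs[nbrs != prev]
        if (length(nxt) != 1L) break
        visited[[v]][nbrs == nxt] <- TRUE
        prev <- v
        v <- nxt
        path <- c(path, v)
      }
      visited[[v]][adj[[v]] == prev] <- TRUE
      branches[[length(branches) + 1L]] <- path
    }
  }
  # remaining unvisited edges belong to pure cycles (all degree 2)
  for (u in seq_len(n)) {
    for (k in seq_along(adj[[u]])) {
      if (visited[[u]][k]) next
      visited[[u]][k] <- TRUE
      v <- adj[[u]][k]
      path <- c(u, v)
      prev <- u
      while (v != u) {
        nbrs <- adj[[v]]
        visited[[v]][nbrs == prev] <- TRUE
        nxt <- nbrs[nbrs != prev]
        if (length(nxt) != 1L) break
        visited[[v]][nbrs == nxt] <- TRUE
        prev <- v
        v <- nxt
        path <- c(path, v)
      }
      visited[[v]][adj[[v]] == prev] <- TRUE
      branches[[length(branches) + 1L]] <- path
    }
  }
  branches
}

# Epsilon pruning of terminal-branch tails under witnessed maximal-disk
# containment: a tail point is removable only while some surviving point
# with a strictly larger maximal disk eps-contains its disk
# (|p-q| + r_p - r_q < eps), and previously removed points must keep such
# a direct witness too. Constant-radius trunks (a bar's central segment, a
# neurite's centreline) have no strictly larger witness and are never
# consumed; blob interiors collapse onto their largest disk; a square
# protrusion of extent e on a wide bar first forces a branch into the
# protrusion at e = 2*eps. Passes repeat until no tail can be shortened;
# because witnesses are direct, the reconstruction stays within eps.
.pruneSkeleton <- function(rows, cols, radii, eps) {
  npts <- length(rows)
  removed <- logical(npts)
  if (npts == 0L) return(removed)
  maxRG <- max(radii)
  pad <- maxRG + 2 * eps + 1
  repeat {
    kept <- which(!removed)
    sk <- NULL
    g <- .skGraphPoints(rows[kept], cols[kept])
    changed <- FALSE
    ends <- list()
    for (b in g$branches) {
      if (length(b) < 2L) next
      if (g$deg[b[1]] == 1L) ends[[length(ends) + 1L]] <- kept[b]
      if (g$deg[b[length(b)]] == 1L && b[length(b)] != b[1])
        ends[[length(ends) + 1L]] <- rev(kept[b])
    }
    if (length(ends) == 0L) break
    ord <- order(lengths(ends), vapply(ends, function(b) b[1], integer(1)))
    for (b in ends[ord]) {
      b <- b[!removed[b]]
      m <- length(b) - 1L        # always keep the inner terminal pixel
      if (m < 1L) next
      check <- function(j) {
        rem <- b[seq_len(j)]
        x0 <- min(cols[rem]) - pad; x1 <- max(cols[rem]) + pad
        y0 <- min(rows[rem]) - pad; y1 <- max(rows[rem]) + pad
        inWin <- cols >= x0 & cols <= x1 & rows >= y0 & rows <= y1
        keep <- which(!removed & inWin)
        keep <- setdiff(keep, rem)
        if (length(keep) == 0L) return(FALSE)
        old <- which(removed & inWin)
        .cpp_prune_ok(cols[rem], rows[rem], radii[rem],
                      cols[old], rows[old], radii[old],
                      cols[keep], rows[keep], radii[keep], eps)
      }
      lo <- 0L; hi <- m
      while (lo < hi) {
        mid <- (lo + hi + 1L) %/% 2L
        if (check(mid)) lo <- mid else hi <- mid - 1L
      }
      if (lo > 0L) {
        removed[b[seq_len(lo)]] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # collapse degenerate residues: a tiny near-coincident component (equal
  # maximal disks have no strictly larger witness) reduces to its largest
  # disk, so a discrete disk's skeleton is a single point
  kept <- which(!removed)
  g <- .skGraphPoints(rows[kept], cols[kept])
  comp <- .componentsOf(g$adj)
  for (cid in unique(comp)) {
    mem <- kept[comp == cid]
    if (length(mem) < 2L || length(mem) > 4L) next
    if (max(dist(cbind(rows[mem], cols[mem]))) > 3) next
    best <- mem[which.max(radii[mem])]
    removed[setdiff(mem, best)] <- TRUE
  }
  removed
}

# Connected-component id per node from an adjacency list.
.componentsOf <- function(adj) {
  n <- length(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      u <- queue[[1]]
      queue <- queue[-1]
      for (v in adj[[u]]) if (comp[v] == 0L) {
        comp[v] <- cur
        queue <- c(queue, v)
      }
    }
  }
  comp
}

# Graph of a skeleton given as point coordinates (1-based rows/cols).
.skGraphPoints <- function(rows, cols) {
  if (length(rows) == 0L)
    return(list(rows = rows, cols = cols, adj = list(), deg = integer(),
                branches = list()))
  nr <- max(rows) + 1L
  nc <- max(cols) + 1L
  sk <- matrix(FALSE, nr, nc)
  sk[cbind(rows, cols)] <- TRUE
  .skGraph(sk)
}

# Assemble a NeuriteSkeleton from a skeleton raster + EDT radii.
.skeletonFromRaster <- function(skRaster, dmap, epsilonPx, scale, cal) {
  g <- .skGraph(skRaster)
  pts <- data.frame(x = g$cols - 1, y = g$rows - 1,
                    r = if (length(g$rows)) dmap[cbind(g$rows, g$cols)]
                        else numeric(0))
  new("NeuriteSkeleton", points = pts, branches = g$branches,
      epsilonPx = epsilonPx, scaleFactor = as.integer(scale),
      calibration = cal, maskDim = dim(skRaster))
}

#' Compute the epsilon-pruned propagated skeleton of a binary mask
#'
#' Per 8-connected foreground component, a centred one-pixel skeleton is
#' propagated inward along increasing distance-transform values (homotopic
#' thinning preserving endpoints), then terminal branches are pruned while
#' the maximal-disk reconstruction of the shape stays strictly within
#' `epsilonPx` Hausdorff distance. Small boundary protrusions (extent below
#' `2 * epsilonPx`) therefore generate no branch.
#'
#' @param mask a [BinaryMask-class] (typically the neurite mask after
#'   [upscaleMask()]).
#' @param epsilonPx pruning precision in mask pixels (> 0); default 10.
#' @return a [NeuriteSkeleton-class]; an empty mask yields an empty
#'   skeleton.
#' @export
skeletonizePropagated <- function(mask, epsilonPx = 10) {
  if (epsilonPx <= 0) stop("epsilonPx must be > 0")
  r <- mask@raster
  if (!any(r)) {
    return(new("NeuriteSkeleton",
               points = data.frame(x = numeric(), y = numeric(),
                                   r = numeric()),
               branches = list(), epsilonPx = epsilonPx,
               scaleFactor = mask@scaleFactor,
               calibration = mask@calibration, maskDim = dim(r)))
  }
  d <- .distmapPadded(r)
  sk <- .cpp_thin(matrix(as.integer(r), nrow(r), ncol(r)), d) > 0L
  g <- .skGraph(sk)
  radii <- d[cbind(g$rows, g$cols)]
  removed <- .pruneSkeleton(g$rows, g$cols, radii, epsilonPx)
  if (any(removed)) {
    sk[cbind(g$rows[removed], g$cols[removed])] <- FALSE
  }
  .skeletonFromRaster(sk, d, epsilonPx, mask@scaleFactor, mask@calibration)
}

#' Construct a NeuriteSkeleton directly
#'
#' Mainly for interoperability and testing; [skeletonizePropagated()] is
#' the usual producer.
#'
#' @param points data.frame with columns `x`, `y`, `r` (0-based pixel
#'   coordinates, maximal-disk radius in px).
#' @param branches list of integer index vectors into `points`.
#' @param epsilonPx pruning precision recorded with the skeleton.
#' @param scaleFactor integer scale of the skeletonized mask.
#' @param cal source-frame [Calibration-class].
#' @param maskDim dimensions (rows, cols) of the skeletonized raster.
#' @return a [NeuriteSkeleton-class].
#' @export
neuriteSkeleton <- function(points, branches, epsilonPx = 10,
                            scaleFactor = 1L, cal = Calibration(),
                            maskDim = c(0L, 0L)) {
  new("NeuriteSkeleton", points = points, branches = branches,
      epsilonPx = epsilonPx, scaleFactor = as.integer(scaleFactor),
      calibration = cal, maskDim = as.integer(maskDim))
}

# Moving-average smoothing of a polyline (endpoints pinned); removes the
# pixel-staircase length bias of 8-connected chains.
.smoothPolyline <- function(m, window = 5L) {
  k <- nrow(m)
  if (k <= 2L) return(m)
  h <- (window - 1L) %/% 2L
  i <- seq_len(k)
  a <- pmax(1L, i - h); b <- pmin(k, i + h)
  cs <- rbind(0, apply(m, 2, cumsum))
  out <- (cs[b + 1L, , drop = FALSE] - cs[a, , drop = FALSE]) / (b - a + 1L)
  out[1L, ] <- m[1L, ]
  out[k, ] <- m[k, ]
  out
}

.branchLengthPx <- function(m) {
  if (nrow(m) < 2L) return(0)
  sm <- .smoothPolyline(m)
  sum(sqrt(rowSums(diff(sm)^2)))
}

#' @rdname branchStatistics
#' @export
setMethod("branchStatistics", "NeuriteSkeleton", function(skeleton) {
  bs <- skeleton@branches[lengths(skeleton@branches) >= 2L]
  ends <- unlist(lapply(bs, function(b) c(b[1], b[length(b)])),
                 use.names = FALSE)
  degTab <- table(ends)
  list(endpoint_count = sum(degTab == 1L),
       branch_point_count = sum(degTab >= 3L),
       branch_segment_count = length(bs))
})

#' @rdname branchStatistics
#' @export
setMethod("totalLengthUm", "NeuriteSkeleton", function(skeleton) {
  bs <- skeleton@branches[lengths(skeleton@branches) >= 2L]
  if (length(bs) == 0L) return(0)
  px <- sum(vapply(bs, function(b) {
    .branchLengthPx(cbind(skeleton@points$x[b], skeleton@points$y[b]))
  }, numeric(1)))
  px / skeleton@scaleFactor * skeleton@calibration@pixelSizeUm
})

setMethod("show", "NeuriteSkeleton", function(object) {
  st <- branchStatistics(object)
  cat(sprintf(paste0("NeuriteSkeleton: %d point(s), %d segment(s), ",
                     "%d endpoint(s), %d branch point(s)\n"),
              nrow(object@points), st$branch_segment_count,
              st$endpoint_count, st$branch_point_count))
  cat(sprintf("  epsilon = %g px (upscaled), scale %dx, total length %.2f um\n",
              object@epsilonPx, object@scaleFactor, totalLengthUm(object)))
})

#' Export skeleton branches as an edge-list text file
#'
#' One line per consecutive polyline segment: `x0 y0 x1 y1` in 0-based
#' upscaled-pixel coordinates.
#'
#' @param skeleton a [NeuriteSkeleton-class].
#' @param path output text file.
#' @return `path`, invisibly.
#' @export
exportSkeletonEdges <- function(skeleton, path) {
  segs <- do.call(rbind, lapply(skeleton@branches, function(b) {
    if (length(b) < 2L) return(NULL)
    cbind(skeleton@points$x[b[-length(b)]], skeleton@points$y[b[-length(b)]],
          skeleton@points$x[b[-1]], skeleton@points$y[b[-1]])
  }))
  if (is.null(segs)) segs <- matrix(numeric(0), 0, 4)
  utils::write.table(segs, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
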