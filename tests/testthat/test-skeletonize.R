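# Upscaling, the epsilon-pruned skeleton on canonical shapes, branch
# statistics and length measurement.

test_that("nearest-neighbour upscaling replicates pixels exactly", {
  m <- matrix(runif(100) < 0.4, 10, 10)
  mk <- mkMask(m)
  up <- upscaleMask(mk, 3L)
  expect_equal(dim(maskRaster(up)), c(30L, 30L))
  expect_equal(sum(maskRaster(up)), 9L * sum(m))
  expect_equal(scaleFactor(up), 3L)
  expect_identical(maskRaster(upscaleMask(mk, 1L)), m)
  expect_error(upscaleMask(mk, 0L), ">= 1")
})

test_that("a wide rectangle skeletonizes to its central segment", {
  m <- rectMatrix(80, 240, 21, 60, 21, 220)  # 200 x 40
  sk <- skeletonizePropagated(mkMask(m), 10)
  st <- branchStatistics(sk)
  expect_equal(st$branch_segment_count, 1L)
  expect_equal(st$endpoint_count, 2L)
  expect_equal(st$branch_point_count, 0L)
  expect_lt(abs(skLenPx(sk) - 160), 3)
})

test_that("a discrete disk collapses to a near-point skeleton", {
  sk <- skeletonizePropagated(mkMask(diskMatrix(100, 50, 50, 30)), 10)
  expect_lte(skLenPx(sk), 2)
  expect_lte(nrow(sk@points), 3)
})

test_that("an empty mask yields an empty skeleton with zero statistics", {
  sk <- skeletonizePropagated(mkMask(matrix(FALSE, 20, 20)), 10)
  expect_equal(nrow(sk@points), 0L)
  expect_equal(totalLengthUm(sk), 0)
  st <- branchStatistics(sk)
  expect_equal(unlist(st), c(endpoint_count = 0L, branch_point_count = 0L,
                             branch_segment_count = 0L))
})

test_that("skeleton radii equal the boundary distance within one pixel", {
  m <- diskMatrix(90, 45, 45, 20) | rectMatrix(90, 90, 42, 48, 10, 80)
  sk <- skeletonizePropagated(mkMask(m), 5)
  ref <- bruteEdt(m)
  key <- paste(ref$coords[, 1], ref$coords[, 2])
  refR <- setNames(ref$r, key)
  got <- sk@points
  expect_true(all(abs(got$r - refR[paste(got$y + 1, got$x + 1)]) <= 1))
})

test_that("branch statistics classify paths and stars", {
  bar <- rectMatrix(40, 120, 18, 22, 10, 110)
  stBar <- branchStatistics(skeletonizePropagated(mkMask(bar), 10))
  expect_equal(stBar$endpoint_count, 2L)
  expect_equal(stBar$branch_point_count, 0L)
  expect_equal(stBar$branch_segment_count, 1L)
  # Y shape: three 5-px-wide arms from a centre
  y <- matrix(FALSE, 120, 120)
  y[58:62, 10:60] <- TRUE
  y[10:60, 58:62] <- TRUE
  y[58:62, 60:110] <- TRUE
  stY <- branchStatistics(skeletonizePropagated(mkMask(y), 8))
  expect_equal(stY$endpoint_count, 3L)
  expect_equal(stY$branch_point_count, 1L)
  expect_equal(stY$branch_segment_count, 3L)
})

test_that("total length converts upscaled pixels through the scale factor", {
  pts <- data.frame(x = 0:300, y = rep(0, 301), r = rep(6, 301))
  sk <- neuriteSkeleton(pts, list(1:301), epsilonPx = 10, scaleFactor = 3L,
                        cal = Calibration(), maskDim = c(10L, 310L))
  expect_equal(round(totalLengthUm(sk), 2), 64.31)  # 100 source px
  sk1 <- neuriteSkeleton(pts, list(1:301), epsilonPx = 10, scaleFactor = 1L,
                         cal = Calibration(), maskDim = c(10L, 310L))
  expect_equal(totalLengthUm(sk1), 3 * totalLengthUm(sk))
})

test_that("increasing epsilon never increases total skeleton length", {
  shapes <- list(rectMatrix(80, 240, 21, 60, 21, 220),
                 rotatedBarMatrix(30),
                 barWithProtrusion(25))
  for (m in shapes) {
    lens <- vapply(c(2, 5, 10, 20), function(e)
      skLenPx(skeletonizePropagated(mkMask(m), e)), numeric(1))
    expect_true(all(diff(lens) <= 1e-6))
  }
})

test_that("skeleton length is robust to rotation of the shape", {
  axis <- skLenPx(skeletonizePropagated(mkMask(rotatedBarMatrix(0)), 10))
  rot <- skLenPx(skeletonizePropagated(mkMask(rotatedBarMatrix(30)), 10))
  expect_lt(abs(rot - axis) / axis, 0.05)
})

test_that("each connected foreground component yields one skeleton component", {
  m <- diskMatrix(120, 30, 30, 15) | rectMatrix(120, 120, 80, 86, 20, 100)
  sk <- skeletonizePropagated(mkMask(m), 5)
  g <- neuritracer:::.skGraphPoints(sk@points$y + 1L, sk@points$x + 1L)
  expect_equal(max(neuritracer:::.componentsOf(g$adj)), 2L)
})

test_that("protrusions below twice epsilon generate no branch", {
  enters <- function(extent) {
    sk <- skeletonizePropagated(mkMask(barWithProtrusion(extent)), 10)
    any(sk@points$y + 1 <= 40)
  }
  expect_false(enters(17.5))
  expect_true(enters(20))
})

test_that("edge-list export writes one segment per polyline edge", {
  bar <- rectMatrix(30, 80, 13, 17, 10, 70)
  sk <- skeletonizePropagated(mkMask(bar), 10)
  f <- withr::local_tempfile(fileext = ".txt")
  exportSkeletonEdges(sk, f)
  segs <- utils::read.table(f)
  expect_equal(ncol(segs), 4L)
  expect_equal(nrow(segs),
               sum(pmax(0L, lengths(sk@branches) - 1L)))
})
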