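# Distance-transform watershed separation of clustered nuclei and region
# measurement.

test_that("degenerate nuclear masks yield zero regions, flagged undefined", {
  empty <- binaryMask(matrix(FALSE, 30, 30), mkCal(30, 30))
  regions <- splitTouchingNuclei(empty)
  expect_equal(regionCount(regions), 0L)
  meas <- measureRegions(regions)
  expect_equal(meas$count, 0L)
  expect_true(meas$undefined)
  expect_true(is.na(meas$mean_area_um2))
})

test_that("a single disk stays one region; a touching pair splits in two", {
  one <- diskMatrix(60, 30, 30, 12)
  r1 <- splitTouchingNuclei(mkMask(one))
  expect_equal(regionCount(r1), 1L)
  pair <- diskMatrix(60, 30, 20, 12) | diskMatrix(60, 30, 38, 12)
  expect_equal(max(labelComponents(pair)), 1L)  # genuinely fused input
  r2 <- splitTouchingNuclei(mkMask(pair))
  expect_equal(regionCount(r2), 2L)
})

test_that("K overlapping disks are recovered exactly over 50 placements", {
  set.seed(77)
  rad <- 12
  hits <- 0L
  for (rep in 1:50) {
    k <- sample(2:6, 1)
    centers <- matrix(numeric(0), 0, 2)
    while (nrow(centers) < k) {
      cand <- runif(2, rad + 5, 220 - rad - 5)
      if (nrow(centers) == 0 ||
          all(sqrt(rowSums(t(t(centers) - cand)^2)) >= 1.5 * rad))
        centers <- rbind(centers, cand)
    }
    m <- matrix(FALSE, 220, 220)
    for (i in seq_len(k)) m <- m | diskMatrix(220, centers[i, 1],
                                              centers[i, 2], rad)
    got <- regionCount(splitTouchingNuclei(mkMask(m)))
    hits <- hits + (got == k)
  }
  expect_equal(hits, 50L)
})

test_that("region areas conserve the foreground and labels are consecutive", {
  set.seed(5)
  m <- diskMatrix(80, 25, 25, 11) | diskMatrix(80, 40, 38, 12) |
    diskMatrix(80, 60, 60, 9)
  regions <- splitTouchingNuclei(mkMask(m))
  tab <- regionTable(regions)
  expect_equal(sum(tab$area_px), sum(m))
  expect_equal(tab$label, seq_len(nrow(tab)))
  expect_true(all(tab$eccentricity >= 0 & tab$eccentricity < 1))
})

test_that("region count is invariant under translation and 90-degree rotation", {
  base <- diskMatrix(80, 30, 26, 12) | diskMatrix(80, 30, 44, 12)
  shifted <- matrix(FALSE, 80, 80)
  shifted[11:80, 11:80] <- base[1:70, 1:70]
  rotated <- t(base)[, 80:1]
  counts <- vapply(list(base, shifted, rotated), function(m)
    regionCount(splitTouchingNuclei(mkMask(m))), integer(1))
  expect_true(all(counts == counts[1]))
})

test_that("measureRegions reports physical areas and their mean", {
  cal <- mkCal(60, 60)
  m <- rectMatrix(60, 60, 5, 14, 5, 14)  # one 10x10 region
  regions <- splitTouchingNuclei(binaryMask(m, cal))
  meas <- measureRegions(regions)
  expect_equal(round(meas$area_um2, 2), 41.36)
  # three well-separated rectangles of 100, 200, 300 px
  m3 <- rectMatrix(60, 60, 2, 11, 2, 11) |
    rectMatrix(60, 60, 2, 11, 30, 49) |
    rectMatrix(60, 60, 40, 54, 10, 29)
  meas3 <- measureRegions(splitTouchingNuclei(binaryMask(m3, cal)))
  expect_equal(meas3$count, 3L)
  expect_equal(meas3$mean_area_um2, 200 * DEFAULT_PIXEL_SIZE_UM^2)
})
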