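# Brightness reduction, Phansalkar thresholding (vs brute-force window
# oracle), closing and the plausibility-area filter.

test_that("Phansalkar matches the double-loop window oracle exactly", {
  set.seed(7)
  cal <- mkCal(16, 16)
  for (rep in 1:6) {
    x <- matrix(as.integer(runif(256, 0, 65535)), 16)
    for (w in c(5L, 9L)) {
      got <- binarizePhansalkar(x, cal, preprocessParams(windowPx = w))
      expect_identical(maskRaster(got), phansalkarOracle(x, w))
    }
  }
})

test_that("Phansalkar handles degenerate rasters as the formula dictates", {
  cal <- mkCal(16, 16)
  zero <- matrix(0L, 16, 16)
  expect_false(any(maskRaster(binarizePhansalkar(zero, cal,
                                                 preprocessParams(windowPx = 5L)))))
  # constant full scale: T = 1 * (1 + 2 e^-10 - 0.25) ~ 0.7501 < 1
  ones <- matrix(65535L, 16, 16)
  expect_true(all(maskRaster(binarizePhansalkar(ones, cal,
                                                preprocessParams(windowPx = 5L)))))
  expect_error(binarizePhansalkar(zero, cal, preprocessParams(windowPx = 25L)),
               "window")
})

test_that("a bright square on dark background thresholds to the square", {
  cal <- mkCal(9, 9)
  x <- matrix(as.integer(0.05 * 65535), 9, 9)
  x[4:6, 4:6] <- 65535L
  got <- maskRaster(binarizePhansalkar(x, cal, preprocessParams(windowPx = 9L)))
  expect_identical(got, phansalkarOracle(x, 9L))
  want <- matrix(FALSE, 9, 9); want[4:6, 4:6] <- TRUE
  expect_identical(got, want)
})

test_that("brightness reduction triggers only on saturated rasters", {
  p <- preprocessParams()
  x <- matrix(as.integer(runif(1e4, 0, 50000)), 100)
  expect_identical(normalizeBrightness(x, p), x)       # no saturation
  const <- matrix(65535L, 50, 50)
  expect_identical(normalizeBrightness(const, p), const)
  sat <- matrix(30000L, 100, 100)
  sat[1:500] <- 65535L                                  # 5% at full scale
  v <- stats::quantile(sat, 0.999, names = FALSE)
  out <- normalizeBrightness(sat, p)
  expect_equal(max(out), 65535L)
  expect_equal(out[sat == v][1], 65535L)                # clip value -> full scale
  expect_error(normalizeBrightness(matrix(integer(0), 0, 0), p), "empty")
})

test_that("closing bridges small gaps and leaves solids untouched", {
  cal <- mkCal(9, 9)
  m <- matrix(FALSE, 9, 9); m[5, 3] <- TRUE; m[5, 6] <- TRUE
  closed <- closeMask(binaryMask(m, cal), preprocessParams(closingRadiusPx = 2L))
  expect_equal(max(labelComponents(closed)), 1L)
  solid <- rectMatrix(9, 9, 3, 7, 3, 7)
  expect_identical(maskRaster(closeMask(binaryMask(solid, cal),
                                        preprocessParams(closingRadiusPx = 1L))),
                   solid)
  empty <- binaryMask(matrix(FALSE, 9, 9), cal)
  expect_false(any(maskRaster(closeMask(empty))))
})

test_that("plausibility filter removes small components at the stated area", {
  cal <- mkCal(40, 40)
  sq14 <- rectMatrix(40, 40, 5, 18, 5, 18)    # 196 px^2 = 81.06 um^2
  expect_false(any(maskRaster(filterImplausible(binaryMask(sq14, cal)))))
  sq15 <- rectMatrix(40, 40, 5, 19, 5, 19)    # 225 px^2 = 93.05 um^2
  expect_identical(maskRaster(filterImplausible(binaryMask(sq15, cal))), sq15)
  empty <- binaryMask(matrix(FALSE, 40, 40), cal)
  expect_false(any(maskRaster(filterImplausible(empty))))
})

test_that("plausibility filter never adds pixels and is idempotent", {
  set.seed(11)
  cal <- mkCal(60, 60)
  for (rep in 1:5) {
    m <- matrix(runif(3600) < 0.3, 60, 60)
    f1 <- filterImplausible(binaryMask(m, cal))
    expect_true(all(m[maskRaster(f1)]))
    f2 <- filterImplausible(f1)
    expect_identical(maskRaster(f2), maskRaster(f1))
  }
})

test_that("connected-component labelling is 8-connected and consecutive", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE          # diagonal pair: one component
  m[5:6, 5:6] <- TRUE
  lab <- labelComponents(m)
  expect_equal(max(lab), 2L)
  expect_equal(sort(unique(lab[lab > 0])), 1:2)
  expect_equal(lab[2, 2], lab[3, 3])
})

test_that("the full preprocessing chain is deterministic", {
  res <- generateFrame(standardTestSpec(seed = 3), "d")
  cal <- calibration(res$frame)
  a <- preprocessChannel(neuriteChannel(res$frame), cal)
  b <- preprocessChannel(neuriteChannel(res$frame), cal)
  expect_identical(maskRaster(a), maskRaster(b))
})

test_that("preprocess parameter validation rejects bad windows", {
  expect_error(preprocessParams(windowPx = 4), "odd")
  expect_error(preprocessParams(windowPx = 1), "odd")
  expect_error(preprocessParams(maxImplausibleAreaUm2 = 0), "> 0")
})
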