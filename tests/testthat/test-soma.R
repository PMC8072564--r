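# Soma detection, neuron identification, orphan removal, skeleton-soma
# combination and neurite area.

somaFixture <- function() {
  # disk soma (r = 15) with a 4-px-wide arm, nucleus inside the disk
  neurite <- diskMatrix(120, 60, 30, 15)
  neurite[58:61, 30:110] <- TRUE
  nuc <- diskMatrix(120, 60, 30, 8)
  nucRegions <- splitTouchingNuclei(mkMask(nuc))
  list(neurite = mkMask(neurite), nuclei = nucRegions)
}

test_that("somata are the thick mask cores; thin arms contribute nothing", {
  fx <- somaFixture()
  soma <- detectSomata(fx$neurite, fx$nuclei, somaRadiusPx = 8)
  sm <- maskRaster(soma)
  expect_true(any(sm))
  expect_true(all(maskRaster(fx$neurite)[sm]))         # soma subset of mask
  idx <- which(sm, arr.ind = TRUE)
  dCenter <- sqrt((idx[, 1] - 60)^2 + (idx[, 2] - 30)^2)
  expect_lte(max(dCenter), 17)                          # no spread down the arm
  onlyLines <- matrix(FALSE, 60, 60); onlyLines[20:23, 5:55] <- TRUE
  somaNone <- detectSomata(mkMask(onlyLines), fx$nuclei, somaRadiusPx = 8)
  expect_false(any(maskRaster(somaNone)))
  empty <- mkMask(matrix(FALSE, 60, 60))
  expect_false(any(maskRaster(detectSomata(empty, fx$nuclei, 8))))
})

test_that("neurons are nuclei that intersect the neurite mask", {
  neurite <- matrix(FALSE, 80, 80); neurite[38:42, 10:70] <- TRUE
  nucs <- diskMatrix(80, 40, 20, 7) | diskMatrix(80, 15, 60, 7)
  regions <- splitTouchingNuclei(mkMask(nucs))
  asn <- identifyNeurons(regions, mkMask(neurite))
  expect_equal(asn@neuronCount, 1L)
  noOverlap <- matrix(FALSE, 80, 80); noOverlap[70:74, 10:70] <- TRUE
  expect_equal(identifyNeurons(regions, mkMask(noOverlap))@neuronCount, 0L)
  emptyReg <- splitTouchingNuclei(mkMask(matrix(FALSE, 80, 80)))
  expect_equal(identifyNeurons(emptyReg, mkMask(neurite))@neuronCount, 0L)
})

test_that("orphan neurite components are removed, anchored ones kept", {
  neurite <- matrix(FALSE, 80, 120)
  neurite[38:42, 5:55] <- TRUE     # component through the nucleus
  neurite[60:70, 80:110] <- TRUE   # orphan blob
  nucs <- matrix(FALSE, 80, 120)
  nucs[1:80, 1:80] <- diskMatrix(80, 40, 20, 7)
  regions <- splitTouchingNuclei(mkMask(nucs))
  mask <- binaryMask(neurite, mkCal(120, 80))
  asn <- identifyNeurons(regions, mask)
  cleaned <- removeOrphanComponents(mask, asn, regions)
  expect_true(any(maskRaster(cleaned)[38:42, 5:55]))
  expect_false(any(maskRaster(cleaned)[60:70, 80:110]))
  expect_equal(identifyNeurons(regions, cleaned)@neuronCount,
               asn@neuronCount)
  # all components anchored -> unchanged
  again <- removeOrphanComponents(cleaned, asn, regions)
  expect_identical(maskRaster(again), maskRaster(cleaned))
  empty <- binaryMask(matrix(FALSE, 80, 120), mkCal(120, 80))
  expect_false(any(maskRaster(removeOrphanComponents(empty, asn, regions))))
})

test_that("soma overlap clips a crossing skeleton by the chord length", {
  bar <- rectMatrix(100, 200, 48, 52, 10, 190)
  sk <- skeletonizePropagated(mkMask(bar), 10)
  full <- skLenPx(sk)
  r <- 20
  somaM <- matrix(FALSE, 100, 200)
  somaM[1:100, 51:150] <- diskMatrix(100, 50, 50, r)
  soma <- binaryMask(somaM, mkCal(200, 100))
  clipped <- pruneSomaOverlap(sk, soma)
  expect_lt(abs((full - skLenPx(clipped)) - 2 * r), 2.5)
  # idempotence and monotonicity
  twice <- pruneSomaOverlap(clipped, soma)
  expect_equal(skLenPx(twice), skLenPx(clipped))
  expect_lte(skLenPx(clipped), full)
  # no soma -> unchanged; skeleton fully inside -> empty
  none <- binaryMask(matrix(FALSE, 100, 200), mkCal(200, 100))
  expect_equal(skLenPx(pruneSomaOverlap(sk, none)), full)
  all <- binaryMask(matrix(TRUE, 100, 200), mkCal(200, 100))
  expect_equal(nrow(pruneSomaOverlap(sk, all)@points), 0L)
})

test_that("soma overlap pruning works across the upscale factor", {
  bar <- rectMatrix(60, 120, 28, 32, 10, 110)
  up <- upscaleMask(mkMask(bar), 3L)
  sk <- skeletonizePropagated(up, 10)
  somaM <- matrix(FALSE, 60, 120)
  somaM[1:60, 31:90] <- diskMatrix(60, 30, 30, 12)
  soma <- binaryMask(somaM, mkCal(120, 60))
  clipped <- pruneSomaOverlap(sk, soma)
  expect_lt(skLenPx(clipped), skLenPx(sk))
  # clipped vertices all outside the upscaled soma
  upSoma <- maskRaster(upscaleMask(soma, 3L))
  expect_false(any(upSoma[cbind(clipped@points$y + 1, clipped@points$x + 1)]))
})

test_that("neurite area subtracts the soma in physical units", {
  cal <- mkCal(60, 60)
  neurite <- matrix(FALSE, 60, 60); neurite[11:30, 11:35] <- TRUE  # 500 px
  soma <- matrix(FALSE, 60, 60); soma[11:22, 11:20] <- TRUE        # 120 px
  expect_equal(neuriteAreaUm2(binaryMask(neurite, cal),
                              binaryMask(soma, cal)),
               380 * DEFAULT_PIXEL_SIZE_UM^2)
  disjoint <- matrix(FALSE, 60, 60); disjoint[40:50, 40:50] <- TRUE
  expect_equal(neuriteAreaUm2(binaryMask(neurite, cal),
                              binaryMask(disjoint, cal)),
               500 * DEFAULT_PIXEL_SIZE_UM^2)
  expect_equal(neuriteAreaUm2(binaryMask(neurite, cal),
                              binaryMask(neurite, cal)), 0)
  expect_error(neuriteAreaUm2(binaryMask(neurite, cal),
                              binaryMask(matrix(FALSE, 30, 30), mkCal(30, 30))),
               "dimensions")
})
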