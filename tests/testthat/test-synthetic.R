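# The synthetic-frame generator: determinism, exact ground truth,
# degenerate specs and the dose-response plate design.

test_that("generation is bit-reproducible and restores the RNG state", {
  spec <- standardTestSpec(seed = 12)
  set.seed(999)
  before <- runif(1)
  set.seed(999)
  a <- generateFrame(spec, "a")
  after <- runif(1)
  b <- generateFrame(spec, "b")
  expect_identical(a$frame@nuclearChannel, b$frame@nuclearChannel)
  expect_identical(a$frame@neuriteChannel, b$frame@neuriteChannel)
  expect_identical(a$truth$totalNeuriteLengthUm,
                   b$truth$totalNeuriteLengthUm)
  expect_equal(before, after)  # caller RNG stream untouched
})

test_that("ground-truth length equals the summed polyline lengths exactly", {
  res <- generateFrame(standardTestSpec(seed = 6), "t")
  expect_equal(res$truth$totalNeuriteLengthUm,
               sum(res$truth$neurites$length_um))
  expect_equal(res$truth$branchPointCount,
               sum(res$truth$neurites$branch_points))
  expect_equal(res$truth$nucleiCount, nrow(res$truth$nuclei))
  expect_equal(res$truth$neuronCount, nrow(res$truth$somata))
})

test_that("a spec with no neurons yields a background-only neurite channel", {
  spec <- standardTestSpec(seed = 8, nNeurons = 0L, nNonNeuronNuclei = 0L,
                           artifactCount = 0L)
  res <- generateFrame(spec, "blank")
  expect_equal(res$truth$totalNeuriteLengthUm, 0)
  mask <- preprocessChannel(neuriteChannel(res$frame),
                            calibration(res$frame))
  expect_false(any(maskRaster(mask)))
})

test_that("an overcrowded spec fails with a clear error", {
  spec <- standardTestSpec(seed = 1, widthPx = 120L, heightPx = 100L,
                           nNeurons = 12L)
  expect_error(generateFrame(spec), "overcrowded")
})

test_that("artifact inventory records drawn blobs on both sides of the criterion", {
  res <- generateFrame(standardTestSpec(seed = 15), "t")
  art <- res$truth$artifacts
  expect_gt(nrow(art), 0)
  expect_equal(art$below_criterion, art$area_px <= 200)
  expect_true(any(art$below_criterion) && any(!art$below_criterion))
  expect_equal(art$area_um2, art$area_px * DEFAULT_PIXEL_SIZE_UM^2)
})

test_that("an empty concentration list gives a control-only plate", {
  plate <- generateDoseResponsePlate(standardTestSpec(seed = 3),
                                     concentrations = numeric(0),
                                     framesPerCondition = 2L)
  expect_equal(length(plate$frames), 2L)
  expect_true(all(plate$truth$is_control))
})

test_that("per-condition truth follows the lesion model", {
  plate <- generateDoseResponsePlate(standardTestSpec(seed = 101),
                                     framesPerCondition = 3L)
  tr <- plate$truth
  ctrl <- mean(tr$true_total_length_um[tr$is_control])
  for (conc in unique(tr$concentration_nM[!tr$is_control])) {
    frac <- mean(tr$true_total_length_um[tr$concentration_nM == conc]) / ctrl
    expected <- fourParamLogistic(conc, 100, 10, 500, -1.2) / 100
    expect_lt(abs(frac - expected), 0.12)
  }
})

test_that("more frames per condition reduce the SEM of condition means", {
  sems <- vapply(c(4L, 16L), function(n) {
    plate <- generateDoseResponsePlate(standardTestSpec(seed = 5),
                                       concentrations = c(500),
                                       framesPerCondition = n)
    tr <- plate$truth
    v <- tr$true_total_length_um[!tr$is_control]
    stats::sd(v) / sqrt(length(v))
  }, numeric(1))
  expect_lt(sems[2], sems[1])
})

test_that("plates materialize as readable TIFFs plus manifest and truth", {
  plate <- generateDoseResponsePlate(standardTestSpec(seed = 2),
                                     concentrations = c(500),
                                     framesPerCondition = 1L)
  dir <- withr::local_tempdir()
  mpath <- writePlate(plate, dir)
  manifest <- utils::read.csv(mpath)
  expect_equal(nrow(manifest), 2L)
  expect_true(all(file.exists(manifest$path)))
  fr <- readFrame(manifest$path[1],
                  Calibration(frameWidthPx = 360L, frameHeightPx = 270L))
  expect_s4_class(fr, "MicrographFrame")
  expect_true(file.exists(file.path(dir, "truth.csv")))
})
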