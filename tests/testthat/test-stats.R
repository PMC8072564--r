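# Metrics assembly, control normalization, constrained 4PL dose-response
# fitting and OLS method comparison.

test_that("per-cell metrics divide by the configured denominator", {
  res <- generateFrame(standardTestSpec(seed = 2), "m1")
  out <- processFrame(res$frame, pipelineConfig(), keepIntermediates = TRUE)
  m <- out$metrics
  expect_equal(m$neurite_length_per_cell_um,
               m$total_neurite_length_um / m$nuclei_count)
  expect_false(m$excluded)
  mN <- computeImageMetrics(res$frame, out$nuclei, out$assignment,
                            out$somaMask, out$neuriteMask, out$skeleton,
                            denominator = "neurons")
  expect_equal(mN$neurite_length_per_cell_um,
               mN$total_neurite_length_um / mN$neuron_count)
})

test_that("a frame with no nuclei is excluded, not an error", {
  spec <- standardTestSpec(seed = 4, nNeurons = 0L, nNonNeuronNuclei = 0L,
                           artifactCount = 0L)
  res <- generateFrame(spec, "empty")
  m <- processFrame(res$frame, pipelineConfig())
  expect_true(m$excluded)
  expect_match(m$exclusion_reason, "denominator")
  expect_equal(m$total_neurite_length_um, 0)
  expect_equal(m$branch_point_count, 0L)
})

test_that("normalization maps the control mean to 100%", {
  tab <- data.frame(
    frame_id = paste0("f", 1:3), experiment_id = "E1",
    compound = c("DMSO", "DMSO", "drug"),
    concentration_nM = c(0, 0, 500),
    is_control = c(TRUE, TRUE, FALSE),
    neurite_length_per_cell_um = c(100, 120, 55),
    excluded = FALSE)
  out <- normalizeToControl(tab, metricCols = "neurite_length_per_cell_um")
  expect_equal(out$neurite_length_per_cell_um_pct_control, c(100 / 1.1,
                                                             120 / 1.1, 50))
  ctrlOnly <- tab[tab$is_control, ]
  outC <- normalizeToControl(ctrlOnly,
                             metricCols = "neurite_length_per_cell_um")
  expect_equal(mean(outC$neurite_length_per_cell_um_pct_control), 100)
})

test_that("excluded frames neither contribute to nor receive normalization", {
  tab <- data.frame(
    frame_id = paste0("f", 1:4), experiment_id = "E1",
    compound = c("DMSO", "DMSO", "drug", "drug"),
    concentration_nM = c(0, 0, 500, 500),
    is_control = c(TRUE, TRUE, FALSE, FALSE),
    neurite_length_per_cell_um = c(100, 9999, 55, 70),
    excluded = c(FALSE, TRUE, FALSE, TRUE))
  out <- normalizeToControl(tab, metricCols = "neurite_length_per_cell_um")
  expect_equal(out$neurite_length_per_cell_um_pct_control[3], 55)
  expect_true(is.na(out$neurite_length_per_cell_um_pct_control[4]))
  tab$is_control <- FALSE
  expect_error(normalizeToControl(tab,
                                  metricCols = "neurite_length_per_cell_um"),
               "control")
})

test_that("normalization is invariant to rescaling raw values", {
  tab <- data.frame(
    frame_id = paste0("f", 1:5), experiment_id = "E1",
    compound = c("DMSO", "DMSO", "d", "d", "d"),
    concentration_nM = c(0, 0, 100, 500, 1000),
    is_control = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    neurite_length_per_cell_um = c(90, 110, 80, 50, 20),
    excluded = FALSE)
  a <- normalizeToControl(tab, metricCols = "neurite_length_per_cell_um")
  tab2 <- tab
  tab2$neurite_length_per_cell_um <- tab$neurite_length_per_cell_um * 3.7
  b <- normalizeToControl(tab2, metricCols = "neurite_length_per_cell_um")
  expect_equal(a$neurite_length_per_cell_um_pct_control,
               b$neurite_length_per_cell_um_pct_control)
})

test_that("the constrained 4PL fit recovers exact model data", {
  conc <- c(100, 250, 500, 1000, 2500, 5000)
  y <- fourParamLogistic(conc, 100, 10, 500, 1.2)
  fit <- fitFourParamLogistic(conc, y, 100)
  expect_true(fit@converged)
  expect_lt(abs(fit@ld50 - 500) / 500, 0.01)
  expect_lt(abs(fit@hillSlope - 1.2), 0.05)
  expect_lt(abs(fit@bottom - 10), 0.5)
  # midpoint identity
  expect_equal(fourParamLogistic(500, 100, 0, 500, 1.7), 50)
  # declining curves (negative slope) work identically
  yd <- fourParamLogistic(conc, 100, 10, 500, -1.2)
  fd <- fitFourParamLogistic(conc, yd, 100)
  expect_lt(abs(fd@ld50 - 500) / 500, 0.01)
  expect_lt(abs(fd@hillSlope + 1.2), 0.05)
})

test_that("degenerate 4PL inputs are refused or flagged", {
  conc <- c(100, 250, 500, 1000, 2500, 5000)
  flat <- fitFourParamLogistic(conc, rep(100, 6), 100)
  expect_false(flat@converged)
  expect_true(is.na(flat@ld50))
  expect_error(fitFourParamLogistic(c(100, 250, 500), c(90, 70, 50), 100),
               ">= 4")
  expect_error(fitFourParamLogistic(c(0, 100, 250, 500), c(100, 90, 70, 50),
                                    100), "positive")
})

test_that("noisy 4PL replicates recover the median LD50 within 10%", {
  conc <- rep(c(100, 250, 500, 1000, 2500, 5000), each = 3)
  truth <- fourParamLogistic(conc, 100, 10, 500, 1.2)
  set.seed(2024)
  ld <- vapply(1:20, function(i) {
    y <- truth * (1 + rnorm(length(truth), 0, 0.05))
    fitFourParamLogistic(conc, y, 100)@ld50
  }, numeric(1))
  expect_lt(abs(median(ld) - 500) / 500, 0.10)
})

test_that("OLS matches hand-computed closed forms and lm", {
  r1 <- olsRegression(c(0, 1, 2), c(0, 1, 2))
  expect_equal(r1$slope, 1); expect_equal(r1$intercept, 0)
  expect_equal(r1$r_squared, 1)
  r2 <- olsRegression(c(0, 1, 2), c(0, 2, 2))
  expect_equal(r2$slope, 1)
  expect_equal(r2$intercept, 1 / 3)
  expect_equal(r2$r_squared, 0.75)
  set.seed(9)
  x <- runif(15); y <- 2 * x + rnorm(15, 0, 0.2)
  got <- olsRegression(x, y)
  ref <- stats::lm(y ~ x)
  expect_equal(got$slope, unname(coef(ref)[2]))
  expect_equal(got$intercept, unname(coef(ref)[1]))
  expect_equal(got$r_squared, summary(ref)$r.squared)
  self <- olsRegression(y, y)
  expect_equal(self$slope, 1); expect_equal(self$r_squared, 1)
  expect_error(olsRegression(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(olsRegression(1:2, 1:2), ">= 3")
})

test_that("OLS matches a brute-force grid minimization of the SSE", {
  set.seed(13)
  x <- runif(8, 0, 5); y <- 1.3 * x - 0.7 + rnorm(8, 0, 0.3)
  got <- olsRegression(x, y)
  grid <- expand.grid(slope = seq(got$slope - 0.5, got$slope + 0.5, 0.0005),
                      icpt = seq(got$intercept - 0.5, got$intercept + 0.5,
                                 0.0005))
  sse <- vapply(seq_len(nrow(grid)), function(i)
    sum((y - grid$icpt[i] - grid$slope[i] * x)^2), numeric(1))
  best <- grid[which.min(sse), ]
  expect_lt(abs(got$slope - best$slope), 1e-3)
  expect_lt(abs(got$intercept - best$icpt), 1e-3)
})
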